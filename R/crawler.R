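#' Path-pattern templates for image trees
#'
#' High-throughput imaging platforms encode metadata — plant id, time stamp,
#' image type, camera angle — in the directory structure and file names.
#' A path template describes that structure as an ordered list of path
#' components, each mixing literal text with named captures written
#' `{name}` or `{name:regex}`. For a LemnaTec-style tree
#' `p001_2024-01-05/rgbsv/0.png` the pattern is
#' `c("{id}_{date}", "{imtype}", "{angle}.png")`.
#'
#' Within one component, captures without an explicit regex match greedily
#' up to the next literal (the last capture of a component takes the rest).
#' Capture names must be unique across the pattern and must include at
#' least `id` and `imtype`.
#'
#' @param pattern Character vector of path-component specs, root first.
#' @return An object of class `path_template`.
#' @export
path_template <- function(pattern) {
  if (!is.character(pattern) || length(pattern) < 1L)
    stop("pattern must be a character vector of path components", call. = FALSE)
  comp <- lapply(pattern, compile_component)
  fields <- unlist(lapply(comp, `[[`, "names"))
  if (anyDuplicated(fields))
    stop("duplicate capture name(s): ",
         paste(unique(fields[duplicated(fields)]), collapse = ", "), call. = FALSE)
  if (!all(c("id", "imtype") %in% fields))
    stop("template error: pattern must capture at least `id` and `imtype`",
         call. = FALSE)
  structure(list(pattern = pattern, components = comp, fields = fields),
            class = "path_template")
}

#' @export
print.path_template <- function(x, ...) {
  cat("<path_template> ", paste(x$pattern, collapse = "/"),
      "\n  captures: ", paste(x$fields, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# One path component -> anchored regex with one group per capture.
compile_component <- function(spec) {
  rx <- ""
  names <- character()
  i <- 1L; n <- nchar(spec)
  while (i <= n) {
    ch <- substr(spec, i, i)
    if (ch == "{") {
      close <- regexpr("}", substr(spec, i, n), fixed = TRUE)
      if (close < 0) stop("unclosed capture in component: ", spec, call. = FALSE)
      body <- substr(spec, i + 1L, i + close - 2L)
      parts <- strsplit(body, ":", fixed = TRUE)[[1]]
      nm <- parts[1]
      if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", nm))
        stop("invalid capture name in component: ", spec, call. = FALSE)
      sub_rx <- if (length(parts) > 1L) paste(parts[-1], collapse = ":") else NULL
      i <- i + close
      if (is.null(sub_rx)) {
        # default: non-greedy, except a capture that ends the component
        sub_rx <- if (i > n) "[^/]+" else "[^/]+?"
      }
      rx <- paste0(rx, "(", sub_rx, ")")
      names <- c(names, nm)
    } else {
      specials <- c(".", "\\", "|", "(", ")", "[", "]", "}", "^", "$", "*", "+", "?")
      rx <- paste0(rx, if (ch %in% specials) paste0("\\", ch) else ch)
      i <- i + 1L
    }
  }
  list(regex = paste0("^", rx, "$"), names = names)
}

#' Crawl an image tree into metadata records
#'
#' Walks every file under `root`, parses paths that match the template into
#' one record per image, and counts the files that do not match — skipped
#' files are reported, never silently dropped, and
#' `nrow(records) + length(skipped)` always equals the number of files
#' under `root`.
#'
#' A `date` or `timestamp` capture is additionally parsed to ISO-8601; a
#' value that cannot be parsed is kept verbatim and flagged in the
#' `timestamp_valid` column (with a warning).
#'
#' @param root Directory to crawl.
#' @param template A [path_template()] or the character pattern for one.
#' @return `list(records = <data.frame>, skipped = <character paths>)`.
#'   `records` has one column per capture plus `path` (relative to `root`).
#' @export
crawl <- function(root, template) {
  if (!dir.exists(root)) stop("cannot read image root: ", root, call. = FALSE)
  if (!inherits(template, "path_template")) template <- path_template(template)
  files <- list.files(root, recursive = TRUE, all.files = FALSE)
  depth <- length(template$components)
  rows <- vector("list", length(files))
  skipped <- character()
  for (f in files) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1]]
    if (length(parts) != depth) { skipped <- c(skipped, f); next }
    caps <- list()
    ok <- TRUE
    for (k in seq_len(depth)) {
      comp <- template$components[[k]]
      m <- regexec(comp$regex, parts[k])[[1]]
      if (m[1] < 0) { ok <- FALSE; break }
      got <- regmatches(parts[k], list(m))[[1]]
      for (ci in seq_along(comp$names)) caps[[comp$names[ci]]] <- got[ci + 1L]
    }
    if (!ok) { skipped <- c(skipped, f); next }
    caps$path <- f
    rows[[f]] <- caps
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    records <- as.data.frame(stats::setNames(
      rep(list(character()), length(template$fields) + 1L),
      c(template$fields, "path")), stringsAsFactors = FALSE)
  } else {
    records <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(records) <- NULL
  }
  tcol <- intersect(c("timestamp", "date"), names(records))[1]
  if (!is.na(tcol) && nrow(records) > 0L) {
    parsed <- as.Date(records[[tcol]], optional = TRUE,
                      tryFormats = c("%Y-%m-%d", "%Y_%m_%d", "%Y%m%d"))
    records$timestamp_valid <- !is.na(parsed)
    if (any(!records$timestamp_valid))
      warning(sum(!records$timestamp_valid),
              " record(s) have unparseable timestamps (kept verbatim)",
              call. = FALSE)
  }
  list(records = records, skipped = skipped)
}

#' Join experiment metadata onto crawled records
#'
#' Additional metadata — genotype, replicate, greenhouse position — comes as
#' a comma-separated file with a key column matching the identifiers
#' extracted from the directory names. The join is left-join semantics:
#' records without a matching key survive with empty extras and are
#' counted.
#'
#' @param records Data frame from [crawl()] (the `records` element).
#' @param table A data frame or path to a CSV file with a header.
#' @param key_column Name of the key column in `table`; matched against the
#'   records' `id`.
#' @return `list(records = <joined data.frame>, unmatched = <ids without
#'   metadata>)`.
#' @export
join_metadata <- function(records, table, key_column = "id") {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE,
                                                    colClasses = "character")
  if (!key_column %in% names(table))
    stop("schema error: key column `", key_column, "` not in metadata header (",
         paste(names(table), collapse = ", "), ")", call. = FALSE)
  keys <- as.character(table[[key_column]])
  if (anyDuplicated(keys))
    stop("duplicate key(s) in metadata: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  extra_cols <- setdiff(names(table), key_column)
  m <- match(records$id, keys)
  for (col in extra_cols) {
    v <- as.character(table[[col]])[m]
    v[is.na(m)] <- ""
    records[[col]] <- v
  }
  unmatched <- unique(records$id[is.na(m)])
  list(records = records, unmatched = unmatched)
}

#' Load image records into the results database
#'
#' Writes one row per record into the `images` table of a single SQLite
#' database, keyed on `path`: re-loading the same tree is idempotent and
#' never duplicates rows.
#'
#' @param records Data frame of image records (from [crawl()] /
#'   [join_metadata()]).
#' @param db_path Path to the SQLite database file (created if absent).
#' @return The number of records written, invisibly.
#' @export
load_database <- function(records, db_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  cols <- names(records)
  for (col in cols) records[[col]] <- as.character(records[[col]])
  col_defs <- paste(sprintf("`%s` TEXT", cols), collapse = ", ")
  DBI::dbExecute(con, sprintf(
    "CREATE TABLE IF NOT EXISTS images (%s, UNIQUE(`path`))", col_defs))
  if (nrow(records) > 0L) {
    placeholders <- paste(rep("?", length(cols)), collapse = ", ")
    sql <- sprintf("INSERT OR REPLACE INTO images (%s) VALUES (%s)",
                   paste(sprintf("`%s`", cols), collapse = ", "), placeholders)
    DBI::dbExecute(con, sql, params = unname(as.list(records)))
  }
  invisible(nrow(records))
}

#' Read the images table back from a results database
#'
#' @param db_path Path to the SQLite database.
#' @return The `images` table as a data frame.
#' @export
read_image_table <- function(db_path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbReadTable(con, "images")
}
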