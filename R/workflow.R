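## Template-driven workflow engine: validate the three JSON templates,
## expand per-image-type job lists into a dependency DAG over all crawled
## images, execute with an in-process scheduler, and aggregate per-worker
## databases into the final results database.

# Registry of operations a processing-template job may name. `kind` is what
# the job produces: a transformed image or trait rows.
op_registry <- function() {
  list(
    crop = list(kind = "image",
      fn = function(image, args) crop(image, unlist(args$roi)),
      check = function(args) {
        if (is.null(args$roi) || length(unlist(args$roi)) != 4L)
          "crop requires `roi` = [ystart, yend, xstart, xend]" else NULL
      }),
    colorFilter = list(kind = "image",
      fn = function(image, args)
        color_filter(image, args$expr,
                     roi = if (!is.null(args$roi)) unlist(args$roi)),
      check = function(args) {
        if (is.null(args$expr)) return("colorFilter requires `expr`")
        tryCatch({ parse_filter(args$expr); NULL },
                 error = function(e) conditionMessage(e))
      }),
    contourChop = list(kind = "image",
      fn = function(image, args) contour_chop(image, args$min_area),
      check = function(args) {
        if (is.null(args$min_area) || args$min_area < 0)
          "contourChop requires `min_area` >= 0" else NULL
      }),
    morphologicalOpen = list(kind = "image",
      fn = function(image, args)
        morphological_open(image, args$kernel %||% 3L, args$iterations %||% 1L),
      check = function(args) {
        k <- args$kernel %||% 3L
        if (k < 1 || k %% 2 != 1) "morphologicalOpen requires an odd `kernel`" else NULL
      }),
    contourCut = list(kind = "image",
      fn = function(image, args)
        contour_cut(image, args$min_area %||% 0, args$padding %||% 0)$image,
      check = function(args) NULL),
    extract = list(kind = "traits",
      fn = function(image, args) {
        mask <- to_binary(image)
        traits <- extract_base_traits(mask)
        rows <- data.frame(trait = names(traits), value = unname(traits),
                           stringsAsFactors = FALSE)
        if (isTRUE(args$histogram)) {
          h <- color_histogram(image, mask, args$bins %||% 8L)
          hrows <- data.frame(
            trait = paste0("hist_", rep(c("r", "g", "b"), each = h$bins),
                           "_", rep(seq_len(h$bins), 3L)),
            value = as.vector(h$proportions), stringsAsFactors = FALSE)
          rows <- rbind(rows, hrows)
        }
        rows
      },
      check = function(args) NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_template <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("missing ", what, " template: ", x, call. = FALSE)
    tryCatch(jsonlite::read_json(x),
             error = function(e) stop(what, " template is not valid JSON: ",
                                      conditionMessage(e), call. = FALSE))
  } else if (is.list(x)) x
  else stop(what, " template must be a file path or a list", call. = FALSE)
}

#' Validate the three workflow templates
#'
#' A run is fully parameterized by three JSON documents: the *loading*
#' template (path pattern + optional metadata CSV and key column), the
#' *processing* template (one job list per image type), and the
#' *configuration* template (executor settings: `max_concurrent`,
#' `output_root`, `seed`). Jobs declare named input/output image slots;
#' dependencies follow slot wiring, not list order. Validation is complete:
#' every violation (unknown operation, bad arguments, dangling input slot,
#' duplicate name, cycle, workflow/image-type mismatch) is collected and
#' reported at once via an error of class `template_error` whose
#' `violations` field is a data frame `(template, workflow, job, field,
#' problem)`.
#'
#' @param loading,processing,config Template file paths or already-parsed
#'   lists.
#' @param imtypes Optional character vector of image types present in the
#'   database; if given, workflow names must be a subset of it.
#' @return A validated `workflow_spec` object.
#' @export
validate_templates <- function(loading, processing, config = list(), imtypes = NULL) {
  v <- list()
  bad <- function(template, workflow, job, field, problem)
    v[[length(v) + 1L]] <<- data.frame(template = template, workflow = workflow,
                                       job = job, field = field, problem = problem,
                                       stringsAsFactors = FALSE)
  ld <- read_template(loading, "loading")
  pr <- read_template(processing, "processing")
  cf <- read_template(config, "configuration")

  tmpl <- NULL
  if (is.null(ld$pattern)) {
    bad("loading", "", "", "pattern", "missing `pattern`")
  } else {
    tmpl <- tryCatch(path_template(unlist(ld$pattern)),
                     error = function(e) { bad("loading", "", "", "pattern",
                                               conditionMessage(e)); NULL })
  }

  reg <- op_registry()
  wfs <- pr$workflows %||% pr   # allow the workflow map at top level
  if (!is.list(wfs) || is.null(names(wfs)) || any(names(wfs) == ""))
    bad("processing", "", "", "workflows", "must map image type -> job list")
  workflows <- list()
  if (is.list(wfs) && !is.null(names(wfs))) {
    for (wname in names(wfs)) {
      jobs <- wfs[[wname]]
      if (!is.list(jobs) || length(jobs) == 0L) {
        bad("processing", wname, "", "jobs", "empty or malformed job list")
        next
      }
      jobs <- lapply(jobs, function(j) {
        j$arguments <- j$arguments %||% list()
        j$inputs <- j$inputs %||% list()
        j$outputs <- j$outputs %||% list()
        j
      })
      names(jobs) <- vapply(jobs, function(j) j$name %||% "", "")
      if (any(names(jobs) == ""))
        bad("processing", wname, "", "name", "every job needs a `name`")
      if (anyDuplicated(names(jobs)))
        bad("processing", wname, names(jobs)[duplicated(names(jobs))][1],
            "name", "duplicate job name")
      out_slots <- list()   # slot -> producing job
      for (j in jobs) {
        if (is.null(j$operation) || !j$operation %in% names(reg)) {
          bad("processing", wname, j$name %||% "", "operation",
              paste0("unknown operation `", j$operation %||% "", "`"))
          next
        }
        prob <- reg[[j$operation]]$check(j$arguments)
        if (!is.null(prob)) bad("processing", wname, j$name, "arguments", prob)
        for (slot in unlist(j$outputs)) {
          if (!is.null(out_slots[[slot]]))
            bad("processing", wname, j$name, "outputs",
                paste0("slot `", slot, "` produced twice"))
          out_slots[[slot]] <- j$name
        }
      }
      # dangling inputs + dependency edges
      edges <- list()
      for (j in jobs) {
        for (slot in unlist(j$inputs)) {
          if (identical(slot, "raw")) next
          prod <- out_slots[[slot]]
          if (is.null(prod))
            bad("processing", wname, j$name %||% "", "inputs",
                paste0("dangling input slot `", slot, "`"))
          else edges[[length(edges) + 1L]] <- c(prod, j$name)
        }
      }
      ord <- topo_order(names(jobs), edges)
      if (is.null(ord))
        bad("processing", wname, "", "inputs", "cycle in job dependencies")
      workflows[[wname]] <- list(jobs = jobs, edges = edges, order = ord)
    }
    if (!is.null(imtypes)) {
      for (wname in setdiff(names(wfs), imtypes))
        bad("processing", wname, "", "workflow",
            paste0("no image type `", wname, "` in the database (types: ",
                   paste(imtypes, collapse = ", "), ")"))
    }
  }

  mc <- cf$max_concurrent %||% 1L
  if (!is.numeric(mc) || mc < 1)
    bad("configuration", "", "", "max_concurrent", "must be an integer >= 1")

  if (length(v)) {
    viol <- do.call(rbind, v)
    stop(structure(class = c("template_error", "error", "condition"),
                   list(message = paste0(
                          "invalid templates (", nrow(viol), " violation(s)):\n",
                          paste(sprintf("  [%s] %s/%s %s: %s", viol$template,
                                        viol$workflow, viol$job, viol$field,
                                        viol$problem), collapse = "\n")),
                        call = NULL, violations = viol)))
  }
  structure(list(
    loading = list(template = tmpl, metadata = ld$metadata,
                   key_column = ld$key_column %||% "id"),
    workflows = workflows,
    config = list(max_concurrent = as.integer(mc),
                  output_root = cf$output_root %||% ".",
                  seed = cf$seed)),
    class = "workflow_spec")
}

#' @export
print.workflow_spec <- function(x, ...) {
  cat("<workflow_spec>\n  pattern: ",
      paste(x$loading$template$pattern, collapse = "/"), "\n", sep = "")
  for (w in names(x$workflows))
    cat(sprintf("  workflow %s: %d job(s) [%s]\n", w,
                length(x$workflows[[w]]$jobs),
                paste(x$workflows[[w]]$order, collapse = " -> ")))
  cat("  max_concurrent:", x$config$max_concurrent, "\n")
  invisible(x)
}

# Kahn topological sort; NULL if the graph has a cycle.
topo_order <- function(nodes, edges) {
  nodes <- nodes[nodes != ""]
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (e in edges) {
    if (!all(e %in% nodes)) next
    indeg[[e[2]]] <- indeg[[e[2]]] + 1L
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
  }
  queue <- nodes[indeg == 0L]
  out <- character()
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    out <- c(out, n)
    for (m in adj[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

#' Expand a workflow spec over image records into an execution plan
#'
#' One task per (image record, job); edges follow the jobs' slot wiring.
#' Records whose image type has no workflow are excluded and reported in
#' the plan's `excluded` element, never silently dropped.
#'
#' @param spec A [validate_templates()] result.
#' @param records Data frame of image records (needs `imtype` and `path`).
#' @param root Image tree root; `root/path` must be the image file.
#' @return An `execution_plan`: `list(tasks, records, excluded)` where
#'   `tasks` has one row per task and `n_edges` counts dependencies.
#' @export
build_plan <- function(spec, records, root = ".") {
  if (!inherits(spec, "workflow_spec")) stop("`spec` must be a workflow_spec")
  known <- records$imtype %in% names(spec$workflows)
  excluded <- records[!known, , drop = FALSE]
  records <- records[known, , drop = FALSE]
  tasks <- list()
  n_edges <- 0L
  if (nrow(records) > 0L) {
    for (i in seq_len(nrow(records))) {
      wf <- spec$workflows[[records$imtype[i]]]
      tasks[[i]] <- data.frame(record = i, image_key = records$path[i],
                               job = wf$order, stringsAsFactors = FALSE)
      n_edges <- n_edges + length(wf$edges)
    }
  }
  tasks <- if (length(tasks)) do.call(rbind, tasks)
           else data.frame(record = integer(), image_key = character(),
                           job = character(), stringsAsFactors = FALSE)
  structure(list(tasks = tasks, records = records, excluded = excluded,
                 root = root, n_edges = n_edges, spec = spec),
            class = "execution_plan")
}

#' @export
print.execution_plan <- function(x, ...) {
  cat(sprintf("<execution_plan> %d task(s) over %d image(s), %d dependency edge(s)",
              nrow(x$tasks), nrow(x$records), x$n_edges), "\n")
  if (nrow(x$excluded))
    cat("  excluded (no workflow for image type):", nrow(x$excluded), "record(s)\n")
  invisible(x)
}

sanitize_key <- function(key) gsub("[^A-Za-z0-9._-]", "_", key)

# Run every job of one record in topological order; write that record's
# worker database (traits + per-task status) and processed images. A task
# failure blocks only its descendants; earlier outputs are preserved.
run_record <- function(i, plan, out_dir) {
  rec <- plan$records[i, ]
  wf <- plan$spec$workflows[[rec$imtype]]
  key <- rec$path
  img_dir <- file.path(out_dir, "images", sanitize_key(key))
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  db_path <- file.path(out_dir, "workers", sprintf("worker_%05d.db", i))
  reg <- op_registry()
  slots <- list()
  status <- stats::setNames(rep("pending", length(wf$order)), wf$order)
  msgs <- stats::setNames(rep("", length(wf$order)), wf$order)
  trait_rows <- list()
  slots[["raw"]] <- tryCatch(read_image(file.path(plan$root, rec$path)),
                             error = function(e) e)
  for (jname in wf$order) {
    j <- wf$jobs[[jname]]
    ins <- lapply(unlist(j$inputs), function(s) slots[[s]])
    blocked <- any(vapply(ins, function(x) is.null(x) || inherits(x, "error"),
                          logical(1)))
    if (blocked) { status[jname] <- "skipped"; msgs[jname] <- "upstream failure"; next }
    res <- tryCatch(reg[[j$operation]]$fn(ins[[1]], j$arguments),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[jname] <- "failed"
      msgs[jname] <- conditionMessage(res)
      for (slot in unlist(j$outputs)) slots[[slot]] <- res
      next
    }
    status[jname] <- "done"
    if (reg[[j$operation]]$kind == "image") {
      for (slot in unlist(j$outputs)) slots[[slot]] <- res
      write_image(res, file.path(img_dir, paste0(jname, ".png")))
    } else {
      res$image_key <- key
      trait_rows[[jname]] <- res[, c("image_key", "trait", "value")]
    }
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  traits <- if (length(trait_rows)) do.call(rbind, trait_rows)
            else data.frame(image_key = character(), trait = character(),
                            value = numeric(), stringsAsFactors = FALSE)
  rownames(traits) <- NULL
  DBI::dbWriteTable(con, "traits", traits, overwrite = TRUE)
  DBI::dbWriteTable(con, "tasks",
                    data.frame(image_key = key, job = wf$order,
                               status = unname(status), message = unname(msgs),
                               stringsAsFactors = FALSE),
                    overwrite = TRUE)
  db_path
}

#' Execute an execution plan
#'
#' Tasks run grouped by image record — each record's jobs run in dependency
#' order and write an isolated per-record worker database, mirroring
#' worker-node execution on a computing grid: concurrent workers never
#' share a database, so results are identical for any concurrency level.
#' Trait rows and processed images land under `out_dir`.
#'
#' @param plan A [build_plan()] result.
#' @param out_dir Output directory (created if needed).
#' @param max_concurrent Number of records processed in parallel.
#' @return Character vector of worker database paths.
#' @export
execute_plan <- function(plan, out_dir, max_concurrent = 1L) {
  if (!inherits(plan, "execution_plan")) stop("`plan` must be an execution_plan")
  dir.create(file.path(out_dir, "workers"), recursive = TRUE, showWarnings = FALSE)
  n <- nrow(plan$records)
  if (n == 0L) return(character())
  runner <- function(i) run_record(i, plan, out_dir)
  if (max_concurrent > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(seq_len(n), runner,
                              mc.cores = as.integer(max_concurrent))
    err <- vapply(res, inherits, logical(1), what = "try-error")
    if (any(err)) stop("worker failure: ", res[[which(err)[1]]], call. = FALSE)
    unlist(res)
  } else {
    vapply(seq_len(n), runner, character(1))
  }
}

#' Aggregate per-worker databases into the final database
#'
#' Workers write to separate databases to avoid concurrency issues; this
#' combines them into the single final database. All workers must share one
#' schema (same tables, same columns) — a mismatch is an error naming the
#' divergent table. No row is created, lost or altered: the final row count
#' of every table is the sum of the worker counts, and rows are inserted in
#' a canonical sort order so the result is independent of worker order.
#'
#' @param worker_dbs Character vector of worker database paths.
#' @param final_db Path of the final database (appended to if it exists).
#' @return Named integer vector: rows written per table.
#' @export
aggregate_dbs <- function(worker_dbs, final_db) {
  if (length(worker_dbs) == 0L) return(stats::setNames(integer(), character()))
  contents <- lapply(worker_dbs, function(p) {
    con <- DBI::dbConnect(RSQLite::SQLite(), p)
    on.exit(DBI::dbDisconnect(con))
    tabs <- sort(DBI::dbListTables(con))
    stats::setNames(lapply(tabs, DBI::dbReadTable, conn = con), tabs)
  })
  ref <- lapply(contents[[1]], names)
  for (k in seq_along(contents)) {
    got <- lapply(contents[[k]], names)
    if (!identical(names(got), names(ref)))
      stop("schema mismatch in ", worker_dbs[k], ": tables {",
           paste(names(got), collapse = ", "), "} vs {",
           paste(names(ref), collapse = ", "), "}", call. = FALSE)
    for (tb in names(ref))
      if (!identical(got[[tb]], ref[[tb]]))
        stop("schema mismatch in ", worker_dbs[k], ", table `", tb,
             "`: columns {", paste(got[[tb]], collapse = ", "), "} vs {",
             paste(ref[[tb]], collapse = ", "), "}", call. = FALSE)
  }
  con <- DBI::dbConnect(RSQLite::SQLite(), final_db)
  on.exit(DBI::dbDisconnect(con))
  counts <- integer()
  for (tb in names(ref)) {
    all_rows <- do.call(rbind, lapply(contents, `[[`, tb))
    ord <- do.call(order, unname(as.list(all_rows)))
    all_rows <- all_rows[ord, , drop = FALSE]
    rownames(all_rows) <- NULL
    DBI::dbWriteTable(con, tb, all_rows, append = TRUE)
    counts[tb] <- nrow(all_rows)
  }
  counts
}

#' Read the trait table of a results database
#'
#' @param db_path Path to a results database.
#' @param sort Return rows in canonical `(image_key, trait)` order.
#' @return Data frame `(image_key, trait, value)`.
#' @export
read_trait_table <- function(db_path, sort = TRUE) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  tr <- DBI::dbReadTable(con, "traits")
  if (sort) {
    tr <- tr[order(tr$image_key, tr$trait), , drop = FALSE]
    rownames(tr) <- NULL
  }
  tr
}

#' Pivot a long trait table to wide format
#'
#' @param traits Long data frame `(image_key, trait, value)`.
#' @return Wide data frame: one row per image, one column per trait.
#' @export
traits_wide <- function(traits) {
  wide <- stats::reshape(traits, idvar = "image_key", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Run a complete workflow from the three templates
#'
#' The end-to-end entry point: validates the templates, crawls the image
#' tree, joins metadata, loads everything into the results database, builds
#' and executes the plan, and aggregates the per-worker databases. Output
#' goes to a fresh date-and-time-stamped directory under the configuration
#' template's `output_root`, containing the final database (`results.db`,
#' tables `images`, `traits`, `tasks`), verbatim copies of the three
#' templates, the metadata CSV, worker databases, and processed images.
#' Re-running creates a new directory and leaves earlier runs untouched.
#'
#' @param loading,processing,config Template file paths (or lists; file
#'   paths are required for the verbatim template copies).
#' @param root Image tree root directory.
#' @return A `workflow_run` object: `list(output_dir, db, n_images, n_skipped,
#'   worker_dbs, row_counts)`. With zero matching images the run completes
#'   with a warning and an empty trait table.
#' @export
run_workflow <- function(loading, processing, config, root) {
  cr0 <- crawl(root, path_template(unlist(read_template(loading, "loading")$pattern)))
  spec <- validate_templates(loading, processing, config,
                             imtypes = if (nrow(cr0$records) > 0L)
                               unique(cr0$records$imtype))
  if (!is.null(spec$config$seed)) set.seed(as.integer(spec$config$seed))
  stamp <- format(Sys.time(), "run_%Y%m%d_%H%M%S")
  out_dir <- file.path(spec$config$output_root, stamp)
  k <- 1L
  while (dir.exists(out_dir)) {
    out_dir <- file.path(spec$config$output_root, sprintf("%s_%d", stamp, k))
    k <- k + 1L
  }
  dir.create(file.path(out_dir, "templates"), recursive = TRUE)
  for (tf in c(loading, processing, config))
    if (is.character(tf) && file.exists(tf))
      file.copy(tf, file.path(out_dir, "templates", basename(tf)))
  records <- cr0$records
  meta <- spec$loading$metadata
  if (!is.null(meta)) {
    meta_path <- if (file.exists(meta)) meta else file.path(root, meta)
    if (file.exists(meta_path)) {
      file.copy(meta_path, file.path(out_dir, basename(meta_path)))
      records <- join_metadata(records, meta_path, spec$loading$key_column)$records
    } else warning("metadata file not found: ", meta, call. = FALSE)
  }
  db <- file.path(out_dir, "results.db")
  load_database(records, db)
  plan <- build_plan(spec, records, root)
  workers <- execute_plan(plan, out_dir, spec$config$max_concurrent)
  counts <- aggregate_dbs(workers, db)
  if (nrow(records) == 0L)
    warning("run produced no images: nothing matched the loading pattern under ",
            root, call. = FALSE)
  structure(list(output_dir = out_dir, db = db, n_images = nrow(records),
                 n_skipped = length(cr0$skipped), worker_dbs = workers,
                 row_counts = counts),
            class = "workflow_run")
}

#' @export
print.workflow_run <- function(x, ...) {
  cat("<workflow_run>", x$output_dir, "\n")
  cat(sprintf("  images: %d (skipped files: %d)\n", x$n_images, x$n_skipped))
  if (length(x$row_counts))
    cat("  aggregated rows:",
        paste(sprintf("%s=%d", names(x$row_counts), x$row_counts), collapse = ", "),
        "\n")
  invisible(x)
}
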