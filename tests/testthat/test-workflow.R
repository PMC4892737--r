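make_jobs <- function() standard_jobs()

test_that("a correctly wired four-stage workflow validates", {
  dir <- withr::local_tempdir()
  paths <- write_templates(dir, output_root = dir)
  spec <- validate_templates(paths[1], paths[2], paths[3])
  expect_s3_class(spec, "workflow_spec")
  expect_identical(spec$workflows$rgbsv$order,
                   c("crop1", "filter1", "chop1", "cut1", "extract1"))
})

test_that("validation collects dangling slots, cycles, and unknown operations", {
  jobs <- make_jobs()
  jobs[[2]]$inputs$image <- "nonexistent"        # dangling
  jobs[[3]]$operation <- "sharpen"               # unknown op
  pr <- list(workflows = list(rgbsv = jobs))
  ld <- list(pattern = list("{id}_{date}", "{imtype}", "{angle}.png"))
  err <- tryCatch(validate_templates(ld, pr), error = function(e) e)
  expect_s3_class(err, "template_error")
  expect_true(any(grepl("dangling", err$violations$problem)))
  expect_true(any(grepl("unknown operation", err$violations$problem)))
  expect_true(all(c("template", "workflow", "job", "field", "problem")
                  %in% names(err$violations)))
  # cycle: two jobs consuming each other's outputs
  cyc <- list(
    list(name = "a", operation = "contourChop", arguments = list(min_area = 1),
         inputs = list(image = "bout"), outputs = list(image = "aout")),
    list(name = "b", operation = "contourChop", arguments = list(min_area = 1),
         inputs = list(image = "aout"), outputs = list(image = "bout")))
  err2 <- tryCatch(validate_templates(ld, list(workflows = list(rgbsv = cyc))),
                   error = function(e) e)
  expect_s3_class(err2, "template_error")
  expect_true(any(grepl("cycle", err2$violations$problem)))
  # bad filter expression is caught at validation time
  bad <- make_jobs(); bad[[2]]$arguments$expr <- "g >"
  err3 <- tryCatch(validate_templates(ld, list(workflows = list(rgbsv = bad))),
                   error = function(e) e)
  expect_true(any(grepl("parse error", err3$violations$problem)))
  # workflow name not among database image types
  err4 <- tryCatch(validate_templates(ld, list(workflows = list(rgbsv = make_jobs())),
                                      imtypes = c("fluosv")),
                   error = function(e) e)
  expect_true(any(grepl("no image type", err4$violations$problem)))
})

test_that("plans have one task per record-job pair and report exclusions", {
  dir <- withr::local_tempdir()
  paths <- write_templates(dir, output_root = dir)
  spec <- validate_templates(paths[1], paths[2], paths[3])
  records <- data.frame(id = sprintf("p%02d", 1:10), imtype = "rgbsv",
                        path = sprintf("f%02d.png", 1:10),
                        stringsAsFactors = FALSE)
  plan <- build_plan(spec, records)
  expect_identical(nrow(plan$tasks), 50L)       # 10 records x 5 jobs
  expect_identical(plan$n_edges, 40L)           # 4 wired edges per record
  # unknown image type is excluded and reported
  records2 <- rbind(records, data.frame(id = "p99", imtype = "fluosv",
                                        path = "x.png"))
  plan2 <- build_plan(spec, records2)
  expect_identical(nrow(plan2$excluded), 1L)
  expect_identical(nrow(plan2$tasks), 50L)
  # zero records -> empty plan
  expect_identical(nrow(build_plan(spec, records[0, ])$tasks), 0L)
})

test_that("job list order does not affect the plan: wiring defines the DAG", {
  dir <- withr::local_tempdir()
  paths <- write_templates(dir, output_root = dir)
  spec_f <- validate_templates(paths[1], paths[2], paths[3])
  rev_jobs <- rev(make_jobs())
  pr <- list(workflows = list(rgbsv = rev_jobs, rgbtv = rev_jobs))
  spec_r <- validate_templates(paths[1], pr, paths[3])
  expect_identical(spec_f$workflows$rgbsv$order, spec_r$workflows$rgbsv$order)
})

test_that("execution is schedule-invariant and aggregation conserves rows", {
  base <- withr::local_tempdir()
  root <- file.path(base, "tree")
  generate_tree(root, n_plants = 2, n_days = 3, seed = 5)
  paths <- write_templates(base, output_root = file.path(base, "out"))
  r1 <- run_workflow(paths[1], paths[2], paths[3], root)
  cf8 <- list(max_concurrent = 8, output_root = file.path(base, "out"))
  r8 <- run_workflow(paths[1], paths[2], cf8, root)
  t1 <- read_trait_table(r1$db); t8 <- read_trait_table(r8$db)
  expect_gt(nrow(t1), 0L)
  expect_identical(t1, t8)
  expect_identical(length(unique(t1$image_key)), 18L)
  # aggregation conserves counts under worker permutation
  set.seed(9)
  perm <- sample(r1$worker_dbs)
  db2 <- file.path(base, "agg2.db")
  counts <- aggregate_dbs(perm, db2)
  expect_identical(unname(counts["traits"]), nrow(t1))
  expect_identical(read_trait_table(db2), t1)
})

test_that("a failing job blocks only its descendants and keeps upstream output", {
  base <- withr::local_tempdir()
  root <- file.path(base, "tree")
  generate_tree(root, n_plants = 1, n_days = 1, seed = 2)
  jobs <- make_jobs()
  # contourCut with an impossible threshold fails after filtering succeeds
  jobs[[4]]$arguments$min_area <- 1e9
  paths <- write_templates(base, output_root = file.path(base, "out"),
                           jobs = jobs)
  res <- run_workflow(paths[1], paths[2], paths[3], root)
  con <- DBI::dbConnect(RSQLite::SQLite(), res$db)
  tasks <- DBI::dbReadTable(con, "tasks")
  DBI::dbDisconnect(con)
  st <- setNames(tasks$status, tasks$job)
  expect_identical(unname(st[c("crop1", "filter1", "chop1")]),
                   rep("done", 3))
  expect_identical(unname(st["cut1"]), "failed")
  expect_identical(unname(st["extract1"]), "skipped")
  expect_match(tasks$message[tasks$job == "cut1"], "empty plant")
  # upstream processed images were still written
  imgs <- list.files(file.path(res$output_dir, "images"), recursive = TRUE)
  expect_true(any(grepl("chop1", imgs)))
  expect_identical(nrow(read_trait_table(res$db)), 0L)
})

test_that("runs copy templates and metadata into a fresh stamped directory", {
  base <- withr::local_tempdir()
  root <- file.path(base, "tree")
  generate_tree(root, n_plants = 1, n_days = 1, seed = 8)
  paths <- write_templates(base, output_root = file.path(base, "out"))
  r1 <- run_workflow(paths[1], paths[2], paths[3], root)
  expect_setequal(list.files(file.path(r1$output_dir, "templates")),
                  c("loading.json", "processing.json", "config.json"))
  expect_true(file.exists(file.path(r1$output_dir, "metadata.csv")))
  before <- file.info(r1$db)$mtime
  r2 <- run_workflow(paths[1], paths[2], paths[3], root)
  expect_false(identical(r1$output_dir, r2$output_dir))
  expect_identical(file.info(r1$db)$mtime, before)  # first run untouched
})

test_that("a run over an empty tree completes with a warning and empty traits", {
  base <- withr::local_tempdir()
  root <- file.path(base, "empty")
  dir.create(root)
  writeLines("id,genotype", file.path(root, "metadata.csv"))
  paths <- write_templates(base, output_root = file.path(base, "out"))
  expect_warning(res <- run_workflow(paths[1], paths[2], paths[3], root),
                 "no images")
  expect_identical(res$n_images, 0L)
  con <- DBI::dbConnect(RSQLite::SQLite(), res$db)
  on.exit(DBI::dbDisconnect(con))
  expect_false("traits" %in% DBI::dbListTables(con) &&
                 nrow(DBI::dbReadTable(con, "traits")) > 0)
})

test_that("aggregation rejects schema drift, naming the divergent table", {
  base <- withr::local_tempdir()
  mkdb <- function(name, extra = FALSE) {
    p <- file.path(base, name)
    con <- DBI::dbConnect(RSQLite::SQLite(), p)
    df <- data.frame(image_key = "a", trait = "x", value = 1)
    if (extra) df$extra <- "!"
    DBI::dbWriteTable(con, "traits", df)
    DBI::dbWriteTable(con, "tasks", data.frame(image_key = "a", job = "j",
                                               status = "done", message = ""))
    DBI::dbDisconnect(con)
    p
  }
  a <- mkdb("a.db"); b <- mkdb("b.db"); bad <- mkdb("c.db", extra = TRUE)
  counts <- aggregate_dbs(c(a, b), file.path(base, "ok.db"))
  expect_identical(unname(counts["traits"]), 2L)
  expect_error(aggregate_dbs(c(a, bad), file.path(base, "no.db")),
               "schema mismatch.*traits")
})
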