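# Record a generated pipeline under a session and return everything the
# replication tests need.
recorded_pipeline <- function(n_stages, branching, seed) {
  pipe <- gen_pipeline(n_stages, branching, seed)
  root <- tempfile("src")
  materialize_pipeline(pipe, root)
  ctx <- mount_session(root)
  run_pipeline(ctx, pipe)
  bundle <- export_bundle(ctx, pipe$target)
  session_close(ctx)
  list(pipe = pipe, root = root, bundle = bundle)
}

test_that("an exported bundle is self-contained and matches the known topology", {
  rec <- recorded_pipeline(3, 1, seed = 11)
  withr::defer(unlink(rec$root, recursive = TRUE))
  b <- rec$bundle
  ## 3 stage processes + the driver shell
  expect_equal(length(b$processes), rec$pipe$expected$n_stage_procs + 1)
  expect_equal(length(b$files), rec$pipe$expected$n_files)
  expect_equal(length(b$external_inputs), rec$pipe$expected$n_external)
  expect_identical(b$target$content_checksum, rec$pipe$expected$checksum)
  ## every edge endpoint is present
  pk <- vapply(b$processes, function(p) as.numeric(p$proc_key), 1)
  fk <- vapply(b$files, function(f) as.numeric(f$file_key), 1)
  for (e in b$write_edges) {
    expect_true(as.numeric(e$proc_key) %in% pk)
    expect_true(as.numeric(e$file_key) %in% fk)
  }
})

test_that("an external-origin target exports with no processes", {
  root <- withr::local_tempdir()
  writeLines("downloaded", file.path(root, "ref.db"))
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  r <- sim_caller(600, "reader")
  h <- vfs_open(ctx, "ref.db", "r", caller = r); vfs_read(ctx, h, Inf); vfs_close(ctx, h)
  b <- export_bundle(ctx, "ref.db")
  expect_length(b$processes, 0)
  expect_length(b$external_inputs, 1)
  expect_error(reconstruct_script(b), "external origin")
})

test_that("bundle serialization round-trips to identical bytes", {
  rec <- recorded_pipeline(2, 2, seed = 12)
  withr::defer(unlink(rec$root, recursive = TRUE))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_bundle(rec$bundle, p1)
  write_bundle(read_bundle(p1), p2)
  expect_identical(readBin(p1, raw(), file.size(p1)),
                   readBin(p2, raw(), file.size(p2)))
  expect_error(read_bundle(write_bundle(
    structure(list(schema_version = 99), class = "repl_bundle"),
    withr::local_tempfile())), "schema")
})

test_that("the reconstructed script alone reproduces the target byte-for-byte", {
  rec <- recorded_pipeline(4, 2, seed = 13)
  withr::defer(unlink(rec$root, recursive = TRUE))
  script <- reconstruct_script(rec$bundle)
  ## the original driver is a wrapper: its children are invoked, it is not
  expect_false(grepl("run_pipeline.sh", script))
  cmd_lines <- grep("^'bin/tool_", strsplit(script, "\n")[[1]], value = TRUE)
  expect_length(cmd_lines, rec$pipe$expected$n_stage_procs)
  ## run it standalone in a clean directory seeded with external inputs
  wd <- tempfile("standalone"); dir.create(wd)
  withr::defer(unlink(wd, recursive = TRUE))
  for (f in rec$bundle$external_inputs) {
    dir.create(dirname(file.path(wd, f$path)), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(rec$root, f$path), file.path(wd, f$path), copy.mode = TRUE)
  }
  writeLines(script, file.path(wd, "go.sh"))
  res <- processx::run("sh", "go.sh", wd = wd, env = c(Sys.getenv(), LC_ALL = "C"))
  expect_equal(res$status, 0)
  expect_identical(digest::digest(file.path(wd, rec$pipe$target), algo = "sha256",
                                  file = TRUE),
                   rec$pipe$expected$checksum)
})

test_that("independent branches replicate identically under either order", {
  ## two independent unary chains merged by a final stage: run the two
  ## branch prefixes in both orders and compare targets
  rec <- recorded_pipeline(5, 2, seed = 14)
  withr::defer(unlink(rec$root, recursive = TRUE))
  leaf <- Filter(function(p) !identical(basename(p$exe_path), "sh"),
                 rec$bundle$processes)
  cmds <- vapply(leaf, function(p) paste(vapply(unlist(p$cmdline), shQuote, ""),
                                         collapse = " "), "")
  run_order <- function(cmds) {
    wd <- tempfile("order"); dir.create(wd)
    on.exit(unlink(wd, recursive = TRUE))
    for (f in rec$bundle$external_inputs) {
      dir.create(dirname(file.path(wd, f$path)), recursive = TRUE, showWarnings = FALSE)
      file.copy(file.path(rec$root, f$path), file.path(wd, f$path), copy.mode = TRUE)
    }
    dir.create(file.path(wd, "out"), showWarnings = FALSE)
    writeLines(c("#!/bin/sh", "set -e", cmds), file.path(wd, "go.sh"))
    processx::run("sh", "go.sh", wd = wd, env = c(Sys.getenv(), LC_ALL = "C"))
    digest::digest(file.path(wd, rec$pipe$target), algo = "sha256", file = TRUE)
  }
  ## dependency-order (as reconstructed) vs a valid alternative: swap the
  ## first two commands when they are independent (different inputs)
  h1 <- run_order(cmds)
  if (length(cmds) >= 3) {
    alt <- cmds
    args1 <- strsplit(cmds[1], " ")[[1]]; args2 <- strsplit(cmds[2], " ")[[1]]
    if (!any(gsub("'", "", args1) %in% gsub("'", "", args2))) {
      alt[c(1, 2)] <- alt[c(2, 1)]
      expect_identical(run_order(alt), h1)
    }
  }
  expect_identical(h1, rec$pipe$expected$checksum)
})

test_that("verify_environment reports exactly the altered executables", {
  rec <- recorded_pipeline(4, 2, seed = 15)
  withr::defer(unlink(rec$root, recursive = TRUE))
  ## identical environment: empty report
  expect_equal(nrow(verify_environment(rec$bundle, root = rec$root)), 0)
  ## swap one tool for a differently-checksummed build
  tools <- grep("bin/tool_", vapply(rec$bundle$processes, function(p) p$exe_path, ""),
                value = TRUE)
  victim <- unique(tools)[1]
  alt <- tempfile("altenv"); materialize_pipeline(rec$pipe, alt)
  withr::defer(unlink(alt, recursive = TRUE))
  cat("#!/bin/sh\n# different build\nexit 1\n", file = file.path(alt, victim))
  Sys.chmod(file.path(alt, victim), "755")
  mism <- verify_environment(rec$bundle, root = alt)
  expect_equal(mism$exe_path, victim)
  expect_equal(mism$status, "version_mismatch")
  ## absent tool: a missing_executable entry
  unlink(file.path(alt, victim))
  mism2 <- verify_environment(rec$bundle, root = alt)
  expect_true("missing_executable" %in%
                mism2$status[mism2$exe_path == victim])
})

test_that("replication in an identical environment is byte-faithful", {
  for (case in list(c(1, 1, 21), c(3, 2, 22), c(6, 3, 23))) {
    rec <- recorded_pipeline(case[1], case[2], seed = case[3])
    rep <- replicate_bundle(rec$bundle, tempfile("rep"), inputs_dir = rec$root)
    expect_true(rep$target_match,
                info = sprintf("stages=%d branching=%d", case[1], case[2]))
    expect_equal(nrow(rep$mismatches), 0)
    expect_true(all(rep$per_process$status == "ok"))
    expect_identical(rep$produced_checksum, rec$pipe$expected$checksum)
    unlink(c(rec$root, rep$workdir), recursive = TRUE)
  }
})

test_that("an output-altering substitute is flagged and fails the target check", {
  rec <- recorded_pipeline(4, 2, seed = 24)
  withr::defer(unlink(rec$root, recursive = TRUE))
  alt <- tempfile("tampered"); materialize_pipeline(rec$pipe, alt)
  withr::defer(unlink(alt, recursive = TRUE))
  used <- unique(grep("bin/tool_", vapply(rec$bundle$processes,
                                          function(p) p$exe_path, ""), value = TRUE))
  victim <- used[1]
  cat("#!/bin/sh\nLC_ALL=C sort -r \"$1\" > \"$2\"\n", file = file.path(alt, victim))
  if (grepl("merge", victim))
    cat("#!/bin/sh\no=\"$1\"; shift; cat \"$@\" | LC_ALL=C sort -r > \"$o\"\n",
        file = file.path(alt, victim))
  Sys.chmod(file.path(alt, victim), "755")
  rep <- replicate_bundle(rec$bundle, tempfile("reptam"), inputs_dir = alt)
  withr::defer(unlink(rep$workdir, recursive = TRUE))
  expect_false(rep$target_match)
  expect_true(victim %in% rep$mismatches$exe_path)
})

test_that("a behaviour-preserving rebuild matches output but keeps the version warning", {
  rec <- recorded_pipeline(2, 1, seed = 25)
  withr::defer(unlink(rec$root, recursive = TRUE))
  alt <- tempfile("rebuilt"); materialize_pipeline(rec$pipe, alt)
  withr::defer(unlink(alt, recursive = TRUE))
  used <- unique(grep("bin/tool_", vapply(rec$bundle$processes,
                                          function(p) p$exe_path, ""), value = TRUE))
  victim <- used[1]
  old <- readLines(file.path(alt, victim))
  writeLines(c(old, "# recompiled with different flags"), file.path(alt, victim))
  Sys.chmod(file.path(alt, victim), "755")
  rep <- replicate_bundle(rec$bundle, tempfile("repwrap"), inputs_dir = alt)
  withr::defer(unlink(rep$workdir, recursive = TRUE))
  expect_true(rep$target_match)
  expect_equal(rep$mismatches$exe_path, victim)
})

test_that("replication refuses to start without its external inputs", {
  rec <- recorded_pipeline(2, 1, seed = 26)
  withr::defer(unlink(rec$root, recursive = TRUE))
  empty <- withr::local_tempdir()
  expect_error(replicate_bundle(rec$bundle, tempfile("repmiss"), inputs_dir = empty),
               "external input missing")
})
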