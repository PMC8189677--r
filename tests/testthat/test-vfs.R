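fasta_cfg <- function() {
  default_config(list(vdf_spec("fastq2fasta", "\\.fastq$", ".fasta",
                               "awk 'NR % 4 == 1 || NR % 4 == 2' {source} | sed 's/^@/>/'")))
}

test_that("operations route to the VDF engine only for derivable virtual names", {
  root <- withr::local_tempdir()
  writeLines(c("@r", "ACGT", "+", "IIII"), file.path(root, "reads.fastq"))
  ctx <- mount_session(root, config = fasta_cfg())
  withr::defer(session_close(ctx))
  expect_identical(route_operation(syscall_event("open", "reads.fastq"), ctx), "real")
  expect_identical(route_operation(syscall_event("open", "reads.fastq.fasta"), ctx), "virtual")
  ## source absent: falls through to the real FS (which will report not-found)
  expect_identical(route_operation(syscall_event("open", "ghost.fastq.fasta"), ctx), "real")
  expect_error(route_operation(syscall_event("open", "../outside"), ctx), "escapes")
})

test_that("directory listings add one virtual entry per matching source, shadowed by real files", {
  root <- withr::local_tempdir()
  writeLines("x", file.path(root, "a.fastq"))
  writeLines("y", file.path(root, "b.txt"))
  ctx <- mount_session(root, config = fasta_cfg())
  withr::defer(session_close(ctx))
  expect_setequal(list_directory("", ctx), c("a.fastq", "a.fastq.fasta", "b.txt"))
  ## a real file with the virtual name shadows it; each name appears once
  writeLines("real", file.path(root, "a.fastq.fasta"))
  lst <- list_directory("", ctx)
  expect_equal(sum(lst == "a.fastq.fasta"), 1)
  expect_identical(route_operation(syscall_event("open", "a.fastq.fasta"), ctx), "real")
  ## empty directory
  dir.create(file.path(root, "sub"))
  expect_length(list_directory("sub", ctx), 0)
})

test_that("the mount is a faithful passthrough for data and metadata", {
  root <- withr::local_tempdir()
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  w <- sim_caller(501, "writer")
  payload <- as.raw(sample(0:255, 1024 * 1024, replace = TRUE))
  vfs_create(ctx, "blob.bin", caller = w)
  h <- vfs_open(ctx, "blob.bin", "w", caller = w)
  vfs_write(ctx, h, payload)
  vfs_close(ctx, h)
  ## byte-identical to direct access
  direct <- readBin(file.path(root, "blob.bin"), raw(), n = 2e6)
  expect_identical(direct, payload)
  h <- vfs_open(ctx, "blob.bin", "r", caller = w)
  expect_identical(vfs_read(ctx, h, Inf), payload)
  vfs_close(ctx, h)
  ## stat agrees with a direct stat
  s <- vfs_stat(ctx, "blob.bin")
  info <- file.info(file.path(root, "blob.bin"))
  expect_equal(s$size, info$size)
  expect_equal(s$mtime, as.numeric(info$mtime))
  ## unlink: gone through the mount and on disk
  vfs_unlink(ctx, "blob.bin", caller = w)
  expect_false(file.exists(file.path(root, "blob.bin")))
  expect_error(vfs_stat(ctx, "blob.bin"), "no such file")
})

test_that("every routed operation yields exactly one provenance record", {
  root <- withr::local_tempdir()
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  w <- sim_caller(502, "scripted")
  vfs_create(ctx, "a.txt", caller = w)                       # 1 create
  h <- vfs_open(ctx, "a.txt", "a", caller = w)               # 1 open
  vfs_write(ctx, h, "hello\n")                               # 1 write
  vfs_write(ctx, h, "world\n")                               # coalesces
  vfs_close(ctx, h)                                          # 1 close
  h <- vfs_open(ctx, "a.txt", "r", caller = w)               # 1 open
  vfs_read(ctx, h, Inf)                                      # 1 read
  vfs_close(ctx, h)                                          # 1 close
  vfs_rename(ctx, "a.txt", "b.txt", caller = w)              # 1 rename
  vfs_unlink(ctx, "b.txt", caller = w)                       # 1 unlink
  store_flush(ctx$store)
  ev <- DBI::dbGetQuery(ctx$store$con,
    "SELECT op_kind, COUNT(*) n, SUM(count) s FROM events GROUP BY op_kind")
  got <- stats::setNames(ev$s, ev$op_kind)
  expect_equal(got[["create"]], 1)
  expect_equal(got[["write"]], 2)   # two primitives, one coalesced row
  expect_equal(ev$n[ev$op_kind == "write"], 1)
  expect_equal(got[["read"]], 1)
  expect_equal(got[["rename"]], 1)
  expect_equal(got[["unlink"]], 1)
  expect_equal(got[["open"]], 2)
  expect_equal(got[["close"]], 2)
})

test_that("daemon-issued operations are excluded from provenance", {
  root <- withr::local_tempdir()
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  vfs_create(ctx, "self.txt")        # caller NULL = the session daemon
  h <- vfs_open(ctx, "self.txt", "a")
  vfs_write(ctx, h, "x")
  vfs_close(ctx, h)
  store_flush(ctx$store)
  n <- DBI::dbGetQuery(ctx$store$con, "SELECT COUNT(*) n FROM events")$n
  expect_equal(n, 0)
})

test_that("capture_caller reads identity from the live process table", {
  px <- processx::process$new("sleep", "5")
  withr::defer(px$kill())
  rec <- capture_caller(px$get_pid())
  expect_true(rec$available)
  expect_identical(basename(rec$exe_path), "sleep")
  expect_identical(rec$cmdline, c("sleep", "5"))
  ## checksum matches an independent hash of the binary
  expect_identical(rec$exe_checksum,
                   digest::digest(rec$exe_path, algo = "sha256", file = TRUE))
  rec2 <- capture_caller(px$get_pid())
  expect_identical(rec[c("pid", "start_time", "exe_path", "exe_checksum", "cmdline")],
                   rec2[c("pid", "start_time", "exe_path", "exe_checksum", "cmdline")])
  ## the daemon's own pid is flagged self
  expect_true(capture_caller(Sys.getpid())$is_self)
  ## a dead pid yields an unavailable record, never an error
  px$kill(); px$wait()
  Sys.sleep(0.1)
  dead <- capture_caller(px$get_pid())
  expect_s3_class(dead, "process_record")
})

test_that("write versioning: reopening after reads or a completed writer starts a new version", {
  root <- withr::local_tempdir()
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  w <- sim_caller(503, "vtest")
  vfs_create(ctx, "v.txt", caller = w)
  h <- vfs_open(ctx, "v.txt", "a", caller = w); vfs_write(ctx, h, "one"); vfs_close(ctx, h)
  k1 <- file_current(ctx$store, "v.txt")
  ## completed writer -> next open-for-write versions
  h <- vfs_open(ctx, "v.txt", "a", caller = w); vfs_write(ctx, h, "two"); vfs_close(ctx, h)
  k2 <- file_current(ctx$store, "v.txt")
  expect_true(k2 > k1)
  ## reads alone do not version
  h <- vfs_open(ctx, "v.txt", "r", caller = w); vfs_read(ctx, h, Inf); vfs_close(ctx, h)
  expect_identical(file_current(ctx$store, "v.txt"), k2)
  ## truncate always starts a new version
  vfs_truncate(ctx, "v.txt", 0, caller = w)
  expect_true(file_current(ctx$store, "v.txt") > k2)
  ## the superseded version keeps its recorded checksum
  chk <- provtrace:::store_get_file(ctx$store, k2)$content_checksum
  expect_match(chk, "^[0-9a-f]{64}$")
})

test_that("session_exec records identity, reads and writes of a real command", {
  root <- withr::local_tempdir()
  writeLines(c("pear", "apple", "quince"), file.path(root, "fruit.txt"))
  ctx <- mount_session(root)
  withr::defer(session_close(ctx))
  res <- session_exec(ctx, "sort", c("-o", "sorted.txt", "fruit.txt"),
                      outputs = "sorted.txt")
  expect_equal(res$status, 0)
  expect_equal(readLines(file.path(root, "sorted.txt")),
               c("apple", "pear", "quince"))
  pr <- provtrace:::store_get_process(ctx$store, res$proc_key)
  expect_identical(basename(pr$exe_path), "sort")
  expect_identical(pr$exe_checksum,
                   digest::digest(pr$exe_path, algo = "sha256", file = TRUE))
  ## the input was recorded as a read, the output as a write
  reads <- query_reads(ctx$store, res$proc_key, before = Inf)
  rp <- vapply(reads$file_key, function(k) provtrace:::store_get_file(ctx$store, k)$path, "")
  expect_true("fruit.txt" %in% rp)
  wk <- file_current(ctx$store, "sorted.txt")
  expect_equal(query_writes(ctx$store, wk)$proc_key, res$proc_key)
})
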