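local_vdf <- function(seed = 3, block_size = NULL, memory_limit = NULL,
                      env = parent.frame()) {
  fx <- gen_vdf_fixtures(tempfile("vdffx"), seed = seed)
  cfg <- fx$config
  if (!is.null(block_size)) cfg$cache$block_size <- block_size
  if (!is.null(memory_limit)) cfg$cache$memory_limit <- memory_limit
  ctx <- mount_session(fx$dir, config = cfg)
  withr::defer(
    { session_close(ctx); unlink(fx$dir, recursive = TRUE) }, envir = env)
  list(fx = fx, ctx = ctx)
}

read_virtual <- function(ctx, path, chunk = Inf) {
  h <- vfs_open(ctx, path, "r")
  on.exit(vfs_close(ctx, h))
  if (!is.finite(chunk)) return(vfs_read(ctx, h, Inf))
  out <- raw(0)
  repeat {
    piece <- vfs_read(ctx, h, chunk)
    if (!length(piece)) break
    out <- c(out, piece)
  }
  out
}

cache_of <- function(ctx, needle) {
  key <- grep(needle, ls(ctx$vdf_caches), value = TRUE, fixed = TRUE)
  stopifnot(length(key) == 1)
  ctx$vdf_caches[[key]]
}

test_that("virtual names resolve uniquely, including chained rules", {
  v <- local_vdf()
  ctx <- v$ctx
  res <- resolve_virtual(ctx, "reads_1.fastq.fasta")
  expect_equal(res$rule$name, "fastq2fasta")
  expect_equal(res$source, "reads_1.fastq")
  expect_false(res$source_virtual)
  expect_null(resolve_virtual(ctx, "reads_1.fasta"))     # no matching source
  expect_null(resolve_virtual(ctx, "nope.fastq.fasta"))
})

test_that("each rule's VDF bytes equal the direct command output", {
  v <- local_vdf()
  cases <- list(c("fastq2fasta", "reads_1.fastq", ".fasta"),
                c("fastq2fasta", "reads_2.fastq", ".fasta"),
                c("taxa", "abund.tsv", ".taxa"),
                c("sorted", "abund.tsv", ".sorted"))
  for (cs in cases) {
    got <- read_virtual(v$ctx, paste0(cs[2], cs[3]))
    expect_identical(got, v$fx$direct(cs[1], cs[2]),
                     info = paste(cs[1], "on", cs[2]))
  }
})

test_that("an empty source yields an existing, empty VDF", {
  v <- local_vdf()
  expect_identical(read_virtual(v$ctx, "empty.fastq.fasta"), raw(0))
  expect_true("empty.fastq.fasta" %in% list_directory("", v$ctx))
  s <- vfs_stat(v$ctx, "empty.fastq.fasta")
  expect_true(s$virtual)
})

test_that("reads past end-of-data return empty; the command runs exactly once", {
  v <- local_vdf()
  full <- read_virtual(v$ctx, "reads_1.fastq.fasta")
  ca <- cache_of(v$ctx, "reads_1")
  expect_identical(read_block(ca, 1000), raw(0))
  h <- vfs_open(v$ctx, "reads_1.fastq.fasta", "r")
  expect_identical(vfs_read(v$ctx, h, 10, offset = length(full) + 5), raw(0))
  vfs_close(v$ctx, h)
  expect_equal(ca$exec_count, 1L)
})

test_that("two interleaved readers see identical bytes from a single task", {
  v <- local_vdf()
  h1 <- vfs_open(v$ctx, "reads_2.fastq.fasta", "r")
  h2 <- vfs_open(v$ctx, "reads_2.fastq.fasta", "r")
  a <- raw(0); b <- raw(0)
  repeat {
    x <- vfs_read(v$ctx, h1, 16); y <- vfs_read(v$ctx, h2, 16)
    a <- c(a, x); b <- c(b, y)
    if (!length(x) && !length(y)) break
  }
  vfs_close(v$ctx, h1); vfs_close(v$ctx, h2)
  expect_identical(a, b)
  expect_identical(a, v$fx$direct("fastq2fasta", "reads_2.fastq"))
  expect_equal(cache_of(v$ctx, "reads_2")$exec_count, 1L)
})

test_that("a reader of a not-yet-produced block waits for the full block", {
  root <- withr::local_tempdir()
  writeLines("ignored", file.path(root, "slow.src"))
  cfg <- default_config(list(vdf_spec(
    "slow", "\\.src$", ".out",
    "printf aaaa; cat {source} > /dev/null; sleep 0.4; printf bbbb")))
  cfg$cache$block_size <- 8L
  ctx <- mount_session(root, config = cfg)
  withr::defer(session_close(ctx))
  t0 <- Sys.time()
  got <- read_virtual(ctx, "slow.src.out")
  expect_identical(rawToChar(got), "aaaabbbb")   # waited for the late half
  expect_gt(as.numeric(Sys.time() - t0), 0.3)
})

test_that("a failing task surfaces a read error", {
  root <- withr::local_tempdir()
  writeLines("x", file.path(root, "bad.src"))
  cfg <- default_config(list(vdf_spec("bad", "\\.src$", ".out",
                                      "cat {source}; exit 3")))
  ctx <- mount_session(root, config = cfg)
  withr::defer(session_close(ctx))
  h <- vfs_open(ctx, "bad.src.out", "r")
  expect_error(vfs_read(ctx, h, Inf), "status 3")
  vfs_close(ctx, h)
})

test_that("manual ingestion seals blocks exactly as streamed", {
  ca <- block_cache(block_size = 100, memory_limit = 1e6)
  payload <- as.raw(sample(0:255, 250, replace = TRUE))
  ingest_output(ca, payload[1:90])
  expect_length(ls(ca$mem), 0)                    # no complete block yet
  ingest_output(ca, payload[91:230])
  expect_setequal(ls(ca$mem), c("0", "1"))        # blocks 0,1 ready mid-stream
  ingest_output(ca, payload[231:250], final = TRUE)
  expect_equal(ca$final_length, 250)
  expect_identical(c(read_block(ca, 0), read_block(ca, 1), read_block(ca, 2)),
                   payload)
  expect_identical(read_block(ca, 3), raw(0))
  ## ready blocks never change
  before <- read_block(ca, 0)
  ingest_output(ca, raw(0), final = TRUE)
  expect_identical(read_block(ca, 0), before)
})

test_that("over-limit memory spills oldest blocks to disk and promotes on re-read", {
  v <- local_vdf(block_size = 64L, memory_limit = 128)
  got <- read_virtual(v$ctx, "reads_1.fastq.fasta")
  want <- v$fx$direct("fastq2fasta", "reads_1.fastq")
  expect_identical(got, want)
  ca <- cache_of(v$ctx, "reads_1")
  expect_gt(length(ls(ca$on_disk)), 0)            # spill actually happened
  expect_lte(provtrace:::mem_bytes(ca), 128)
  ## promote a spilled block back: content unchanged, occupancy still bounded
  spilled <- ls(ca$on_disk)[1]
  idx <- as.integer(spilled)
  blk <- read_block(ca, idx)
  expect_identical(blk, want[(idx * 64 + 1):min(length(want), (idx + 1) * 64)])
  expect_false(isTRUE(ca$on_disk[[spilled]]))
  expect_lte(provtrace:::mem_bytes(ca), 128)
})

test_that("copy-out matches direct output and reuses the materialisation", {
  v <- local_vdf()
  d1 <- withr::local_tempfile(); d2 <- withr::local_tempfile()
  vdf_copy_out(v$ctx, "abund.tsv.taxa", d1)
  vdf_copy_out(v$ctx, "abund.tsv.taxa", d2)
  want <- v$fx$direct("taxa", "abund.tsv")
  expect_identical(readBin(d1, raw(), file.size(d1)), want)
  expect_identical(readBin(d2, raw(), file.size(d2)), want)
  expect_equal(cache_of(v$ctx, "taxa|abund")$exec_count, 1L)
})

test_that("modifying the source triggers a fresh task over the new version", {
  v <- local_vdf()
  first <- read_virtual(v$ctx, "reads_1.fastq.fasta")
  w <- sim_caller(700, "editor")
  h <- vfs_open(v$ctx, "reads_1.fastq", "a", caller = w)
  vfs_write(v$ctx, h, "@extra\nGGGG\n+\nIIII\n")
  vfs_close(v$ctx, h)
  second <- read_virtual(v$ctx, "reads_1.fastq.fasta")
  expect_identical(second, v$fx$direct("fastq2fasta", "reads_1.fastq"))
  expect_false(identical(first, second))
  expect_match(rawToChar(second), ">extra")
})

test_that("chained rules materialise through their virtual source", {
  root <- withr::local_tempdir()
  writeLines(c("@r1", "acgtacgt", "+", "IIIIIIII"), file.path(root, "x.fastq"))
  cfg <- default_config(list(
    vdf_spec("f2a", "\\.fastq$", ".fasta",
             "awk 'NR % 4 == 1 || NR % 4 == 2' {source} | sed 's/^@/>/'"),
    vdf_spec("upper", "\\.fasta$", ".up", "tr 'a-z' 'A-Z' < {source}")))
  ctx <- mount_session(root, config = cfg)
  withr::defer(session_close(ctx))
  res <- resolve_virtual(ctx, "x.fastq.fasta.up")
  expect_true(res$source_virtual)
  expect_identical(rawToChar(read_virtual(ctx, "x.fastq.fasta.up")),
                   ">R1\nACGTACGT\n")
})

test_that("VDF reads and the generating task are traceable in provenance", {
  v <- local_vdf()
  w <- sim_caller(701, "consumer")
  h <- vfs_open(v$ctx, "reads_1.fastq.fasta", "r", caller = w)
  vfs_read(v$ctx, h, Inf)
  vfs_close(v$ctx, h)
  g <- trace_lineage(v$ctx$store, "reads_1.fastq.fasta")
  paths <- g$files$path
  expect_true("reads_1.fastq" %in% paths)      # lineage through the VDF
  expect_true(any(g$files$origin == "virtual"))
  expect_gte(nrow(g$procs), 1)
})
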