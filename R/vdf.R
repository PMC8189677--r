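## Virtual dynamic files: on-demand views materialised by configured shell
## commands and served through a two-tier (memory/disk) block cache.
##
## The generating command streams into a session-local spool file; the
## cache ingests completed blocks into the memory tier as they appear,
## spills the least-recently-used ready blocks to the disk tier when over
## the memory limit, and makes readers of not-yet-produced blocks wait
## until their block is ready, the task ends (end-of-data), or it fails.

#' Resolve a path to a virtual-dynamic-file rule
#'
#' A path is virtual when some rule's extension can be stripped to leave a
#' source name matching the rule's pattern, and that source exists -- as a
#' real file or, for chained rules, as a virtual file itself. Rules that
#' could claim the same virtual name are rejected at configuration load,
#' so resolution is unique.
#'
#' @param ctx A `mount_ctx`.
#' @param path Mount-relative path.
#' @param depth Chained-resolution limit.
#' @return `NULL`, or a list with `rule` (the `vdf_spec`), `source`
#'   (mount-relative source path) and `source_virtual` (logical).
#' @export
resolve_virtual <- function(ctx, path, depth = 3L) {
  if (depth <= 0L) return(NULL)
  rel <- rel_clean(path)
  for (rule in ctx$config$vdf_rules) {
    if (!endsWith(rel, rule$extension)) next
    src <- substr(rel, 1L, nchar(rel) - nchar(rule$extension))
    if (!nzchar(basename(src)) || !grepl(rule$source_pattern, basename(src))) next
    if (file.exists(real_path(ctx, src)) && !dir.exists(real_path(ctx, src)))
      return(list(rule = rule, source = src, source_virtual = FALSE))
    up <- resolve_virtual(ctx, src, depth - 1L)
    if (!is.null(up))
      return(list(rule = rule, source = src, source_virtual = TRUE))
  }
  NULL
}

vdf_cache_key <- function(ctx, res) {
  ver <- if (res$source_virtual) {
    up <- resolve_virtual(ctx, res$source)
    vdf_cache_key(ctx, up)           # chained: inherit the upstream identity
  } else {
    ensure_version(ctx, res$source)  # register so the version is stable
    ctx$store$cur_file[[res$source]][2]
  }
  paste(res$rule$name, res$source, ver, sep = "|")
}

#' Create a block cache
#'
#' Backing store for one VDF materialisation. Usually managed by the
#' session ([vfs_open()] on a virtual path), but usable standalone with
#' [ingest_output()] for direct testing.
#'
#' @param block_size Block size in bytes.
#' @param memory_limit Memory-tier capacity in bytes.
#' @param disk_dir Disk-tier directory (created on demand).
#' @param timeout Seconds a blocked read waits before erroring.
#' @return A `block_cache` (mutable environment).
#' @export
block_cache <- function(block_size = 131072L, memory_limit = 268435456,
                        disk_dir = tempfile("vdfdisk"), timeout = 120) {
  ca <- new.env(parent = emptyenv())
  ca$block_size <- as.integer(block_size)
  ca$memory_limit <- memory_limit
  ca$disk_dir <- disk_dir
  ca$timeout <- timeout
  ca$mem <- new.env(parent = emptyenv())     # block idx -> raw
  ca$on_disk <- new.env(parent = emptyenv()) # block idx -> TRUE
  ca$staging <- raw(0)                        # partial trailing block
  ca$bytes_produced <- 0
  ca$final_length <- NA_real_
  ca$task <- NULL
  ca$task_status <- "idle"                    # idle|running|done|failed
  ca$exec_count <- 0L
  ca$spool <- NULL
  ca$spool_read <- 0
  ca$access_seq <- 0
  ca$last_access <- new.env(parent = emptyenv())
  ca$produced_at <- new.env(parent = emptyenv())
  class(ca) <- "block_cache"
  ca
}

mem_bytes <- function(ca) {
  idx <- ls(ca$mem)
  if (!length(idx)) 0 else sum(vapply(idx, function(i) length(ca$mem[[i]]), numeric(1)))
}

touch_block <- function(ca, i) {
  ca$access_seq <- ca$access_seq + 1
  ca$last_access[[as.character(i)]] <- ca$access_seq
}

#' Feed task output into a block cache
#'
#' Appends `chunk` at the current production offset; every completed block
#' becomes ready in the memory tier (readers waiting on it are released on
#' their next poll). Call with `final = TRUE` once the producing task has
#' ended: the trailing partial block is sealed and the total length fixed.
#'
#' @param ca A `block_cache`.
#' @param chunk Raw vector (may be empty).
#' @param final Is production complete?
#' @export
ingest_output <- function(ca, chunk = raw(0), final = FALSE) {
  stopifnot(is.raw(chunk))
  ca$staging <- c(ca$staging, chunk)
  ca$bytes_produced <- ca$bytes_produced + length(chunk)
  bs <- ca$block_size
  while (length(ca$staging) >= bs) {
    i <- (ca$bytes_produced - length(ca$staging)) %/% bs
    place_block(ca, i, ca$staging[seq_len(bs)])
    ca$staging <- ca$staging[-seq_len(bs)]
  }
  if (final && is.na(ca$final_length)) {
    if (length(ca$staging)) {
      i <- (ca$bytes_produced - length(ca$staging)) %/% bs
      place_block(ca, i, ca$staging)
      ca$staging <- raw(0)
    }
    ca$final_length <- ca$bytes_produced
  }
  invisible(ca)
}

place_block <- function(ca, i, data) {
  k <- as.character(i)
  if (!is.null(ca$mem[[k]]) || isTRUE(ca$on_disk[[k]])) return(invisible(NULL))  # ready blocks never change
  ca$mem[[k]] <- data
  ca$access_seq <- ca$access_seq + 1
  ca$produced_at[[k]] <- ca$access_seq
  ca$last_access[[k]] <- ca$access_seq
  cache_evict(ca)
  invisible(NULL)
}

#' Spill over-limit memory blocks to the disk tier
#'
#' When memory-tier occupancy exceeds the limit, ready blocks are moved to
#' the disk tier oldest-first (least recently accessed, production order
#' as tie-break) until occupancy fits. Spilled blocks remain readable and
#' are promoted back on access. A no-op under the limit.
#'
#' @param ca A `block_cache`.
#' @return Character vector of spilled block indices, invisibly.
#' @export
cache_evict <- function(ca) {
  spilled <- character(0)
  while (mem_bytes(ca) > ca$memory_limit) {
    idx <- ls(ca$mem)
    if (length(idx) <= 1) break  # never evict the sole/most recent block mid-use
    ages <- vapply(idx, function(i)
      (ca$last_access[[i]] %||% 0) + (ca$produced_at[[i]] %||% 0) * 1e-9, numeric(1))
    victim <- idx[which.min(ages)]
    dir.create(ca$disk_dir, recursive = TRUE, showWarnings = FALSE)
    dest <- file.path(ca$disk_dir, paste0("block_", victim, ".bin"))
    ok <- tryCatch({ writeBin(ca$mem[[victim]], dest); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("disk tier write failed for block ", victim, call. = FALSE)
    ca$on_disk[[victim]] <- TRUE
    rm(list = victim, envir = ca$mem)
    spilled <- c(spilled, victim)
  }
  invisible(spilled)
}

## Pull newly spooled bytes (the producing command's output so far) into
## the cache.
pump_task <- function(ca) {
  if (is.null(ca$task) || ca$task_status != "running") return(invisible(NULL))
  sz <- file.size(ca$spool)
  if (is.na(sz)) sz <- 0
  if (sz > ca$spool_read) {
    con <- file(ca$spool, open = "rb")
    on.exit(close(con))
    seek(con, ca$spool_read)
    chunk <- readBin(con, raw(), n = sz - ca$spool_read)
    ca$spool_read <- ca$spool_read + length(chunk)
    ingest_output(ca, chunk)
  }
  if (!ca$task$is_alive()) {
    ca$task$wait()
    status <- ca$task$get_exit_status()
    ## drain any bytes written between the last poll and exit
    sz <- file.size(ca$spool); if (is.na(sz)) sz <- 0
    if (sz > ca$spool_read) {
      con2 <- file(ca$spool, open = "rb"); seek(con2, ca$spool_read)
      chunk <- readBin(con2, raw(), n = sz - ca$spool_read); close(con2)
      ca$spool_read <- ca$spool_read + length(chunk)
      ingest_output(ca, chunk)
    }
    if (status == 0) {
      ingest_output(ca, raw(0), final = TRUE)
      ca$task_status <- "done"
      if (!is.null(ca$on_done)) ca$on_done(ca)
    } else {
      ca$task_status <- "failed"
      ca$task_error <- paste0("VDF task exited with status ", status)
    }
  }
  invisible(NULL)
}

#' Read one block, blocking until it is ready
#'
#' Ready-in-memory blocks return immediately; disk-tier blocks are
#' promoted to memory first. A missing block launches the generating task
#' on first miss (exactly once per cache) and waits -- polling the task's
#' output stream -- until the block is produced or production ends. Reads
#' past the final length return an empty raw vector (end-of-data); a
#' failed task raises for every waiting reader.
#'
#' @param ca A `block_cache`.
#' @param i Block index (0-based).
#' @return Raw vector (full block, trailing partial block, or empty).
#' @export
read_block <- function(ca, i) {
  stopifnot(i >= 0)
  k <- as.character(i)
  deadline <- Sys.time() + ca$timeout
  repeat {
    if (!is.null(ca$mem[[k]])) { touch_block(ca, i); return(ca$mem[[k]]) }
    if (isTRUE(ca$on_disk[[k]])) {               # promote disk -> memory
      src <- file.path(ca$disk_dir, paste0("block_", k, ".bin"))
      data <- readBin(src, raw(), n = file.size(src))
      unlink(src)
      rm(list = k, envir = ca$on_disk)
      ca$mem[[k]] <- data
      touch_block(ca, i)
      cache_evict(ca)
      return(data)
    }
    if (ca$task_status == "failed") stop(ca$task_error, call. = FALSE)
    if (!is.na(ca$final_length)) {
      if (i * ca$block_size >= ca$final_length) return(raw(0))  # end-of-data
      ## block exists but was sealed into a tier we just missed; loop again
    }
    if (ca$task_status == "idle" && !is.null(ca$start_task)) ca$start_task(ca)
    pump_task(ca)
    if (ca$task_status %in% c("idle", "done") && is.na(ca$final_length) &&
        is.null(ca$task))
      ingest_output(ca, raw(0), final = TRUE)    # manual cache: EOF at current length
    if (Sys.time() > deadline) stop("timed out waiting for block ", i, call. = FALSE)
    Sys.sleep(0.002)
  }
}

## Byte-range read across blocks; n = Inf reads to end-of-data.
vdf_read_range <- function(ca, offset, n = Inf) {
  bs <- ca$block_size
  out <- list()
  pos <- offset
  got <- 0
  repeat {
    if (is.finite(n) && got >= n) break
    i <- pos %/% bs
    blk <- read_block(ca, i)
    if (length(blk) == 0) break
    off_in <- pos - i * bs
    if (off_in >= length(blk)) break              # inside trailing partial block
    piece <- blk[(off_in + 1):length(blk)]
    if (is.finite(n) && got + length(piece) > n) piece <- piece[seq_len(n - got)]
    out[[length(out) + 1L]] <- piece
    got <- got + length(piece)
    pos <- pos + length(piece)
    if (length(blk) < bs && !is.na(ca$final_length)) break
  }
  do.call(c, out) %||% raw(0)
}

cache_destroy <- function(ca) {
  if (!is.null(ca$task) && ca$task$is_alive()) ca$task$kill()
  if (!is.null(ca$spool)) unlink(ca$spool)
  unlink(ca$disk_dir, recursive = TRUE)
  invisible(NULL)
}

## -- Session integration -----------------------------------------------------

## Find or create the cache for a virtual path; keyed by (rule, source
## path, source version) so source modification triggers a fresh task.
vdf_cache_for <- function(ctx, path, proc_key = NULL) {
  rel <- rel_clean(path)
  res <- resolve_virtual(ctx, rel)
  if (is.null(res)) stop("not a virtual file: ", rel, call. = FALSE)
  key <- vdf_cache_key(ctx, res)
  hit <- ctx$vdf_caches[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- ctx$config$cache
  ca <- block_cache(block_size = cfg$block_size, memory_limit = cfg$memory_limit,
                    disk_dir = file.path(cfg$disk_tier %||% tempdir(),
                                         paste0("vdf-", gsub("[^A-Za-z0-9]", "_", key))))
  ca$ctx <- ctx
  ca$resolution <- res
  ca$vpath <- rel
  ca$vfile_key <- file_register(ctx$store, rel, origin = "virtual")
  ca$start_task <- vdf_start_task
  ca$on_done <- vdf_task_done
  ctx$vdf_caches[[key]] <- ca
  ca
}

## Launch the configured command over the (materialised) source; output is
## spooled to a temp file the cache polls. Runs exactly once per cache.
vdf_start_task <- function(ca) {
  ctx <- ca$ctx
  res <- ca$resolution
  src_real <- real_path(ctx, res$source)
  if (res$source_virtual) {
    ## chained rule: materialise the virtual source into a scratch file
    src_real <- tempfile("vdfsrc")
    up <- vdf_cache_for(ctx, res$source)
    writeBin(vdf_read_range(up, 0, Inf), src_real)
  }
  ca$spool <- tempfile("vdfspool")
  cmd <- gsub("{source}", shQuote(src_real), res$rule$command_template, fixed = TRUE)
  out_file <- if (res$rule$output_channel == "file") {
    of <- tempfile("vdfout")
    cmd <- gsub("{output}", shQuote(of), cmd, fixed = TRUE)
    of
  } else NULL
  ca$exec_count <- ca$exec_count + 1L
  ca$task_status <- "running"
  if (is.null(out_file)) {
    ca$task <- processx::process$new("sh", c("-c", cmd), stdout = ca$spool,
                                     stderr = "|", wd = ctx$source_root)
  } else {
    ## file-channel command: its output file is the spool we poll
    file.create(out_file)
    ca$spool <- out_file
    ca$task <- processx::process$new("sh", c("-c", cmd), stdout = "|",
                                     stderr = "|", wd = ctx$source_root)
  }
  ## provenance: the generating process reads the source, writes the VDF
  st <- ctx$store
  gen <- list(pid = ca$task$get_pid(), start_time = store_now(st),
              exe_path = unname(Sys.which("sh")),
              exe_checksum = file_checksum(unname(Sys.which("sh"))),
              checksum_algo = CHECKSUM_ALGO,
              cmdline = c("sh", "-c", cmd), cwd = ".", is_self = FALSE)
  ca$gen_key <- record_process(st, gen)
  if (!res$source_virtual) {
    sk <- ensure_version(ctx, res$source)
    record_event(st, ca$gen_key, sk, "read",
                 bytes = file.size(real_path(ctx, res$source)))
  }
  invisible(NULL)
}

vdf_task_done <- function(ca) {
  st <- ca$ctx$store
  record_event(st, ca$gen_key, ca$vfile_key, "write", bytes = ca$final_length)
  file_set_checksum(st, ca$vfile_key,
                    digest::digest(vdf_read_range(ca, 0, Inf),
                                   algo = CHECKSUM_ALGO, serialize = FALSE))
  invisible(NULL)
}

#' Copy a virtual dynamic file out of the mount
#'
#' Materialises the VDF (reusing the cache: the generating command runs at
#' most once per source version) and writes its complete content to
#' `destination`. The destination bytes equal the generating command's
#' direct output.
#'
#' @param ctx A `mount_ctx`.
#' @param path Mount-relative virtual path.
#' @param destination File path outside the mount.
#' @param caller Issuing process (see [vfs-ops]).
#' @return `destination`, invisibly.
#' @export
vdf_copy_out <- function(ctx, path, destination, caller = NULL) {
  h <- vfs_open(ctx, path, "r", caller = caller)
  on.exit(vfs_close(ctx, h))
  data <- vfs_read(ctx, h, Inf)
  writeBin(data, destination)
  invisible(destination)
}
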