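## Interception layer: a monitored session over a real directory tree.
##
## The operation interface below is the internal seam between the
## provenance/VDF core and a mount backend: every file operation enters as
## a SyscallEvent, is recorded, then routed to the real file system or to
## the VDF engine. Tests and `session_exec()` drive this interface
## directly, so the full core is exercised without a privileged kernel
## mount.

#' Open a monitored session over a directory tree
#'
#' @param source_root Existing directory to monitor; all recorded paths are
#'   relative to it.
#' @param mount_point Label for where the mirrored tree is presented; must
#'   differ from `source_root`. Defaults to `<source_root>.view`.
#' @param config A `provtrace_config` (see [default_config()],
#'   [parse_config()]).
#' @param db_path Location of the session's provenance database; defaults
#'   to a file under the session temp directory (kept outside the
#'   monitored tree so the store never records itself).
#' @return A `mount_ctx` object.
#' @export
mount_session <- function(source_root, mount_point = NULL,
                          config = default_config(), db_path = NULL) {
  if (!dir.exists(source_root)) stop("source_root is not a directory: ", source_root, call. = FALSE)
  source_root <- normalizePath(source_root)
  mount_point <- mount_point %||% paste0(source_root, ".view")
  if (identical(normalizePath(mount_point, mustWork = FALSE), source_root))
    stop("mount_point must differ from source_root", call. = FALSE)
  session_id <- new_session_id()
  db_path <- db_path %||% config$store$db_path %||%
    file.path(tempdir(), paste0("provtrace-", session_id, ".db"))
  ctx <- new.env(parent = emptyenv())
  ctx$source_root <- source_root
  ctx$mount_point <- mount_point
  ctx$config <- config
  ctx$session_id <- session_id
  ctx$store <- prov_store(db_path, session_id = session_id, source_root = source_root,
                          config = config, flush_threshold = config$store$flush_threshold)
  ctx$deleted <- new.env(parent = emptyenv())     # paths unlinked since last version
  ctx$open_writers <- new.env(parent = emptyenv())# file_key -> open write handle count
  ctx$vdf_caches <- new.env(parent = emptyenv())  # rule|path|version -> block_cache
  ctx$handle_seq <- 0L
  class(ctx) <- "mount_ctx"
  ## the daemon itself: recorded once, flagged self, excluded from events
  self <- capture_caller(Sys.getpid())
  self$is_self <- TRUE
  ctx$self_key <- record_process(ctx$store, self)
  pt_log(ctx, "session opened over ", source_root)
  ctx
}

#' @rdname mount_session
#' @export
session_close <- function(ctx) {
  store_close(ctx$store)
  for (k in ls(ctx$vdf_caches)) cache_destroy(ctx$vdf_caches[[k]])
  pt_log(ctx, "session closed")
  invisible(NULL)
}

real_path <- function(ctx, rel) {
  rel <- rel_clean(rel)
  if (rel == "") ctx$source_root else file.path(ctx$source_root, rel)
}

#' Construct a file-system operation event
#'
#' @param op_kind One of open, read, write, close, create, unlink, rename,
#'   truncate, stat, readdir.
#' @param path Mount-relative path.
#' @param caller_pid Issuing process id.
#' @param timestamp Event time (monotonic; defaults to now).
#' @param offset,length Byte range, for read/write only.
#' @return A `syscall_event`.
#' @export
syscall_event <- function(op_kind, path, caller_pid = Sys.getpid(),
                          timestamp = as.numeric(Sys.time()),
                          offset = NULL, length = NULL) {
  kinds <- c("open", "read", "write", "close", "create", "unlink", "rename",
             "truncate", "stat", "readdir")
  if (!op_kind %in% kinds) stop("unknown op_kind: ", op_kind, call. = FALSE)
  if (op_kind %in% c("read", "write") && (is.null(offset) || is.null(length)))
    stop("read/write events carry a byte range", call. = FALSE)
  if (!op_kind %in% c("read", "write") && !(is.null(offset) && is.null(length)))
    stop("byte range only applies to read/write", call. = FALSE)
  structure(list(op_kind = op_kind, path = path, caller_pid = caller_pid,
                 timestamp = timestamp, offset = offset, length = length),
            class = "syscall_event")
}

#' Route an operation to the real file system or the VDF engine
#'
#' An operation is virtual iff its path names a registered virtual dynamic
#' file derived from an existing source; a real file with the same name
#' shadows the virtual one. Everything else is relayed to the underlying
#' tree.
#'
#' @param ev A `syscall_event`.
#' @param ctx A `mount_ctx`.
#' @return `"real"` or `"virtual"`.
#' @export
route_operation <- function(ev, ctx) {
  rel <- rel_clean(ev$path)
  if (file.exists(real_path(ctx, rel))) return("real")
  if (!is.null(resolve_virtual(ctx, rel))) return("virtual")
  "real"
}

#' Inspect the identity of a calling process
#'
#' Reads the live process's command line, working directory, parent pid,
#' start time and executable path from the OS process table, and checksums
#' the executable. Fields that cannot be read (e.g. the process exited
#' between the call and inspection) are recorded as unavailable rather than
#' raising; repeated calls for the same live process return identical
#' records.
#'
#' @param pid A process id.
#' @return A `process_record` list: pid, parent_pid, start_time, exe_path,
#'   exe_checksum, checksum_algo, cmdline, cwd, is_self, available.
#' @export
capture_caller <- function(pid) {
  grab <- function(expr) tryCatch(expr, error = function(e) NULL)
  h <- grab(ps::ps_handle(as.integer(pid)))
  if (is.null(h)) {
    return(structure(list(pid = as.integer(pid), parent_pid = NA_integer_,
                          start_time = NA_real_, exe_path = NA_character_,
                          exe_checksum = NA_character_, checksum_algo = CHECKSUM_ALGO,
                          cmdline = character(0), cwd = NA_character_,
                          is_self = pid == Sys.getpid(), available = FALSE),
                     class = "process_record"))
  }
  exe <- grab(ps::ps_exe(h)) %||% NA_character_
  structure(list(
    pid = as.integer(pid),
    parent_pid = grab(ps::ps_ppid(h)) %||% NA_integer_,
    start_time = as.numeric(grab(ps::ps_create_time(h)) %||% NA_real_),
    exe_path = exe,
    exe_checksum = if (is.na(exe)) NA_character_ else file_checksum(exe),
    checksum_algo = CHECKSUM_ALGO,
    cmdline = grab(ps::ps_cmdline(h)) %||% character(0),
    cwd = grab(ps::ps_cwd(h)) %||% NA_character_,
    is_self = pid == Sys.getpid(),
    available = TRUE), class = "process_record")
}

## Resolve the caller argument of an operation to a proc_key.
## NULL means the daemon itself (recorded as self, excluded from events).
resolve_caller <- function(ctx, caller) {
  if (is.null(caller)) return(ctx$self_key)
  if (inherits(caller, "process_record")) return(record_process(ctx$store, caller))
  if (is.numeric(caller)) return(caller)
  stop("caller must be NULL, a process_record, or a proc_key", call. = FALSE)
}

caller_is_self <- function(ctx, proc_key) identical(proc_key, ctx$self_key)

## Current version of a path as seen through the mount (NULL after unlink).
live_file_key <- function(ctx, path) {
  if (isTRUE(ctx$deleted[[path]])) return(NULL)
  file_current(ctx$store, path)
}

## Register (or version) a path ahead of an operation. Versioning policy:
## create/truncate always starts a new version; open-for-write starts one
## when the previous version was already read or had a completed writer, so
## read edges keep pointing at the content actually read.
ensure_version <- function(ctx, path, for_write = FALSE, force_new = FALSE,
                           origin = "internal") {
  st <- ctx$store
  key <- live_file_key(ctx, path)
  if (is.null(key)) {
    key <- file_register(st, path, origin = if (for_write || force_new) origin else "external")
    if (exists(path, envir = ctx$deleted)) rm(list = path, envir = ctx$deleted)
    return(key)
  }
  if (force_new ||
      (for_write && (isTRUE(st$has_reads[[as.character(key)]]) ||
                     isTRUE(st$writer_done[[as.character(key)]])))) {
    key <- file_register(st, path, origin = origin)
  }
  key
}

record_op <- function(ctx, proc_key, file_key, op_kind, bytes = 0) {
  if (caller_is_self(ctx, proc_key)) return(invisible(NULL))
  record_event(ctx$store, proc_key, file_key, op_kind, bytes = bytes)
}

#' Passthrough file operations on a monitored session
#'
#' These operations form the session's POSIX-like surface: each records
#' exactly one provenance submission for the issuing caller and then acts
#' on the underlying tree (or the VDF engine, for virtual paths), returning
#' results identical to direct access. `caller` is a `process_record` (or a
#' proc_key) identifying the issuing process; `NULL` means the session
#' daemon itself, whose operations are excluded from provenance.
#'
#' @param ctx A `mount_ctx`.
#' @param path,from,to Mount-relative paths.
#' @param mode `"r"` (read), `"w"` (write/overwrite) or `"a"` (append).
#' @param caller Issuing process (see above).
#' @return `vfs_open()` returns a handle for [vfs_read()]/[vfs_write()];
#'   `vfs_stat()` a list (size, mtime, is_dir, virtual); `vfs_readdir()` a
#'   character vector of entry names.
#' @name vfs-ops
NULL

#' @rdname vfs-ops
#' @export
vfs_create <- function(ctx, path, caller = NULL) {
  rel <- rel_clean(path)
  pk <- resolve_caller(ctx, caller)
  key <- ensure_version(ctx, rel, force_new = TRUE, origin = "internal")
  record_op(ctx, pk, key, "create")
  rp <- real_path(ctx, rel)
  dir.create(dirname(rp), recursive = TRUE, showWarnings = FALSE)
  if (!file.create(rp)) stop("cannot create ", rel, call. = FALSE)
  invisible(key)
}

#' @rdname vfs-ops
#' @export
vfs_open <- function(ctx, path, mode = c("r", "w", "a"), caller = NULL) {
  mode <- match.arg(mode)
  rel <- rel_clean(path)
  pk <- resolve_caller(ctx, caller)
  ev <- syscall_event("open", rel, timestamp = store_now(ctx$store))
  routing <- route_operation(ev, ctx)
  h <- new.env(parent = emptyenv())
  h$path <- rel; h$mode <- mode; h$proc_key <- pk; h$ctx <- ctx
  if (routing == "virtual") {
    if (mode != "r") stop("virtual dynamic files are read-only: ", rel, call. = FALSE)
    h$virtual <- TRUE
    h$cache <- vdf_cache_for(ctx, rel, proc_key = pk)
    h$pos <- 0
    key <- h$cache$vfile_key
    record_op(ctx, pk, key, "open")
  } else {
    rp <- real_path(ctx, rel)
    if (mode == "r" && !file.exists(rp)) stop("no such file: ", rel, call. = FALSE)
    key <- ensure_version(ctx, rel, for_write = mode != "r")
    record_op(ctx, pk, key, "open")
    h$virtual <- FALSE
    if (mode != "r" && !file.exists(rp)) file.create(rp)
    h$con <- switch(mode,
                    r = file(rp, open = "rb"),
                    w = file(rp, open = "r+b"),
                    a = file(rp, open = "ab"))
    if (mode == "w") { truncate(h$con) }
    ck <- as.character(key)
    if (mode != "r")
      ctx$open_writers[[ck]] <- (ctx$open_writers[[ck]] %||% 0L) + 1L
  }
  h$file_key <- key
  h$closed <- FALSE
  class(h) <- "vfs_handle"
  h
}

#' @rdname vfs-ops
#' @param h A handle from [vfs_open()].
#' @param n Bytes to read (`Inf` = to end of file).
#' @param offset Byte offset; `NULL` reads/writes at the current position.
#' @export
vfs_read <- function(ctx, h, n = Inf, offset = NULL) {
  stopifnot(!h$closed)
  if (h$virtual) {
    if (!is.null(offset)) h$pos <- offset
    out <- vdf_read_range(h$cache, h$pos, n)
    h$pos <- h$pos + length(out)
  } else {
    if (!is.null(offset)) seek(h$con, offset)
    sz <- file.size(real_path(ctx, h$path))
    want <- if (is.finite(n)) n else max(0, sz - seek(h$con))
    out <- readBin(h$con, raw(), n = want)
  }
  record_op(ctx, h$proc_key, h$file_key, "read", bytes = length(out))
  out
}

#' @rdname vfs-ops
#' @param data A raw vector or a character scalar to write.
#' @export
vfs_write <- function(ctx, h, data, offset = NULL) {
  stopifnot(!h$closed)
  if (h$virtual) stop("virtual dynamic files are read-only", call. = FALSE)
  if (h$mode == "r") stop("handle not open for writing", call. = FALSE)
  if (is.character(data)) data <- charToRaw(paste0(data, collapse = ""))
  if (!is.null(offset)) seek(h$con, offset, rw = "write")
  writeBin(data, h$con)
  record_op(ctx, h$proc_key, h$file_key, "write", bytes = length(data))
  invisible(length(data))
}

#' @rdname vfs-ops
#' @export
vfs_close <- function(ctx, h) {
  if (h$closed) return(invisible(NULL))
  record_op(ctx, h$proc_key, h$file_key, "close")
  if (!h$virtual) {
    close(h$con)
    if (h$mode != "r") {
      ck <- as.character(h$file_key)
      ctx$open_writers[[ck]] <- max(0L, (ctx$open_writers[[ck]] %||% 1L) - 1L)
      ctx$store$writer_done[[ck]] <- TRUE
      if (ctx$open_writers[[ck]] == 0L)  # last writer closed: content fixed
        file_set_checksum(ctx$store, h$file_key, file_checksum(real_path(ctx, h$path)))
    }
  }
  h$closed <- TRUE
  invisible(NULL)
}

#' @rdname vfs-ops
#' @export
vfs_unlink <- function(ctx, path, caller = NULL) {
  rel <- rel_clean(path)
  pk <- resolve_caller(ctx, caller)
  rp <- real_path(ctx, rel)
  if (!file.exists(rp)) stop("no such file: ", rel, call. = FALSE)
  key <- ensure_version(ctx, rel)
  record_op(ctx, pk, key, "unlink")
  unlink(rp)
  ctx$deleted[[rel]] <- TRUE
  invisible(NULL)
}

#' @rdname vfs-ops
#' @export
vfs_rename <- function(ctx, from, to, caller = NULL) {
  from <- rel_clean(from); to <- rel_clean(to)
  pk <- resolve_caller(ctx, caller)
  if (!file.exists(real_path(ctx, from))) stop("no such file: ", from, call. = FALSE)
  key <- ensure_version(ctx, from)
  record_op(ctx, pk, key, "rename")
  ## rename transfers identity: versions keep their keys under the new path
  st <- ctx$store
  dest_cur <- st$cur_file[[to]]
  shift <- if (is.null(dest_cur)) 0L else dest_cur[2] + 1L
  if (shift > 0L)
    DBI::dbExecute(st$con,
      "UPDATE files SET version_no = version_no + ? WHERE path = ? AND session_id = ?",
      params = list(shift, from, st$session_id))
  src_cur <- st$cur_file[[from]]
  file_transfer(st, from, to)
  if (shift > 0L && !is.null(src_cur)) st$cur_file[[to]] <- c(src_cur[1], src_cur[2] + shift)
  if (exists(to, envir = ctx$deleted)) rm(list = to, envir = ctx$deleted)
  ctx$deleted[[from]] <- TRUE
  dir.create(dirname(real_path(ctx, to)), recursive = TRUE, showWarnings = FALSE)
  file.rename(real_path(ctx, from), real_path(ctx, to))
  invisible(NULL)
}

#' @rdname vfs-ops
#' @param size New length in bytes.
#' @export
vfs_truncate <- function(ctx, path, size = 0, caller = NULL) {
  rel <- rel_clean(path)
  pk <- resolve_caller(ctx, caller)
  rp <- real_path(ctx, rel)
  if (!file.exists(rp)) stop("no such file: ", rel, call. = FALSE)
  key <- ensure_version(ctx, rel, force_new = TRUE, origin = "internal")
  record_op(ctx, pk, key, "truncate")
  keep <- readBin(rp, raw(), n = size)
  writeBin(keep, rp)
  invisible(key)
}

#' @rdname vfs-ops
#' @export
vfs_stat <- function(ctx, path, caller = NULL) {
  rel <- rel_clean(path)
  rp <- real_path(ctx, rel)
  if (file.exists(rp)) {
    info <- file.info(rp)
    return(list(size = info$size[1], mtime = as.numeric(info$mtime[1]),
                is_dir = info$isdir[1], virtual = FALSE))
  }
  res <- resolve_virtual(ctx, rel)
  if (!is.null(res)) {
    cache <- ctx$vdf_caches[[vdf_cache_key(ctx, res)]]
    ## an unmaterialised VDF reports the bytes produced so far (0 before
    ## the first read); consumers detect end-of-data via short reads
    size <- if (is.null(cache)) 0 else cache$bytes_produced
    return(list(size = size, mtime = as.numeric(Sys.time()), is_dir = FALSE,
                virtual = TRUE))
  }
  stop("no such file: ", rel, call. = FALSE)
}

#' @rdname vfs-ops
#' @export
vfs_readdir <- function(ctx, path = "", caller = NULL) {
  list_directory(path, ctx)
}

#' List a directory through the mount
#'
#' Returns the underlying entries plus one virtual entry per (real or
#' chained virtual) file matching a VDF rule's source pattern, named
#' `<source><extension>`. A real file with the same name as a virtual entry
#' shadows it; each name appears once.
#'
#' @param path Mount-relative directory path (`""` for the root).
#' @param ctx A `mount_ctx`.
#' @return Sorted character vector of entry names.
#' @export
list_directory <- function(path, ctx) {
  rel <- rel_clean(path)
  rp <- real_path(ctx, rel)
  if (!dir.exists(rp)) stop("not a directory: ", rel, call. = FALSE)
  entries <- list.files(rp, all.files = FALSE, no.. = TRUE)
  ## add virtual names, iterating so VDF-of-VDF chains appear too
  all <- entries
  for (depth in 1:3) {
    added <- character(0)
    for (rule in ctx$config$vdf_rules) {
      src <- all[grepl(rule$source_pattern, all)]
      if (!length(src)) next
      added <- c(added, setdiff(paste0(src, rule$extension), all))
    }
    if (length(added) == 0) break
    all <- c(all, added)
  }
  sort(unique(all))
}

## -- Monitored execution of real commands -----------------------------------

#' Run a real command under the session, recording its provenance
#'
#' Executes `command args...` as a child process and records it as a
#' provenance event stream: a process record with the live pid, resolved
#' executable path and executable checksum; read events for its inputs;
#' write events (and content checksums) for its outputs. Inputs are the
#' declared `inputs` plus any argument token that resolves to an existing
#' file under the tree; outputs are the declared `outputs` plus files
#' created or modified during execution (detected by a tree snapshot
#' diff). Paths under the tree are recorded mount-relative so exported
#' bundles stay relocatable.
#'
#' @param ctx A `mount_ctx`.
#' @param command Executable: a path under the tree (recorded relative,
#'   checksummed) or a program name resolved on the search path.
#' @param args Character vector of arguments.
#' @param inputs,outputs Mount-relative paths to record as reads/writes in
#'   addition to what is auto-detected.
#' @param stdout_to Optional mount-relative path; the child's standard
#'   output is captured there and recorded as an output.
#' @param parent Optional proc_key of a driver process (records a spawn
#'   link).
#' @param env Extra environment variables (`c(NAME = "value")`).
#' @return List with `proc_key`, `status` (exit code), `outputs`
#'   (mount-relative paths written).
#' @export
session_exec <- function(ctx, command, args = character(0), inputs = NULL,
                         outputs = NULL, stdout_to = NULL, parent = NULL,
                         env = character(0)) {
  st <- ctx$store
  root <- ctx$source_root
  to_rel <- function(p) {
    ap <- normalizePath(p, mustWork = FALSE)
    if (startsWith(ap, paste0(root, "/"))) substring(ap, nchar(root) + 2L) else NULL
  }
  ## resolve the executable
  in_tree <- grepl("/", command) && file.exists(file.path(root, rel_clean(command)))
  if (in_tree) {
    exe_rel <- rel_clean(command)
    exe_abs <- file.path(root, exe_rel)
    exe_rec <- exe_rel
  } else {
    exe_abs <- if (file.exists(command)) normalizePath(command) else Sys.which(command)
    if (!nzchar(exe_abs)) stop("executable not found: ", command, call. = FALSE)
    exe_rec <- exe_abs
  }
  ## detect input files among argument tokens
  tok_inputs <- character(0)
  for (a in args) {
    cand <- file.path(root, a)
    if (!grepl("^/", a) && file.exists(cand) && !dir.exists(cand)) tok_inputs <- c(tok_inputs, a)
  }
  reads <- unique(c(vapply(inputs %||% character(0), rel_clean, ""), tok_inputs,
                    if (in_tree) exe_rel))  # a process reads its own executable
  snap <- tree_snapshot(root)
  full_env <- c(Sys.getenv(), "LC_ALL" = "C", env)
  px <- processx::process$new(exe_abs, args, wd = root,
                              stdout = if (is.null(stdout_to)) "|" else
                                file.path(root, rel_clean(stdout_to)),
                              stderr = "|",
                              env = full_env)
  start_time <- store_now(st)
  rec <- list(pid = px$get_pid(), start_time = start_time,
              parent_key = parent, exe_path = exe_rec,
              exe_checksum = file_checksum(exe_abs), checksum_algo = CHECKSUM_ALGO,
              cmdline = c(exe_rec, args), cwd = ".", is_self = FALSE)
  pk <- record_process(st, rec)
  sz <- function(p) { s <- file.size(p); if (is.na(s)) 0 else s }
  for (r in reads) {
    fk <- ensure_version(ctx, r)
    record_event(st, pk, fk, "read", bytes = sz(file.path(root, r)))
  }
  px$wait()
  status <- px$get_exit_status()
  if (is.null(stdout_to)) invisible(tryCatch(px$read_all_output(), error = function(e) ""))
  errtxt <- tryCatch(px$read_all_error(), error = function(e) "")
  if (status != 0)
    pt_log(ctx, level = "warn", "command failed (", status, "): ", command, " -- ", errtxt)
  changed <- tree_diff(snap, tree_snapshot(root))
  written <- unique(c(vapply(outputs %||% character(0), rel_clean, ""),
                      if (!is.null(stdout_to)) rel_clean(stdout_to), changed))
  written <- setdiff(written, reads)
  for (w in written) {
    fk <- ensure_version(ctx, w, for_write = TRUE)
    record_event(st, pk, fk, "write", bytes = sz(file.path(root, w)))
    ctx$store$writer_done[[as.character(fk)]] <- TRUE
    file_set_checksum(st, fk, file_checksum(file.path(root, w)))
  }
  list(proc_key = pk, status = status, outputs = written)
}

tree_snapshot <- function(root) {
  fs <- list.files(root, recursive = TRUE, all.files = TRUE, no.. = TRUE)
  info <- file.info(file.path(root, fs))
  data.frame(path = fs, size = info$size, mtime = as.numeric(info$mtime),
             stringsAsFactors = FALSE)
}

tree_diff <- function(before, after) {
  m <- merge(after, before, by = "path", all.x = TRUE, suffixes = c("", ".old"))
  new_or_changed <- is.na(m$size.old) | m$size != m$size.old | m$mtime > m$mtime.old
  m$path[new_or_changed]
}
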