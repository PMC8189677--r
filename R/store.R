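## Embedded SQL provenance store.
##
## Three tables -- processes, files (one row per file *version*), events --
## plus a session table. High-throughput primitive reads/writes are
## coalesced in memory and flushed to the database in batches; the two
## lineage queries (query_writes / query_reads) run in SQL.

SCHEMA_VERSION <- 1L

#' Open a provenance store
#'
#' One store backs one mount session. Primitive operations are buffered and
#' coalesced in memory; the buffer is flushed to the database when it
#' exceeds `flush_threshold` events, on [store_flush()], on any query, and
#' at [store_close()].
#'
#' @param db_path SQLite database file, or `":memory:"`.
#' @param session_id Session identifier; generated when omitted. Reopening
#'   an existing database file resumes its recorded sessions' data.
#' @param source_root Absolute path of the monitored tree (metadata).
#' @param config Config snapshot stored with the session.
#' @param flush_threshold Buffered-event count that triggers an automatic
#'   flush.
#' @return A `prov_store` object (mutable environment).
#' @export
prov_store <- function(db_path = ":memory:", session_id = new_session_id(),
                       source_root = NA_character_, config = NULL,
                       flush_threshold = 10000L) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  st <- new.env(parent = emptyenv())
  st$con <- con
  st$db_path <- db_path
  st$session_id <- session_id
  st$flush_threshold <- as.integer(flush_threshold)
  st$clock <- as.numeric(Sys.time())
  st$open_ev <- new.env(parent = emptyenv())   # (proc|file) -> pending coalesced event
  st$done_ev <- list()                          # completed, not yet persisted
  st$n_buffered <- 0L
  st$proc_keys <- new.env(parent = emptyenv())  # "pid@start" -> proc_key
  st$cur_file <- new.env(parent = emptyenv())   # path -> c(file_key, version_no)
  st$has_reads <- new.env(parent = emptyenv())  # file_key -> TRUE once read
  st$writer_done <- new.env(parent = emptyenv())# file_key -> TRUE after a writer closed
  st$closed <- FALSE
  class(st) <- "prov_store"
  store_init_schema(st)
  DBI::dbExecute(con,
    "INSERT INTO sessions (session_id, source_root, config_json, schema_version, created) VALUES (?,?,?,?,?)",
    params = list(session_id, source_root,
                  if (is.null(config)) NA_character_ else
                    as.character(jsonlite::toJSON(config_as_list(config),
                                                  auto_unbox = TRUE, null = "null")),
                  SCHEMA_VERSION, st$clock))
  store_load_state(st)
  st
}

store_init_schema <- function(st) {
  stmts <- c(
    "CREATE TABLE IF NOT EXISTS sessions (
       session_id TEXT, source_root TEXT, config_json TEXT,
       schema_version INTEGER, created REAL)",
    "CREATE TABLE IF NOT EXISTS processes (
       proc_key INTEGER PRIMARY KEY, session_id TEXT, pid INTEGER,
       start_time REAL, parent_key INTEGER, exe_path TEXT, exe_checksum TEXT,
       checksum_algo TEXT, cmdline TEXT, cwd TEXT, is_self INTEGER,
       UNIQUE (session_id, pid, start_time))",
    "CREATE TABLE IF NOT EXISTS files (
       file_key INTEGER PRIMARY KEY, session_id TEXT, path TEXT,
       version_no INTEGER, created_time REAL, content_checksum TEXT,
       origin TEXT, UNIQUE (session_id, path, version_no))",
    "CREATE TABLE IF NOT EXISTS events (
       event_key INTEGER PRIMARY KEY, proc_key INTEGER, file_key INTEGER,
       op_kind TEXT, t_first REAL, t_last REAL, count INTEGER, bytes REAL)",
    "CREATE INDEX IF NOT EXISTS idx_events_file ON events (file_key, op_kind, t_first)",
    "CREATE INDEX IF NOT EXISTS idx_events_proc ON events (proc_key, op_kind, t_first)")
  for (s in stmts) DBI::dbExecute(st$con, s)
}

store_load_state <- function(st) {
  cur <- DBI::dbGetQuery(st$con,
    "SELECT path, file_key, MAX(version_no) AS version_no FROM files GROUP BY path")
  if (nrow(cur)) for (i in seq_len(nrow(cur)))
    assign(cur$path[i], c(cur$file_key[i], cur$version_no[i]), envir = st$cur_file)
  pr <- DBI::dbGetQuery(st$con, "SELECT proc_key, pid, start_time FROM processes")
  if (nrow(pr)) for (i in seq_len(nrow(pr)))
    assign(sprintf("%d@%.6f", pr$pid[i], pr$start_time[i]), pr$proc_key[i],
           envir = st$proc_keys)
}

#' Monotonic store clock
#'
#' All timestamps in one store come from a single monotonic clock so the
#' temporal-correctness constraint is well defined across interleaved
#' recorders. Sub-millisecond resolution; strictly increasing.
#'
#' @param st A `prov_store`.
#' @return Numeric timestamp (seconds).
#' @export
store_now <- function(st) {
  st$clock <- max(st$clock + 1e-6, as.numeric(Sys.time()))
  st$clock
}

store_advance <- function(st, t) {
  if (!is.null(t) && is.finite(t)) st$clock <- max(st$clock, t)
}

#' Record (or look up) a process
#'
#' Idempotent on the natural key (pid, start time, session): re-recording a
#' live process returns its existing key, while a pid reused by the OS
#' after exit gets a fresh record because its start time differs.
#'
#' @param st A `prov_store`.
#' @param rec A `process_record` (see [capture_caller()]), or a list with at
#'   least `pid` and `start_time`; optional `parent_key`, `exe_path`,
#'   `exe_checksum`, `cmdline` (character vector), `cwd`, `is_self`.
#' @return Integer `proc_key`.
#' @export
record_process <- function(st, rec) {
  stopifnot(!st$closed)
  pid <- as.integer(rec$pid)
  start_time <- as.numeric(rec$start_time %||% store_now(st))
  nk <- sprintf("%d@%.6f", pid, start_time)
  if (!is.null(st$proc_keys[[nk]])) return(st$proc_keys[[nk]])
  parent_key <- rec$parent_key
  if (is.null(parent_key) && !is.null(rec$parent_pid)) {
    hit <- DBI::dbGetQuery(st$con,
      "SELECT proc_key FROM processes WHERE pid = ? ORDER BY start_time DESC LIMIT 1",
      params = list(as.integer(rec$parent_pid)))
    if (nrow(hit)) parent_key <- hit$proc_key[1]
  }
  DBI::dbExecute(st$con,
    "INSERT INTO processes (session_id, pid, start_time, parent_key, exe_path,
       exe_checksum, checksum_algo, cmdline, cwd, is_self)
     VALUES (?,?,?,?,?,?,?,?,?,?)",
    params = list(st$session_id, pid, start_time,
                  parent_key %||% NA_integer_,
                  rec$exe_path %||% NA_character_,
                  rec$exe_checksum %||% NA_character_,
                  rec$checksum_algo %||% CHECKSUM_ALGO,
                  as.character(jsonlite::toJSON(as.list(rec$cmdline %||% character(0)))),
                  rec$cwd %||% NA_character_,
                  as.integer(isTRUE(rec$is_self))))
  key <- DBI::dbGetQuery(st$con, "SELECT last_insert_rowid() AS k")$k[1]
  st$proc_keys[[nk]] <- key
  key
}

#' Register a file version
#'
#' `file_register` creates the next version of `path` (version 0 when the
#' path is new). `origin` is `"external"` for content that entered the tree
#' from outside (no recorded writer), `"internal"` for content produced by
#' a recorded process, `"virtual"` for virtual dynamic files.
#'
#' @param st A `prov_store`.
#' @param path Mount-relative path.
#' @param origin Version origin.
#' @param time Creation time (store clock when omitted).
#' @return Integer `file_key` of the new version.
#' @export
file_register <- function(st, path, origin = c("external", "internal", "virtual"),
                          time = NULL) {
  origin <- match.arg(origin)
  cur <- st$cur_file[[path]]
  vno <- if (is.null(cur)) 0L else cur[2] + 1L
  time <- time %||% store_now(st)
  store_advance(st, time)
  DBI::dbExecute(st$con,
    "INSERT INTO files (session_id, path, version_no, created_time, content_checksum, origin)
     VALUES (?,?,?,?,NULL,?)",
    params = list(st$session_id, path, vno, time, origin))
  key <- DBI::dbGetQuery(st$con, "SELECT last_insert_rowid() AS k")$k[1]
  st$cur_file[[path]] <- c(key, vno)
  key
}

#' @rdname file_register
#' @export
file_current <- function(st, path) {
  cur <- st$cur_file[[path]]
  if (is.null(cur)) NULL else cur[1]
}

file_set_checksum <- function(st, file_key, checksum) {
  DBI::dbExecute(st$con, "UPDATE files SET content_checksum = ? WHERE file_key = ?",
                 params = list(checksum, file_key))
  invisible(NULL)
}

## Rename transfers identity: every version of the old path keeps its keys,
## only the recorded path changes.
file_transfer <- function(st, old_path, new_path) {
  DBI::dbExecute(st$con, "UPDATE files SET path = ? WHERE path = ? AND session_id = ?",
                 params = list(new_path, old_path, st$session_id))
  cur <- st$cur_file[[old_path]]
  if (!is.null(cur)) {
    rm(list = old_path, envir = st$cur_file)
    st$cur_file[[new_path]] <- cur
  }
  invisible(NULL)
}

#' Record a primitive I/O event
#'
#' Consecutive primitive reads (resp. writes) by one process on one file
#' version coalesce into a single event with incremented `count`/`bytes`
#' and extended `t_last`; an intervening operation of a different kind by
#' that process on that file breaks the run. Other kinds are stored
#' un-coalesced.
#'
#' @param st A `prov_store`.
#' @param proc_key Process key (from [record_process()]).
#' @param file_key File-version key (from [file_register()]).
#' @param op_kind One of read, write, open, close, create, rename, unlink,
#'   truncate.
#' @param time Event time; store clock when omitted.
#' @param bytes Bytes moved (reads/writes).
#' @export
record_event <- function(st, proc_key, file_key, op_kind, time = NULL, bytes = 0) {
  stopifnot(!st$closed)
  kinds <- c("read", "write", "open", "close", "create", "rename", "unlink", "truncate")
  if (!op_kind %in% kinds) stop("unknown op_kind: ", op_kind, call. = FALSE)
  if (is.null(time)) time <- store_now(st) else store_advance(st, time)
  if (op_kind == "read") st$has_reads[[as.character(file_key)]] <- TRUE
  k <- paste0(proc_key, "|", file_key)
  cur <- st$open_ev[[k]]
  coalescable <- op_kind %in% c("read", "write")
  if (!is.null(cur) && cur$op_kind == op_kind && coalescable) {
    cur$count <- cur$count + 1L
    cur$bytes <- cur$bytes + bytes
    cur$t_last <- time
    cur$dirty <- TRUE
    st$open_ev[[k]] <- cur
  } else {
    if (!is.null(cur)) {
      ## run broken: the open event is final (flush will persist it if a
      ## mid-run flush already gave it a row, an update keeps it whole)
      st$done_ev[[length(st$done_ev) + 1L]] <- cur
      rm(list = k, envir = st$open_ev)
    }
    ev <- list(proc_key = proc_key, file_key = file_key, op_kind = op_kind,
               t_first = time, t_last = time, count = 1L, bytes = bytes,
               rowid = NA_real_, dirty = TRUE)
    if (coalescable) st$open_ev[[k]] <- ev
    else st$done_ev[[length(st$done_ev) + 1L]] <- ev
  }
  st$n_buffered <- st$n_buffered + 1L
  if (st$n_buffered >= st$flush_threshold) store_flush(st)
  invisible(NULL)
}

#' Flush the coalescing buffer to the database
#'
#' After a flush every event recorded before the call is visible to the
#' queries. Also triggered automatically when the buffer exceeds its
#' threshold, by any query, and at session close.
#'
#' @param st A `prov_store`.
#' @return Number of (coalesced) event rows persisted, invisibly.
#' @export
store_flush <- function(st) {
  evs <- st$done_ev
  st$done_ev <- list()
  open_keys <- ls(st$open_ev)
  open_keys <- open_keys[vapply(open_keys, function(k) isTRUE(st$open_ev[[k]]$dirty),
                                logical(1))]
  st$n_buffered <- 0L
  n <- 0L
  ## A still-open coalescing run is persisted too (queries must see it) but
  ## stays open: later primitives extend the same row, so query results do
  ## not depend on when flushes happened.
  persist <- function(ev) {
    if (is.na(ev$rowid)) {
      DBI::dbExecute(st$con,
        "INSERT INTO events (proc_key, file_key, op_kind, t_first, t_last, count, bytes)
         VALUES (?,?,?,?,?,?,?)",
        params = list(ev$proc_key, ev$file_key, ev$op_kind, ev$t_first,
                      ev$t_last, ev$count, ev$bytes))
      DBI::dbGetQuery(st$con, "SELECT last_insert_rowid() AS k")$k[1]
    } else {
      DBI::dbExecute(st$con,
        "UPDATE events SET t_last = ?, count = ?, bytes = ? WHERE event_key = ?",
        params = list(ev$t_last, ev$count, ev$bytes, ev$rowid))
      ev$rowid
    }
  }
  ordr <- order(c(vapply(evs, `[[`, numeric(1), "t_first"),
                  vapply(open_keys, function(k) st$open_ev[[k]]$t_first, numeric(1))))
  items <- c(lapply(seq_along(evs), function(i) list(kind = "done", i = i)),
             lapply(open_keys, function(k) list(kind = "open", k = k)))[ordr]
  for (it in items) {
    if (it$kind == "done") {
      persist(evs[[it$i]])
    } else {
      ev <- st$open_ev[[it$k]]
      ev$rowid <- persist(ev)
      ev$dirty <- FALSE
      st$open_ev[[it$k]] <- ev
    }
    n <- n + 1L
  }
  invisible(n)
}

#' Query 1: past write operations on a file version
#'
#' Returns all write/create/truncate events on `file_key`, optionally
#' restricted to those whose first byte landed strictly before `before`,
#' ordered by time. This is the first of the two queries the lineage trace
#' alternates.
#'
#' @param st A `prov_store`.
#' @param file_key File-version key.
#' @param before Optional exclusive upper bound on `t_first`.
#' @return data.frame with columns proc_key, file_key, op_kind, t_first,
#'   t_last, count, bytes.
#' @export
query_writes <- function(st, file_key, before = NULL) {
  store_flush(st)
  n <- DBI::dbGetQuery(st$con, "SELECT COUNT(*) AS n FROM files WHERE file_key = ?",
                       params = list(file_key))$n[1]
  if (n == 0) stop("unknown file_key: ", file_key, call. = FALSE)
  sql <- "SELECT proc_key, file_key, op_kind, t_first, t_last, count, bytes
          FROM events WHERE file_key = ? AND op_kind IN ('write','create','truncate')"
  params <- list(file_key)
  if (!is.null(before)) { sql <- paste(sql, "AND t_first < ?"); params <- c(params, before) }
  DBI::dbGetQuery(st$con, paste(sql, "ORDER BY t_first, event_key"), params = params)
}

#' Query 2: earlier reads by a process
#'
#' Returns all read events issued by `proc_key` whose first byte was read
#' strictly before `before` -- the inputs that could have influenced output
#' written at that time. The second of the two lineage queries.
#'
#' @param st A `prov_store`.
#' @param proc_key Process key.
#' @param before Exclusive upper bound on `t_first`.
#' @return data.frame with the same columns as [query_writes()].
#' @export
query_reads <- function(st, proc_key, before = Inf) {
  store_flush(st)
  n <- DBI::dbGetQuery(st$con, "SELECT COUNT(*) AS n FROM processes WHERE proc_key = ?",
                       params = list(proc_key))$n[1]
  if (n == 0) stop("unknown proc_key: ", proc_key, call. = FALSE)
  if (is.finite(before)) {
    DBI::dbGetQuery(st$con,
      "SELECT proc_key, file_key, op_kind, t_first, t_last, count, bytes
       FROM events WHERE proc_key = ? AND op_kind = 'read' AND t_first < ?
       ORDER BY t_first, event_key", params = list(proc_key, before))
  } else {
    DBI::dbGetQuery(st$con,
      "SELECT proc_key, file_key, op_kind, t_first, t_last, count, bytes
       FROM events WHERE proc_key = ? AND op_kind = 'read'
       ORDER BY t_first, event_key", params = list(proc_key))
  }
}

store_get_process <- function(st, proc_key) {
  r <- DBI::dbGetQuery(st$con, "SELECT * FROM processes WHERE proc_key = ?",
                       params = list(proc_key))
  if (nrow(r) == 0) stop("unknown proc_key: ", proc_key, call. = FALSE)
  r$cmdline_list <- list(unlist(jsonlite::fromJSON(r$cmdline[1])) %||% character(0))
  r
}

store_get_file <- function(st, file_key) {
  r <- DBI::dbGetQuery(st$con, "SELECT * FROM files WHERE file_key = ?",
                       params = list(file_key))
  if (nrow(r) == 0) stop("unknown file_key: ", file_key, call. = FALSE)
  r
}

#' Close a provenance store
#'
#' Flushes the buffer and disconnects; the database file holds the full
#' record.
#'
#' @param st A `prov_store`.
#' @export
store_close <- function(st) {
  if (st$closed) return(invisible(NULL))
  store_flush(st)
  DBI::dbDisconnect(st$con)
  st$closed <- TRUE
  invisible(NULL)
}
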