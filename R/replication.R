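## Replication: export a target's lineage as a portable, self-contained
## bundle; elsewhere, reconstruct the driving script, verify software
## identity by executable checksum, re-execute, and compare the produced
## target's checksum with the recorded one.

BUNDLE_SCHEMA <- 1L
SH_FAMILY <- c("sh", "bash", "dash", "ksh", "zsh")

chk_or_unavailable <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) "unavailable" else x
}

#' Export a replication bundle
#'
#' Traces `target` and packages the complete result -- file versions with
#' checksums, full process records (command line, working directory,
#' executable path and checksum), all edges, and external-origin inputs --
#' into a self-contained structure with no references into the live
#' database.
#'
#' @param st A `prov_store` (or a `mount_ctx`).
#' @param target File key or mount-relative path.
#' @return A `repl_bundle`.
#' @export
export_bundle <- function(st, target) {
  if (inherits(st, "mount_ctx")) st <- st$store
  g <- trace_lineage(st, target)
  tgt <- g$files[g$files$file_key == g$target, ]
  lfile <- function(i) {
    r <- g$files[i, ]
    list(file_key = r$file_key, path = r$path, version_no = r$version_no,
         origin = r$origin, content_checksum = chk_or_unavailable(r$content_checksum))
  }
  lproc <- function(i) {
    r <- g$procs[i, ]
    list(proc_key = r$proc_key, pid = r$pid, start_time = r$start_time,
         parent_key = if (is.na(r$parent_key)) "none" else r$parent_key,
         exe_path = r$exe_path,
         exe_checksum = chk_or_unavailable(r$exe_checksum),
         checksum_algo = r$checksum_algo,
         cmdline = as.list(unlist(jsonlite::fromJSON(r$cmdline)) %||% character(0)),
         cwd = r$cwd %||% ".")
  }
  ledge <- function(df, cols) lapply(seq_len(nrow(df)), function(i) as.list(df[i, cols]))
  structure(list(
    schema_version = BUNDLE_SCHEMA,
    session = list(session_id = st$session_id,
                   source_root = DBI::dbGetQuery(st$con,
                     "SELECT source_root FROM sessions LIMIT 1")$source_root[1]),
    target = list(file_key = tgt$file_key, path = tgt$path,
                  version_no = tgt$version_no,
                  content_checksum = chk_or_unavailable(tgt$content_checksum)),
    files = lapply(seq_len(nrow(g$files)), lfile),
    processes = if (nrow(g$procs)) lapply(seq_len(nrow(g$procs)), lproc) else list(),
    read_edges = ledge(g$read_edges, c("file_key", "proc_key", "time")),
    write_edges = ledge(g$write_edges, c("proc_key", "file_key", "time")),
    spawn_edges = if (nrow(g$spawn_edges))
      ledge(g$spawn_edges, c("parent_key", "child_key")) else list(),
    external_inputs = lapply(which(g$files$origin == "external"), lfile)
  ), class = "repl_bundle")
}

#' Write / read a bundle as JSON
#'
#' Serialisation is canonical: export -> write -> read -> write yields
#' byte-identical documents.
#'
#' @param bundle A `repl_bundle`.
#' @param path File path.
#' @return `read_bundle()` returns a `repl_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  txt <- as.character(jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE,
                                       digits = NA, pretty = TRUE, null = "null"))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(b$schema_version) || b$schema_version > BUNDLE_SCHEMA)
    stop("unsupported bundle schema version: ", b$schema_version %||% "missing",
         call. = FALSE)
  structure(b, class = "repl_bundle")
}

bundle_proc <- function(bundle, key) {
  for (p in bundle$processes) if (identical(p$proc_key, key)) return(p)
  NULL
}

## A shell-interpreter process whose spawned children are all captured in
## the bundle is a wrapper: its children are re-invoked, not the wrapper
## itself (prevents double execution).
is_wrapper <- function(bundle, p) {
  base <- basename(p$exe_path %||% "")
  if (!base %in% SH_FAMILY) return(FALSE)
  kids <- Filter(function(e)
    isTRUE(as.numeric(e$parent_key) == as.numeric(p$proc_key)), bundle$spawn_edges)
  length(kids) > 0
}

## Leaf processes in dependency order: p runs after q whenever q wrote a
## file p later read; recorded start time breaks ties.
ordered_leaf_procs <- function(bundle) {
  leaves <- Filter(function(p) !is_wrapper(bundle, p), bundle$processes)
  keys <- vapply(leaves, function(p) as.numeric(p$proc_key), numeric(1))
  if (!length(keys)) return(list())
  wt <- list(); rt <- list()
  for (e in bundle$write_edges) wt[[length(wt) + 1L]] <-
    c(proc = as.numeric(e$proc_key), file = as.numeric(e$file_key), time = as.numeric(e$time))
  for (e in bundle$read_edges) rt[[length(rt) + 1L]] <-
    c(file = as.numeric(e$file_key), proc = as.numeric(e$proc_key), time = as.numeric(e$time))
  dep <- matrix(FALSE, length(keys), length(keys), dimnames = list(keys, keys))
  for (w in wt) for (r in rt)
    if (w[["file"]] == r[["file"]] && w[["time"]] < r[["time"]] &&
        as.character(w[["proc"]]) %in% rownames(dep) &&
        as.character(r[["proc"]]) %in% rownames(dep) &&
        w[["proc"]] != r[["proc"]])
      dep[as.character(w[["proc"]]), as.character(r[["proc"]])] <- TRUE
  starts <- vapply(leaves, function(p) as.numeric(p$start_time), numeric(1))
  names(starts) <- as.character(keys)
  out <- list()
  remaining <- as.character(keys)
  while (length(remaining)) {
    ready <- remaining[colSums(dep[remaining, remaining, drop = FALSE]) == 0]
    if (!length(ready)) stop("cyclic process dependencies in bundle", call. = FALSE)
    nxt <- ready[order(starts[ready])][1]
    out[[length(out) + 1L]] <- leaves[[which(as.character(keys) == nxt)]]
    remaining <- setdiff(remaining, nxt)
  }
  out
}

#' Reconstruct an executable script from a bundle
#'
#' Emits a POSIX shell script that re-invokes every leaf process (shell
#' wrappers whose children were captured are skipped) with its recorded
#' command line and working directory, in dependency order with recorded
#' start time as tie-break. Executing the script in a directory containing
#' the bundle's external inputs reproduces the target -- even when the
#' original driver script was never copied.
#'
#' @param bundle A `repl_bundle`.
#' @return Script text (character scalar).
#' @export
reconstruct_script <- function(bundle) {
  if (length(bundle$processes) == 0)
    stop("target is of external origin: no recorded processes to reconstruct",
         call. = FALSE)
  procs <- ordered_leaf_procs(bundle)
  if (!length(procs))
    stop("bundle contains only wrapper processes; nothing to reconstruct", call. = FALSE)
  lines <- c("#!/bin/sh", "# reconstructed from recorded provenance", "set -e", "")
  dirs <- unique(dirname(vapply(bundle$files, `[[`, "", "path")))
  dirs <- sort(dirs[dirs != "."])
  if (length(dirs))
    lines <- c(lines, paste("mkdir -p", paste(shQuote(dirs), collapse = " ")), "")
  for (p in procs) {
    cmd <- paste(vapply(unlist(p$cmdline), shQuote, ""), collapse = " ")
    cwd <- p$cwd %||% "."
    lines <- c(lines, if (identical(cwd, ".")) cmd
               else sprintf("(cd %s && %s)", shQuote(cwd), cmd))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Verify the local environment against a bundle
#'
#' Locates every distinct executable the bundle records -- at its recorded
#' path first (relative paths against `root`), then on the search path --
#' checksums it, and reports each one that is missing or whose checksum
#' differs from the recorded one. Identical environments yield an empty
#' report.
#'
#' @param bundle A `repl_bundle`.
#' @param root Directory against which relative executable paths are
#'   resolved (the replication work directory).
#' @return data.frame with columns `exe_path`, `status`
#'   (`version_mismatch` / `missing_executable`), `expected`, `found`;
#'   zero rows when everything matches.
#' @export
verify_environment <- function(bundle, root = ".") {
  exes <- unique(vapply(bundle$processes, function(p) p$exe_path %||% "", ""))
  exes <- exes[nzchar(exes)]
  out <- data.frame(exe_path = character(0), status = character(0),
                    expected = character(0), found = character(0),
                    stringsAsFactors = FALSE)
  for (e in exes) {
    expected <- NULL
    for (p in bundle$processes)
      if (identical(p$exe_path, e)) { expected <- p$exe_checksum; break }
    if (identical(expected, "unavailable")) next  # nothing recorded to compare
    cand <- if (startsWith(e, "/")) e else file.path(root, e)
    if (!file.exists(cand)) cand <- unname(Sys.which(basename(e)))
    if (!nzchar(cand) || !file.exists(cand)) {
      out <- rbind(out, data.frame(exe_path = e, status = "missing_executable",
                                   expected = expected, found = NA_character_,
                                   stringsAsFactors = FALSE))
      next
    }
    found <- file_checksum(cand)
    if (!identical(found, expected))
      out <- rbind(out, data.frame(exe_path = e, status = "version_mismatch",
                                   expected = expected, found = found,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Replicate a bundle's workflow in a clean directory
#'
#' Stages the bundle's external inputs into `workdir` (from `inputs_dir`,
#' which defaults to the recorded source tree when it still exists),
#' verifies the environment, re-executes the reconstructed commands in
#' dependency order -- under a fresh monitored session, so the replica
#' gains its own provenance record -- and checksums the produced target.
#' Version mismatches are warnings, not fatal: replication proceeds and
#' the report retains them even when the output matches.
#'
#' @param bundle A `repl_bundle`.
#' @param workdir Empty or absent directory to replicate into.
#' @param inputs_dir Directory holding the external inputs at their
#'   recorded relative paths.
#' @param monitor Record the replica run under a monitored session.
#' @return A `repl_report`: `per_process` (status per re-run process:
#'   ok / version_mismatch / exec_failed / missing_executable),
#'   `mismatches`, `target_match`, `produced_checksum`,
#'   `expected_checksum`, `script`.
#' @export
replicate_bundle <- function(bundle, workdir, inputs_dir = NULL, monitor = TRUE) {
  if (dir.exists(workdir) && length(list.files(workdir, all.files = TRUE, no.. = TRUE)))
    stop("workdir must be empty or absent: ", workdir, call. = FALSE)
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  workdir <- normalizePath(workdir)
  inputs_dir <- inputs_dir %||% bundle$session$source_root
  for (f in bundle$external_inputs) {
    src <- file.path(inputs_dir, f$path)
    if (!file.exists(src))
      stop("external input missing: ", f$path, " (looked in ", inputs_dir, ")",
           call. = FALSE)
    dest <- file.path(workdir, f$path)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(src, dest, copy.mode = TRUE)
  }
  mism <- verify_environment(bundle, root = workdir)
  script <- reconstruct_script(bundle)
  writeLines(script, file.path(workdir, "replicate.sh"))
  for (d in unique(dirname(vapply(bundle$files, `[[`, "", "path"))))
    if (d != ".") dir.create(file.path(workdir, d), recursive = TRUE, showWarnings = FALSE)
  procs <- ordered_leaf_procs(bundle)
  status <- character(0)
  ctx <- if (monitor) mount_session(workdir) else NULL
  on.exit(if (!is.null(ctx)) session_close(ctx))
  for (p in procs) {
    cmdline <- unlist(p$cmdline)
    exe <- cmdline[1]
    stat <- if (exe %in% mism$exe_path)
      mism$status[mism$exe_path == exe][1] else "ok"
    if (stat == "missing_executable") {
      status <- c(status, stat)
      next
    }
    res <- if (!is.null(ctx)) {
      tryCatch(session_exec(ctx, exe, cmdline[-1]),
               error = function(e) list(status = 127L))
    } else {
      exe_abs <- if (file.exists(file.path(workdir, exe))) file.path(workdir, exe)
                 else unname(Sys.which(basename(exe)))
      px <- processx::run(exe_abs, cmdline[-1], wd = workdir, error_on_status = FALSE,
                          env = c(Sys.getenv(), "LC_ALL" = "C"))
      list(status = px$status)
    }
    if (res$status != 0) {
      status <- c(status, "exec_failed")
      break                                       # halt at the failing process
    }
    status <- c(status, stat)
  }
  per <- data.frame(
    proc_key = vapply(procs[seq_along(status)], function(p) as.numeric(p$proc_key), numeric(1)),
    command = vapply(procs[seq_along(status)],
                     function(p) paste(unlist(p$cmdline), collapse = " "), ""),
    status = status, stringsAsFactors = FALSE)
  produced <- file_checksum(file.path(workdir, bundle$target$path))
  produced <- chk_or_unavailable(produced)
  structure(list(per_process = per, mismatches = mism,
                 target_match = identical(produced, bundle$target$content_checksum),
                 produced_checksum = produced,
                 expected_checksum = bundle$target$content_checksum,
                 script = script, workdir = workdir),
            class = "repl_report")
}

#' @export
print.repl_report <- function(x, ...) {
  cat("replication report:\n")
  cat("  target match:", x$target_match, "\n")
  cat("  processes re-run:", nrow(x$per_process), "\n")
  if (nrow(x$mismatches)) {
    cat("  environment mismatches:\n")
    for (i in seq_len(nrow(x$mismatches)))
      cat(sprintf("    %s: %s\n", x$mismatches$exe_path[i], x$mismatches$status[i]))
  } else cat("  environment mismatches: none\n")
  invisible(x)
}

## Rebuild an in-memory provenance graph from a bundle (for visualising a
## bundle without its database).
graph_from_bundle <- function(bundle) {
  fdf <- do.call(rbind, lapply(bundle$files, function(f)
    data.frame(file_key = as.numeric(f$file_key), session_id = NA_character_,
               path = f$path, version_no = as.integer(f$version_no),
               created_time = NA_real_, content_checksum = f$content_checksum,
               origin = f$origin, stringsAsFactors = FALSE)))
  pdf <- if (length(bundle$processes))
    do.call(rbind, lapply(bundle$processes, function(p)
      data.frame(proc_key = as.numeric(p$proc_key), session_id = NA_character_,
                 pid = as.integer(p$pid), start_time = as.numeric(p$start_time),
                 parent_key = if (identical(p$parent_key, "none")) NA_real_
                              else as.numeric(p$parent_key),
                 exe_path = p$exe_path, exe_checksum = p$exe_checksum,
                 checksum_algo = p$checksum_algo,
                 cmdline = as.character(jsonlite::toJSON(p$cmdline)),
                 cwd = p$cwd, is_self = 0L, stringsAsFactors = FALSE)))
    else data.frame()
  edge_df <- function(es, cols) {
    if (!length(es)) {
      df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
      return(df)
    }
    do.call(rbind, lapply(es, function(e)
      as.data.frame(stats::setNames(lapply(cols, function(cc) as.numeric(e[[cc]])), cols))))
  }
  structure(list(files = fdf, procs = pdf,
                 read_edges = edge_df(bundle$read_edges, c("file_key", "proc_key", "time")),
                 write_edges = edge_df(bundle$write_edges, c("proc_key", "file_key", "time")),
                 spawn_edges = edge_df(bundle$spawn_edges, c("parent_key", "child_key")),
                 target = as.numeric(bundle$target$file_key)),
            class = "prov_graph")
}
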