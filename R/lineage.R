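## Lineage closure with the temporal-correctness constraint.
##
## trace() alternates the store's two queries: (1) who wrote this file
## version (before it was read downstream), (2) what did that process read
## before it wrote. Only reads that began before the write's first byte,
## and only writes that began before the dependent read, are included; the
## recursion moves strictly backward in time and bottoms out at
## external-origin files.

#' Trace the provenance of a file version
#'
#' Reconstructs the full provenance graph of `target`: every process that
#' wrote it; for each such process, every file it read before the write
#' (output is assumed to depend on all data the process read earlier);
#' recursively, the processes that wrote those files before they were
#' read. Recorded process ancestry is attached as spawn edges.
#'
#' @param st A `prov_store`.
#' @param target A `file_key`, or a mount-relative path (current version).
#' @return A `prov_graph`: data.frames `files`, `procs`, `read_edges`
#'   (file -> process, time), `write_edges` (process -> file, time),
#'   `spawn_edges` (parent -> child), and `target` (file_key).
#' @export
trace_lineage <- function(st, target) {
  if (is.character(target)) {
    key <- file_current(st, target)
    if (is.null(key)) stop("unknown target path: ", target, call. = FALSE)
    target <- key
  }
  store_get_file(st, target)  # errors on unknown key
  processed <- new.env(parent = emptyenv())   # file_key -> max bound handled
  files <- numeric(0); procs <- numeric(0)
  wsrc <- numeric(0); wdst <- numeric(0); wt <- numeric(0)
  rsrc <- numeric(0); rdst <- numeric(0); rt <- numeric(0)
  frontier <- list(list(f = target, b = Inf))
  while (length(frontier)) {
    cur <- frontier[[length(frontier)]]
    frontier[[length(frontier)]] <- NULL
    fk <- cur$f; b <- cur$b
    done <- processed[[as.character(fk)]]
    if (!is.null(done) && done >= b) next
    processed[[as.character(fk)]] <- max(done %||% -Inf, b)
    files <- union(files, fk)
    w <- query_writes(st, fk, before = if (is.finite(b)) b else NULL)
    for (i in seq_len(nrow(w))) {
      p <- w$proc_key[i]; tw <- w$t_first[i]
      procs <- union(procs, p)
      wsrc <- c(wsrc, p); wdst <- c(wdst, fk); wt <- c(wt, tw)
      r <- query_reads(st, p, before = tw)
      for (j in seq_len(nrow(r))) {
        g <- r$file_key[j]; tr <- r$t_first[j]
        files <- union(files, g)
        rsrc <- c(rsrc, g); rdst <- c(rdst, p); rt <- c(rt, tr)
        frontier[[length(frontier) + 1L]] <- list(f = g, b = tr)
      }
    }
  }
  ## spawn edges: recorded ancestry of every traced process
  ssrc <- numeric(0); sdst <- numeric(0)
  queue <- procs
  seen <- procs
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    pr <- store_get_process(st, p)
    pa <- pr$parent_key[1]
    if (!is.na(pa)) {
      ssrc <- c(ssrc, pa); sdst <- c(sdst, p)
      if (!pa %in% seen) { seen <- c(seen, pa); queue <- c(queue, pa) }
    }
  }
  procs_all <- unique(seen)
  fdf <- do.call(rbind, lapply(sort(files), function(k) store_get_file(st, k)))
  pdf <- if (length(procs_all))
    do.call(rbind, lapply(sort(procs_all), function(k) {
      r <- store_get_process(st, k); r$cmdline_list <- NULL; r
    }))
  else data.frame()
  we <- unique(data.frame(proc_key = wsrc, file_key = wdst, time = wt))
  re <- unique(data.frame(file_key = rsrc, proc_key = rdst, time = rt))
  se <- unique(data.frame(parent_key = ssrc, child_key = sdst))
  structure(list(files = fdf, procs = pdf,
                 read_edges = re[order(re$time, re$file_key, re$proc_key), , drop = FALSE],
                 write_edges = we[order(we$time, we$proc_key, we$file_key), , drop = FALSE],
                 spawn_edges = se[order(se$parent_key, se$child_key), , drop = FALSE],
                 target = target),
            class = "prov_graph")
}

#' @export
print.prov_graph <- function(x, ...) {
  cat("provenance graph:", nrow(x$files), "file version(s),",
      nrow(x$procs), "process(es),", nrow(x$read_edges), "read edge(s),",
      nrow(x$write_edges), "write edge(s),", nrow(x$spawn_edges), "spawn edge(s)\n")
  tgt <- x$files[x$files$file_key == x$target, ]
  cat("target:", tgt$path[1], sprintf("(v%d)\n", tgt$version_no[1]))
  invisible(x)
}

## -- Reference oracle --------------------------------------------------------

## Mark burst-first primitives: within one (proc, file) pair's time-ordered
## stream, a primitive starts a burst when it is the first operation or its
## kind differs from the previous operation of that pair. Burst starts are
## the t_first values the coalesced store exposes.
burst_firsts <- function(events) {
  ord <- order(events$time)
  ev <- events[ord, , drop = FALSE]
  keyprev <- new.env(parent = emptyenv())
  first <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    k <- paste0(ev$proc[i], "|", ev$file[i])
    first[i] <- !identical(keyprev[[k]], ev$kind[i])
    keyprev[[k]] <- ev$kind[i]
  }
  ev$burst_first <- first
  ev
}

#' Brute-force provenance closure (test oracle)
#'
#' Computes the same lineage closure as [trace_lineage()] by naive repeated
#' scanning of a raw primitive event list, with the same temporal rule
#' expressed directly on burst-start times. Intended as an independent
#' reference for testing; it never touches a store.
#'
#' @param events data.frame with columns `proc`, `file`, `kind`
#'   (`"read"`/`"write"`), `time` (a valid, time-orderable stream).
#' @param target File id to trace.
#' @param parents Optional data.frame (`proc`, `parent`) of spawn links.
#' @return List with `files`, `procs` (id vectors), `read_edges`,
#'   `write_edges`, `spawn_edges` data.frames and `target`.
#' @export
brute_force_trace <- function(events, target, parents = NULL) {
  ev <- burst_firsts(events)
  wb <- ev[ev$kind == "write" & ev$burst_first, , drop = FALSE]
  rb <- ev[ev$kind == "read" & ev$burst_first, , drop = FALSE]
  files <- target; procs <- numeric(0)
  we <- data.frame(proc = numeric(0), file = numeric(0), time = numeric(0))
  re <- data.frame(file = numeric(0), proc = numeric(0), time = numeric(0))
  best <- list()  # file id -> largest bound already expanded
  pending <- list(list(f = target, b = Inf))
  while (length(pending)) {
    it <- pending[[1]]; pending <- pending[-1]
    fid <- as.character(it$f)
    if (!is.null(best[[fid]]) && best[[fid]] >= it$b) next
    best[[fid]] <- max(best[[fid]] %||% -Inf, it$b)
    files <- union(files, it$f)
    ## query 1, by scanning: write bursts on this file before the bound
    for (i in which(wb$file == it$f & wb$time < it$b)) {
      p <- wb$proc[i]; tw <- wb$time[i]
      procs <- union(procs, p)
      we <- unique(rbind(we, data.frame(proc = p, file = it$f, time = tw)))
      ## query 2, by scanning: this process's read bursts before that write
      for (j in which(rb$proc == p & rb$time < tw)) {
        g <- rb$file[j]; tr <- rb$time[j]
        files <- union(files, g)
        re <- unique(rbind(re, data.frame(file = g, proc = p, time = tr)))
        pending[[length(pending) + 1L]] <- list(f = g, b = tr)
      }
    }
  }
  se <- data.frame(parent = numeric(0), child = numeric(0))
  if (!is.null(parents) && nrow(parents)) {
    queue <- procs; seen <- procs
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      pa <- parents$parent[parents$proc == p]
      if (length(pa) == 1 && !is.na(pa)) {
        se <- unique(rbind(se, data.frame(parent = pa, child = p)))
        if (!pa %in% seen) { seen <- c(seen, pa); queue <- c(queue, pa) }
      }
    }
    procs <- seen
  }
  list(files = sort(files), procs = sort(unique(procs)),
       read_edges = re[order(re$time, re$file, re$proc), , drop = FALSE],
       write_edges = we[order(we$time, we$proc, we$file), , drop = FALSE],
       spawn_edges = se[order(se$parent, se$child), , drop = FALSE],
       target = target)
}
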