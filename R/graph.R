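## Human-facing rendering of a provenance graph: signature grouping of
## files, collapse/expand of spawned child processes, DOT and JSON export.

## A proc is visible iff every ancestor inside the graph is expanded; the
## default (top-level) view collapses all spawned children.
visible_procs <- function(g, expanded) {
  if (nrow(g$procs) == 0) return(numeric(0))
  keys <- g$procs$proc_key
  parent <- stats::setNames(g$procs$parent_key, as.character(keys))
  vis <- logical(length(keys)); names(vis) <- as.character(keys)
  is_vis <- function(k) {
    pa <- parent[[as.character(k)]]
    if (is.na(pa) || !pa %in% keys) return(TRUE)
    is_vis(pa) && as.character(pa) %in% expanded
  }
  keys[vapply(keys, is_vis, logical(1))]
}

nearest_visible <- function(g, k, vis) {
  parent <- stats::setNames(g$procs$parent_key, as.character(g$procs$proc_key))
  while (!k %in% vis) {
    pa <- parent[[as.character(k)]]
    if (is.na(pa) || !pa %in% g$procs$proc_key) return(k)
    k <- pa
  }
  k
}

render_graph <- function(g, expanded = character(0), group = TRUE) {
  vis <- visible_procs(g, expanded)
  reattach <- function(k) nearest_visible(g, k, vis)
  re <- g$read_edges; we <- g$write_edges
  if (nrow(re)) re$proc_key <- vapply(re$proc_key, reattach, numeric(1))
  if (nrow(we)) we$proc_key <- vapply(we$proc_key, reattach, numeric(1))
  re <- unique(re[c("file_key", "proc_key")])
  we <- unique(we[c("proc_key", "file_key")])
  ## signature partition of file nodes (target always rendered alone)
  fkeys <- g$files$file_key
  sig <- vapply(fkeys, function(f) {
    paste(paste(sort(re$proc_key[re$file_key == f]), collapse = ","),
          paste(sort(we$proc_key[we$file_key == f]), collapse = ","), sep = ";")
  }, "")
  grp_of <- stats::setNames(rep(NA_character_, length(fkeys)), as.character(fkeys))
  nodes <- data.frame(id = character(0), kind = character(0), label = character(0),
                      member_count = integer(0), stringsAsFactors = FALSE)
  members_of <- list()
  if (group) {
    gi <- 0L
    for (s in unique(sig)) {
      members <- fkeys[sig == s & fkeys != g$target]
      if (length(members) > 1) {
        gi <- gi + 1L
        gid <- paste0("g", gi)
        grp_of[as.character(members)] <- gid
        members_of[[gid]] <- sort(members)
        nodes <- rbind(nodes, data.frame(
          id = gid, kind = "file_group",
          label = sprintf("%d files", length(members)),
          member_count = length(members), stringsAsFactors = FALSE))
      }
    }
  }
  for (i in seq_along(fkeys)) {
    f <- fkeys[i]
    if (!is.na(grp_of[[as.character(f)]])) next
    row <- g$files[g$files$file_key == f, ]
    lab <- if (row$version_no[1] > 0) sprintf("%s (v%d)", row$path[1], row$version_no[1])
           else row$path[1]
    nodes <- rbind(nodes, data.frame(id = paste0("f", f), kind = "file", label = lab,
                                     member_count = 1L, stringsAsFactors = FALSE))
  }
  for (p in sort(vis)) {
    row <- g$procs[g$procs$proc_key == p, ]
    cmd <- tryCatch(unlist(jsonlite::fromJSON(row$cmdline[1])), error = function(e) character(0))
    lab <- if (length(cmd)) paste(basename(cmd[1]), if (length(cmd) > 1)
      paste(cmd[-1], collapse = " ")) else basename(row$exe_path[1] %||% "?")
    nodes <- rbind(nodes, data.frame(id = paste0("p", p), kind = "process",
                                     label = trimws(lab), member_count = 1L,
                                     stringsAsFactors = FALSE))
  }
  fnode <- function(f) { gid <- grp_of[[as.character(f)]]; if (is.na(gid)) paste0("f", f) else gid }
  edges <- data.frame(src = character(0), dst = character(0), kind = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(re))
    edges <- rbind(edges, data.frame(src = vapply(re$file_key, fnode, ""),
                                     dst = paste0("p", re$proc_key),
                                     kind = "read", stringsAsFactors = FALSE))
  if (nrow(we))
    edges <- rbind(edges, data.frame(src = paste0("p", we$proc_key),
                                     dst = vapply(we$file_key, fnode, ""),
                                     kind = "write", stringsAsFactors = FALSE))
  se <- g$spawn_edges
  if (nrow(se)) {
    keep <- se$parent_key %in% vis & se$child_key %in% vis
    if (any(keep))
      edges <- rbind(edges, data.frame(src = paste0("p", se$parent_key[keep]),
                                       dst = paste0("p", se$child_key[keep]),
                                       kind = "spawn", stringsAsFactors = FALSE))
  }
  edges <- unique(edges)
  edges <- edges[order(edges$kind, edges$src, edges$dst), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  ## hidden subtrees, per visible proc with unexpanded children
  collapsed <- list()
  if (nrow(g$procs)) {
    for (p in vis) {
      kids <- g$spawn_edges$child_key[g$spawn_edges$parent_key == p]
      kids <- kids[!kids %in% vis]
      if (length(kids)) collapsed[[as.character(p)]] <- sort(kids)
    }
  }
  structure(list(nodes = nodes, edges = edges, collapsed = collapsed,
                 members = members_of, graph = g, expanded = sort(expanded),
                 grouped = group, target_id = paste0("f", g$target)),
            class = "rendered_graph")
}

#' Group files with identical I/O signatures
#'
#' Partitions the file nodes of a provenance graph by their exact (reader
#' process set, writer process set) signature; every partition of size > 1
#' becomes a single counted `file_group` node, greatly reducing visual
#' complexity. The target file is always rendered individually. Spawned
#' child processes are collapsed into their parents in this default
#' top-level view; see [expand_process()].
#'
#' @param g A `prov_graph` from [trace_lineage()].
#' @param group Set `FALSE` to render without grouping.
#' @return A `rendered_graph`.
#' @export
group_files <- function(g, group = TRUE) render_graph(g, character(0), group)

#' Expand or re-collapse a process's spawned children
#'
#' Expanding makes the children visible as process nodes joined by spawn
#' edges, re-attaching their file I/O from the parent aggregate to the
#' children; collapsing restores the prior rendering. Expanding a process
#' with no hidden children (or an unknown id) is a no-op; expanding twice
#' is idempotent.
#'
#' @param rg A `rendered_graph`.
#' @param proc_key The process to expand/collapse.
#' @return A `rendered_graph`.
#' @export
expand_process <- function(rg, proc_key) {
  pk <- as.character(proc_key)
  if (is.null(rg$collapsed[[pk]])) return(rg)
  render_graph(rg$graph, union(rg$expanded, pk), rg$grouped)
}

#' @rdname expand_process
#' @export
collapse_process <- function(rg, proc_key) {
  render_graph(rg$graph, setdiff(rg$expanded, as.character(proc_key)), rg$grouped)
}

#' Export a rendered graph
#'
#' `graph_to_dot()` emits a deterministic Graphviz DOT digraph (processes
#' red boxes, files blue ellipses, the target green, groups counted);
#' `graph_to_json()` the same structure as a JSON document.
#'
#' @param rg A `rendered_graph`.
#' @return A character scalar.
#' @export
graph_to_dot <- function(rg) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c("digraph provenance {", "  rankdir=BT;")
  for (i in seq_len(nrow(rg$nodes))) {
    n <- rg$nodes[i, ]
    style <- switch(n$kind,
      process = 'shape=box, style=filled, fillcolor="#e05555", fontcolor=white',
      file = if (n$id == rg$target_id)
        'shape=ellipse, style=filled, fillcolor="#4caf50"'
      else 'shape=ellipse, style=filled, fillcolor="#5b7fd4", fontcolor=white',
      file_group = 'shape=folder, style=filled, fillcolor="#5b7fd4", fontcolor=white')
    lines <- c(lines, sprintf('  "%s" [label="%s", %s];', n$id, esc(n$label), style))
  }
  for (i in seq_len(nrow(rg$edges))) {
    e <- rg$edges[i, ]
    attr <- switch(e$kind, read = 'color=black', write = 'color=black, style=bold',
                   spawn = 'color="#e05555"')
    lines <- c(lines, sprintf('  "%s" -> "%s" [%s];', e$src, e$dst, attr))
  }
  paste0(paste(c(lines, "}"), collapse = "\n"), "\n")
}

#' @rdname graph_to_dot
#' @export
graph_to_json <- function(rg) {
  doc <- list(
    nodes = lapply(seq_len(nrow(rg$nodes)), function(i) as.list(rg$nodes[i, ])),
    edges = lapply(seq_len(nrow(rg$edges)), function(i) as.list(rg$edges[i, ])),
    target = rg$target_id,
    expanded = as.list(rg$expanded))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
}

#' @export
print.rendered_graph <- function(x, ...) {
  cat("rendered provenance graph:", nrow(x$nodes), "node(s),",
      nrow(x$edges), "edge(s);", length(x$collapsed), "collapsed subtree(s)\n")
  invisible(x)
}
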