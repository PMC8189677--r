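# Shared fixtures: simulated callers, canonical edge forms, the
# store-vs-oracle comparator, and the mixed passthrough workload driver.

sim_caller <- function(pid, name = "proc", start_time = 1) {
  structure(list(pid = as.integer(pid), start_time = start_time,
                 cmdline = list(name), cwd = ".", exe_path = paste0("/usr/bin/", name),
                 exe_checksum = NA_character_, is_self = FALSE),
            class = "process_record")
}

norm_edges <- function(df, cols) {
  d <- unique(df[cols])
  d[] <- lapply(d, as.numeric)
  d <- d[do.call(order, d), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Compare a store-side trace (store keys) with a log-side oracle result
# (log ids), via the replay key maps. Returns TRUE or a description.
trace_matches_oracle <- function(tr, oracle, rp) {
  fmap <- stats::setNames(as.numeric(names(rp$file_keys)), rp$file_keys)
  pmap <- stats::setNames(as.numeric(names(rp$proc_keys)), rp$proc_keys)
  tr_files <- sort(unname(fmap[as.character(tr$files$file_key)]))
  tr_procs <- sort(unname(pmap[as.character(tr$procs$proc_key)]))
  if (!identical(tr_files, as.numeric(sort(oracle$files))))
    return(sprintf("file sets differ: trace {%s} vs oracle {%s}",
                   toString(tr_files), toString(oracle$files)))
  if (!identical(tr_procs, as.numeric(sort(oracle$procs))))
    return(sprintf("process sets differ: trace {%s} vs oracle {%s}",
                   toString(tr_procs), toString(oracle$procs)))
  twe <- data.frame(proc = unname(pmap[as.character(tr$write_edges$proc_key)]),
                    file = unname(fmap[as.character(tr$write_edges$file_key)]),
                    time = tr$write_edges$time)
  tre <- data.frame(file = unname(fmap[as.character(tr$read_edges$file_key)]),
                    proc = unname(pmap[as.character(tr$read_edges$proc_key)]),
                    time = tr$read_edges$time)
  if (!isTRUE(all.equal(norm_edges(twe, c("proc", "file", "time")),
                        norm_edges(oracle$write_edges, c("proc", "file", "time")))))
    return("write edge sets differ")
  if (!isTRUE(all.equal(norm_edges(tre, c("file", "proc", "time")),
                        norm_edges(oracle$read_edges, c("file", "proc", "time")))))
    return("read edge sets differ")
  TRUE
}

# Drive the same seeded create/write/read/rename/unlink workload against an
# arbitrary backend; returns the primitive operation counts by kind.
run_mixed_workload <- function(n_ops, seed, do_op) {
  set.seed(seed)
  counts <- c(create = 0, write = 0, read = 0, rename = 0, unlink = 0,
              open = 0, close = 0)
  files <- character(0)
  for (i in seq_len(n_ops)) {
    op <- sample(c("create", "write", "read", "rename", "unlink"), 1,
                 prob = c(.2, .3, .3, .1, .1))
    if (op == "create" || !length(files)) {
      nm <- sprintf("f%05d.txt", i)
      do_op("create", nm)
      files <- c(files, nm); counts["create"] <- counts["create"] + 1
    } else if (op == "write") {
      nm <- sample(files, 1)
      do_op("write", nm, sprintf("line %d from workload\n", i))
      counts["write"] <- counts["write"] + 1
      counts["open"] <- counts["open"] + 1; counts["close"] <- counts["close"] + 1
    } else if (op == "read") {
      do_op("read", sample(files, 1))
      counts["read"] <- counts["read"] + 1
      counts["open"] <- counts["open"] + 1; counts["close"] <- counts["close"] + 1
    } else if (op == "rename") {
      nm <- sample(files, 1); nn <- paste0(nm, ".moved")
      do_op("rename", nm, nn)
      files[files == nm] <- nn; counts["rename"] <- counts["rename"] + 1
    } else {
      nm <- sample(files, 1)
      do_op("unlink", nm)
      files <- setdiff(files, nm); counts["unlink"] <- counts["unlink"] + 1
    }
  }
  counts
}

direct_backend <- function(root) {
  function(op, nm, arg = NULL) {
    p <- file.path(root, nm)
    switch(op,
      create = file.create(p),
      write = { con <- file(p, "ab"); writeBin(charToRaw(arg), con); close(con) },
      read = invisible(readBin(p, raw(), n = max(0, file.size(p)))),
      rename = file.rename(p, file.path(root, arg)),
      unlink = unlink(p))
  }
}

mount_backend <- function(ctx, caller) {
  function(op, nm, arg = NULL) {
    switch(op,
      create = vfs_create(ctx, nm, caller = caller),
      write = { h <- vfs_open(ctx, nm, "a", caller = caller)
                vfs_write(ctx, h, arg); vfs_close(ctx, h) },
      read = { h <- vfs_open(ctx, nm, "r", caller = caller)
               invisible(vfs_read(ctx, h, Inf)); vfs_close(ctx, h) },
      rename = vfs_rename(ctx, nm, arg, caller = caller),
      unlink = vfs_unlink(ctx, nm, caller = caller))
  }
}

tree_checksums <- function(root) {
  fs <- sort(list.files(root, recursive = TRUE))
  stats::setNames(vapply(fs, function(f) digest::digest(file.path(root, f),
                                                        algo = "sha256", file = TRUE), ""),
                  fs)
}

# Independent recomputation of the grouped edge quotient (grouping
# oracle). Classes are named by their sorted member file keys so the
# rendered edge set can be compared name-for-name.
naive_quotient <- function(g) {
  sig <- vapply(g$files$file_key, function(f) {
    paste(paste(sort(unique(g$read_edges$proc_key[g$read_edges$file_key == f])),
                collapse = ","),
          paste(sort(unique(g$write_edges$proc_key[g$write_edges$file_key == f])),
                collapse = ","), sep = ";")
  }, "")
  names(sig) <- as.character(g$files$file_key)
  cls <- function(f) {
    s <- sig[[as.character(f)]]
    members <- g$files$file_key[sig == s & g$files$file_key != g$target]
    if (f != g$target && length(members) > 1)
      paste0("grp:", paste(sort(members), collapse = "+"))
    else paste0("f", f)
  }
  e <- character(0)
  for (i in seq_len(nrow(g$read_edges)))
    e <- c(e, paste0(cls(g$read_edges$file_key[i]), "->p", g$read_edges$proc_key[i]))
  for (i in seq_len(nrow(g$write_edges)))
    e <- c(e, paste0("p", g$write_edges$proc_key[i], "->", cls(g$write_edges$file_key[i])))
  sort(unique(e))
}

# The rendered edge set in the oracle's canonical naming (groups named by
# their member file keys). Spawn edges are outside the quotient.
rendered_quotient <- function(rg) {
  canon <- function(id) {
    if (id %in% names(rg$members))
      paste0("grp:", paste(rg$members[[id]], collapse = "+"))
    else id
  }
  e <- rg$edges[rg$edges$kind != "spawn", , drop = FALSE]
  sort(unique(paste0(vapply(e$src, canon, ""), "->", vapply(e$dst, canon, ""))))
}
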