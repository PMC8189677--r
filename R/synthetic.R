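## Deterministic synthetic workloads: multi-stage shell pipelines over
## generated text files, randomized raw event logs with an exhaustively
## computed ground-truth closure, and VDF fixture trees. Everything is a
## pure function of its seed, so any failing case replays exactly.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

rand_words <- function(n) {
  pool <- c("acacia", "basalt", "cormorant", "dactyl", "eider", "fulmar",
            "gannet", "hemlock", "ibis", "juniper", "kestrel", "lichen",
            "murre", "nettle", "osprey", "petrel", "quartz", "rowan",
            "skua", "tern", "umber", "vole", "willow", "xenon", "yarrow", "zephyr")
  paste(sample(pool, n, replace = TRUE), sample(1000:9999, n, replace = TRUE), sep = "-")
}

## Small POSIX tool scripts; each pipeline carries its own copies so they
## are ordinary in-tree files with checksums and provenance.
PIPE_TOOLS <- list(
  tool_sort  = "#!/bin/sh\nLC_ALL=C sort \"$1\" > \"$2\"\n",
  tool_upper = "#!/bin/sh\ntr 'a-z' 'A-Z' < \"$1\" > \"$2\"\n",
  tool_subst = "#!/bin/sh\nsed 'y/aeiou/43105/' \"$1\" > \"$2\"\n",
  tool_first = "#!/bin/sh\nhead -n 8 \"$1\" > \"$2\"\n",
  tool_merge = "#!/bin/sh\no=\"$1\"; shift; cat \"$@\" > \"$o\"\n"
)

#' Generate a deterministic synthetic pipeline
#'
#' Builds an `n_stages`-stage workflow of ubiquitous deterministic text
#' utilities (sorting, case mapping, substitution, truncation, merging)
#' over `branching` generated input files, together with a driver shell
#' script, the expected checksum of the final target (frozen by a single
#' reference execution in a scratch directory at generation time), and the
#' expected lineage topology computed analytically from the stage list.
#' Identical seeds yield identical pipelines and, because every command is
#' deterministic, byte-identical targets on every run.
#'
#' @param n_stages Number of stages (>= 1).
#' @param branching Number of initial input files / merge width (1-3).
#' @param seed RNG seed.
#' @return A `synthetic_pipeline`: `inputs` (named character: path ->
#'   content), `tools`, `stages` (tool, args, inputs, outputs), `driver`
#'   (script text), `target`, `expected` (checksum + topology counts).
#' @export
gen_pipeline <- function(n_stages, branching = 1, seed = 1) {
  stopifnot(n_stages >= 1, branching >= 1)
  with_seed(seed, {
    inputs <- list()
    for (i in seq_len(branching)) {
      nm <- sprintf("data/input_%d.txt", i)
      inputs[[nm]] <- paste0(paste(rand_words(12 + sample(0:8, 1)), collapse = "\n"), "\n")
    }
    pool <- names(inputs)            # files available as stage inputs
    unary <- c("tool_sort", "tool_upper", "tool_subst", "tool_first")
    stages <- list()
    for (s in seq_len(n_stages)) {
      out <- sprintf("out/stage_%02d.txt", s)
      last <- s == n_stages
      wide <- length(pool) > 1 && (last || stats::runif(1) < 0.35)
      if (wide) {
        k <- if (last) length(pool) else sample(2:min(branching, length(pool)), 1)
        ins <- sample(pool, min(k, length(pool)))
        stages[[s]] <- list(tool = "tool_merge", args = c(out, ins),
                            inputs = ins, outputs = out)
        pool <- c(setdiff(pool, ins), out)
      } else {
        tool <- sample(unary, 1)
        src <- sample(pool, 1)
        stages[[s]] <- list(tool = tool, args = c(src, out),
                            inputs = src, outputs = out)
        pool <- c(setdiff(pool, src), out)
      }
    }
    target <- stages[[n_stages]]$outputs
    driver <- paste0("#!/bin/sh\nset -e\n",
                     paste(vapply(stages, function(st)
                       paste(c(file.path("bin", st$tool), st$args), collapse = " "), ""),
                       collapse = "\n"), "\n")
    pipe <- structure(list(seed = seed, n_stages = n_stages, branching = branching,
                           inputs = inputs, tools = PIPE_TOOLS, stages = stages,
                           driver = driver, target = target),
                      class = "synthetic_pipeline")
    pipe$expected <- pipeline_expectations(pipe)
    pipe
  })
}

## Closure of the target over the stage DAG, plus one reference execution
## to freeze the target checksum.
pipeline_expectations <- function(pipe) {
  writers <- list()
  for (s in seq_along(pipe$stages))
    for (o in pipe$stages[[s]]$outputs) writers[[o]] <- s
  need <- pipe$target; seen_f <- character(0); seen_s <- integer(0)
  while (length(need)) {
    f <- need[1]; need <- need[-1]
    if (f %in% seen_f) next
    seen_f <- c(seen_f, f)
    s <- writers[[f]]
    if (!is.null(s) && !s %in% seen_s) {
      seen_s <- c(seen_s, s)
      need <- c(need, pipe$stages[[s]]$inputs)
    }
  }
  tools_used <- unique(vapply(pipe$stages[seen_s], `[[`, "", "tool"))
  scratch <- tempfile("pipegen")
  materialize_pipeline(pipe, scratch)
  for (st in pipe$stages) {
    res <- processx::run(file.path(scratch, "bin", st$tool), st$args, wd = scratch,
                         env = c(Sys.getenv(), "LC_ALL" = "C"), error_on_status = TRUE)
  }
  chk <- file_checksum(file.path(scratch, pipe$target))
  unlink(scratch, recursive = TRUE)
  list(checksum = chk,
       ## files: stage outputs + external inputs in closure + tool scripts used
       n_stage_procs = length(seen_s),
       n_files = length(seen_f) + length(tools_used),
       n_external = length(intersect(seen_f, names(pipe$inputs))) + length(tools_used))
}

#' Materialise a pipeline's inputs and tools into a directory
#'
#' @param pipe A `synthetic_pipeline`.
#' @param dir Target directory (created).
#' @return `dir`, invisibly.
#' @export
materialize_pipeline <- function(pipe, dir) {
  dir.create(file.path(dir, "bin"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "out"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(pipe$inputs)) {
    dir.create(dirname(file.path(dir, nm)), recursive = TRUE, showWarnings = FALSE)
    writeChar(pipe$inputs[[nm]], file.path(dir, nm), eos = NULL)
  }
  for (nm in names(pipe$tools)) {
    p <- file.path(dir, "bin", nm)
    writeChar(pipe$tools[[nm]], p, eos = NULL)
    Sys.chmod(p, "755")
  }
  writeChar(pipe$driver, file.path(dir, "run_pipeline.sh"), eos = NULL)
  Sys.chmod(file.path(dir, "run_pipeline.sh"), "755")
  invisible(dir)
}

#' Execute a pipeline under a monitored session
#'
#' Runs every stage through [session_exec()], recording the driver script
#' as a parent shell process with spawn links to the stages (mirroring how
#' a recorded shell script expands into children).
#'
#' @param ctx A `mount_ctx` over a directory prepared with
#'   [materialize_pipeline()].
#' @param pipe A `synthetic_pipeline`.
#' @return List with `driver_key` and per-stage `proc_keys`.
#' @export
run_pipeline <- function(ctx, pipe) {
  st <- ctx$store
  sh <- unname(Sys.which("sh"))
  driver <- list(pid = Sys.getpid() * 1000L + (pipe$seed %% 1000L),
                 start_time = store_now(st), exe_path = sh,
                 exe_checksum = file_checksum(sh), checksum_algo = CHECKSUM_ALGO,
                 cmdline = c("sh", "run_pipeline.sh"), cwd = ".", is_self = FALSE)
  driver_key <- record_process(st, driver)
  dk <- ensure_version(ctx, "run_pipeline.sh")
  record_event(st, driver_key, dk, "read",
               bytes = file.size(file.path(ctx$source_root, "run_pipeline.sh")))
  pks <- numeric(0)
  for (stage in pipe$stages) {
    res <- session_exec(ctx, file.path("bin", stage$tool), stage$args,
                        inputs = stage$inputs, outputs = stage$outputs,
                        parent = driver_key)
    if (res$status != 0) stop("pipeline stage failed: ", stage$tool, call. = FALSE)
    pks <- c(pks, res$proc_key)
  }
  list(driver_key = driver_key, proc_keys = pks)
}

## -- Randomized event logs with ground truth ---------------------------------

#' Generate a randomized raw event log with known lineage
#'
#' Emits a primitive event stream (strictly increasing integer timestamps)
#' over `n_procs` processes and `n_files` files that deliberately includes
#' the adversarial shapes the temporal constraint must handle: writers
#' that arrive after a dependent read (and must be excluded), multi-writer
#' files, consecutive same-kind runs (exercising coalescing), external
#' roots never written, pid reuse, and spawn links. The ground-truth
#' closure of each suggested target is computed at generation time by an
#' exhaustive fixpoint that shares no code with the lineage tracer.
#'
#' @param n_procs,n_files Sizes (>= 1).
#' @param seed RNG seed.
#' @param n_targets How many files to compute ground truth for.
#' @return List: `events` (data.frame proc, file, kind, time), `procs`
#'   (data.frame proc, pid, start_time, parent), `targets` (file ids),
#'   `truth` (per target: files, procs, read_edges, write_edges,
#'   spawn_edges).
#' @export
gen_event_log <- function(n_procs, n_files, seed = 1, n_targets = 3) {
  stopifnot(n_procs >= 1, n_files >= 1)
  with_seed(seed, {
    procs <- data.frame(proc = seq_len(n_procs),
                        pid = 10000 + seq_len(n_procs),
                        start_time = 0,
                        parent = NA_real_)
    ## pid reuse: a later proc takes an earlier proc's pid
    if (n_procs >= 4) procs$pid[n_procs] <- procs$pid[1]
    ## spawn links for roughly a third of processes
    for (i in seq_len(n_procs)) if (i > 1 && stats::runif(1) < 0.33)
      procs$parent[i] <- sample(seq_len(i - 1), 1)
    n_ext <- max(1L, ceiling(n_files / 4))      # external roots, never written
    ev <- list(); t <- 0L
    emit <- function(p, f, kind, reps = 1L) {
      for (r in seq_len(reps)) {
        t <<- t + 1L
        ev[[length(ev) + 1L]] <<- c(proc = p, file = f, kind = NA, time = t)
        ev[[length(ev)]]["kind"] <<- kind
      }
    }
    written <- logical(n_files)
    n_ops <- max(4L, n_files * 3L)
    for (k in seq_len(n_ops)) {
      p <- sample(n_procs, 1)
      reps <- sample(c(1L, 1L, 1L, sample(2:5, 1)), 1)   # occasional bursts
      if (stats::runif(1) < 0.55) {
        f <- sample(n_files, 1)
        emit(p, f, "read", reps)
      } else {
        f <- sample(setdiff(seq_len(n_files), seq_len(n_ext)), 1)
        emit(p, f, "write", reps)
        written[f] <- TRUE
      }
    }
    ## guaranteed adversarial shape: a read followed by a later writer of
    ## the same file, which temporal correctness must exclude
    if (n_files > n_ext && n_procs >= 2) {
      f <- n_ext + 1L
      emit(1L, f, "read")
      emit(if (n_procs >= 2) 2L else 1L, f, "write")
      written[f] <- TRUE
    }
    events <- do.call(rbind, lapply(ev, function(x)
      data.frame(proc = as.numeric(x[["proc"]]), file = as.numeric(x[["file"]]),
                 kind = x[["kind"]], time = as.numeric(x[["time"]]),
                 stringsAsFactors = FALSE)))
    procs$start_time <- 0
    cand <- which(written)
    targets <- if (length(cand)) sample(cand, min(n_targets, length(cand)))
               else sample(n_files, 1)
    truth <- lapply(targets, function(tg)
      closure_fixpoint(events, procs, tg))
    names(truth) <- as.character(targets)
    list(events = events, procs = procs, targets = targets, truth = truth)
  })
}

## Exhaustive fixpoint closure used only as generation-time ground truth.
## Tabulates burst starts with rle(), then saturates an inclusion table
## until nothing changes -- deliberately a different algorithm and style
## from both trace_lineage() and brute_force_trace().
closure_fixpoint <- function(events, procs, target) {
  ev <- events[order(events$time), ]
  key <- paste(ev$proc, ev$file, sep = "|")
  starts <- logical(nrow(ev))
  for (k in unique(key)) {
    idx <- which(key == k)
    r <- rle(ev$kind[idx])
    starts[idx[cumsum(c(1, utils::head(r$lengths, -1)))]] <- TRUE
  }
  wb <- ev[starts & ev$kind == "write", ]
  rb <- ev[starts & ev$kind == "read", ]
  bound <- stats::setNames(rep(-Inf, max(events$file)), seq_len(max(events$file)))
  bound[as.character(target)] <- Inf
  in_proc <- logical(max(events$proc))
  we <- list(); re <- list()
  repeat {
    changed <- FALSE
    for (f in which(is.finite(bound) | bound == Inf)) {
      if (bound[[as.character(f)]] == -Inf) next
      hits <- wb[wb$file == f & wb$time < bound[[as.character(f)]], ]
      for (i in seq_len(nrow(hits))) {
        p <- hits$proc[i]; tw <- hits$time[i]
        ek <- paste(p, f, tw)
        if (!ek %in% names(we)) { we[[ek]] <- c(p, f, tw); changed <- TRUE }
        in_proc[p] <- TRUE
        rr <- rb[rb$proc == p & rb$time < tw, ]
        for (j in seq_len(nrow(rr))) {
          g <- rr$file[j]; tr <- rr$time[j]
          rk <- paste(g, p, tr)
          if (!rk %in% names(re)) { re[[rk]] <- c(g, p, tr); changed <- TRUE }
          if (tr > bound[[as.character(g)]]) {
            bound[[as.character(g)]] <- tr
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  files <- sort(unique(c(target,
                         vapply(we, `[`, numeric(1), 2),
                         vapply(re, `[`, numeric(1), 1))))
  pset <- sort(which(in_proc))
  se <- list(); queue <- pset; seen <- pset
  while (length(queue)) {
    p <- queue[1]; queue <- queue[-1]
    pa <- procs$parent[procs$proc == p]
    if (length(pa) == 1 && !is.na(pa)) {
      se[[paste(pa, p)]] <- c(pa, p)
      if (!pa %in% seen) { seen <- c(seen, pa); queue <- c(queue, pa) }
    }
  }
  wdf <- if (length(we)) do.call(rbind, lapply(unname(we), function(x)
    data.frame(proc = x[1], file = x[2], time = x[3])))
    else data.frame(proc = numeric(0), file = numeric(0), time = numeric(0))
  rdf <- if (length(re)) do.call(rbind, lapply(unname(re), function(x)
    data.frame(file = x[1], proc = x[2], time = x[3])))
    else data.frame(file = numeric(0), proc = numeric(0), time = numeric(0))
  sdf <- if (length(se)) do.call(rbind, lapply(unname(se), function(x)
    data.frame(parent = x[1], child = x[2])))
    else data.frame(parent = numeric(0), child = numeric(0))
  list(files = files, procs = sort(unique(seen)),
       read_edges = rdf[order(rdf$time, rdf$file, rdf$proc), , drop = FALSE],
       write_edges = wdf[order(wdf$time, wdf$proc, wdf$file), , drop = FALSE],
       spawn_edges = sdf[order(sdf$parent, sdf$child), , drop = FALSE],
       target = target)
}

#' Replay a raw event log into a provenance store
#'
#' Registers the log's processes and files and feeds the primitive stream
#' through [record_event()] (so coalescing applies), returning the key
#' mappings needed to compare a [trace_lineage()] result with log-level
#' ground truth.
#'
#' @param log A log from [gen_event_log()].
#' @param st A `prov_store`; a fresh in-memory store when omitted.
#' @param n_ext Files `1..n_ext` are registered external, the rest internal.
#' @return List: `store`, `proc_keys`, `file_keys` (named by log ids).
#' @export
replay_log <- function(log, st = prov_store(flush_threshold = 1000L)) {
  pk <- numeric(nrow(log$procs)); names(pk) <- log$procs$proc
  ## record parents before children so parent_key links resolve
  done <- logical(nrow(log$procs))
  while (!all(done)) {
    for (i in seq_len(nrow(log$procs))) {
      if (done[i]) next
      pa <- log$procs$parent[i]
      if (!is.na(pa) && !done[log$procs$proc == pa]) next
      pk[as.character(log$procs$proc[i])] <- record_process(st, list(
        pid = log$procs$pid[i], start_time = log$procs$start_time[i] + i * 1e-4,
        parent_key = if (is.na(pa)) NULL else pk[[as.character(pa)]],
        exe_path = sprintf("/opt/sim/prog%d", log$procs$proc[i]),
        cmdline = sprintf("prog%d", log$procs$proc[i]), cwd = "."))
      done[i] <- TRUE
    }
  }
  files <- sort(unique(log$events$file))
  written <- unique(log$events$file[log$events$kind == "write"])
  fk <- numeric(length(files)); names(fk) <- files
  for (f in files)
    fk[as.character(f)] <- file_register(st, sprintf("sim/file_%d.dat", f),
                                         origin = if (f %in% written) "internal" else "external",
                                         time = 0)
  ev <- log$events[order(log$events$time), ]
  for (i in seq_len(nrow(ev)))
    record_event(st, pk[[as.character(ev$proc[i])]], fk[[as.character(ev$file[i])]],
                 ev$kind[i], time = ev$time[i], bytes = 1)
  list(store = st, proc_keys = pk, file_keys = fk)
}

## -- VDF fixture trees -------------------------------------------------------

#' Generate a VDF fixture tree and matching configuration
#'
#' Writes small FASTQ-like files (4-line records) and delimited tables
#' under `dir`, plus an empty source, and returns a configuration whose
#' rules exercise both a format-conversion task (FASTQ -> FASTA header/
#' sequence extraction, stdout channel) and analysis tasks (column
#' extraction on stdout; sorting through the file channel) using only
#' ubiquitous utilities.
#'
#' @param dir Directory to populate (created).
#' @param seed RNG seed.
#' @return List: `dir`, `config` (a `provtrace_config`), `sources`
#'   (relative paths), and `direct` -- a function(rule_name, source_rel)
#'   returning the bytes of running that rule's command directly (the
#'   comparison oracle).
#' @export
gen_vdf_fixtures <- function(dir, seed = 1) {
  with_seed(seed, {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sources <- character(0)
    for (i in 1:2) {
      n <- sample(5:9, 1)
      ids <- sprintf("@read_%03d", sample(100:999, n))
      seqs <- vapply(seq_len(n), function(j)
        paste(sample(c("A", "C", "G", "T"), sample(20:40, 1), replace = TRUE),
              collapse = ""), "")
      qual <- vapply(nchar(seqs), function(l)
        paste(rep("I", l), collapse = ""), "")
      rel <- sprintf("reads_%d.fastq", i)
      writeLines(as.vector(rbind(ids, seqs, "+", qual)), file.path(dir, rel))
      sources <- c(sources, rel)
    }
    tab <- data.frame(taxon = rand_words(12), count = sample(1:500, 12))
    utils::write.table(tab, file.path(dir, "abund.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    sources <- c(sources, "abund.tsv")
    writeLines(character(0), file.path(dir, "empty.fastq"))
    sources <- c(sources, "empty.fastq")
    config <- default_config(vdf_rules = list(
      vdf_spec("fastq2fasta", "\\.fastq$", ".fasta",
               "awk 'NR % 4 == 1 || NR % 4 == 2' {source} | sed 's/^@/>/'"),
      vdf_spec("taxa", "\\.tsv$", ".taxa", "cut -f1 {source}"),
      vdf_spec("sorted", "\\.tsv$", ".sorted",
               "LC_ALL=C sort {source} > {output}", output_channel = "file")))
    direct <- function(rule_name, source_rel) {
      rule <- NULL
      for (r in config$vdf_rules) if (r$name == rule_name) rule <- r
      stopifnot(!is.null(rule))
      cmd <- gsub("{source}", shQuote(file.path(dir, source_rel)),
                  rule$command_template, fixed = TRUE)
      if (rule$output_channel == "file") {
        of <- tempfile()
        cmd <- gsub("{output}", shQuote(of), cmd, fixed = TRUE)
        processx::run("sh", c("-c", cmd), error_on_status = TRUE)
        out <- readBin(of, raw(), n = file.size(of))
        unlink(of)
        out
      } else {
        of <- tempfile()
        processx::run("sh", c("-c", cmd), stdout = of, error_on_status = TRUE)
        out <- readBin(of, raw(), n = file.size(of))
        unlink(of)
        out
      }
    }
    list(dir = dir, config = config, sources = sources, direct = direct)
  })
}
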