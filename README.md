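# provtrace

File-system-level provenance for computational workflows: record which
process produced every file (command line, working directory, executable
checksum), reconstruct the causal lineage of any file, re-execute the
recorded workflow on another system with software-version verification,
and serve on-demand derived files through a block cache.

## Who this is for

Anyone who has tried to answer "which exact commands, in which order, with
which tool builds, produced this file?" months after the fact — a chronic
problem in bioinformatics, where pipelines chain many tools whose output
depends on versions, parameters and reference data. Container and
environment managers pin versions but cannot verify parameters or data
flow; pipeline frameworks require rewriting the workflow into their
language. `provtrace` instead observes workflows as they run, unmodified,
and makes the record itself executable.

## The model

A *monitored session* over a directory tree records every file operation
as an event linking a **process** (pid, start time, command line, cwd,
SHA-256 of the executable) to a **file version** (a path's content
between writer generations) at a **time** from a single monotonic clock.
High-rate reads/writes are coalesced per (process, file, kind) run into
events carrying first/last time, primitive count and byte total, stored
in an embedded SQLite database.

The lineage of a target file is the closure of two alternating queries
under a temporal-correctness constraint:

1. writers of the file: processes with a write event at `t_w` before the
   bound (the time the file was later read);
2. earlier inputs of each writer: its read events with `t_r < t_w`, each
   read seeding a new iteration of query 1 bounded at `t_r`.

Output is assumed to depend on everything the process read earlier —
reads that began *after* output started, and writes that landed *after* a
dependent read, are excluded. Recursion bottoms out at *external* files
(no recorded writer), the workflow's true inputs. The closure is exported
as a self-contained JSON bundle from which a POSIX shell script is
reconstructed (dependency-ordered; shell wrappers whose children were
captured are skipped), executables are verified by checksum, and the
workflow is re-run in a clean directory with the produced target compared
to the recorded checksum.

*Virtual dynamic files* (VDFs) are the automation half: a configured rule
(`pattern`, appended `extension`, command template) makes every matching
source appear alongside a derived virtual file, materialised on first
read by running the command once per source version, streamed through a
two-tier (memory/disk) block cache in which readers of not-yet-produced
blocks wait until the bytes arrive.

## Worked example

```r
library(provtrace)

pipe <- gen_pipeline(n_stages = 3, branching = 2, seed = 42)  # synthetic workflow
root <- tempfile("workflow")
materialize_pipeline(pipe, root)          # inputs + tool scripts + driver

ctx <- mount_session(root)                # monitored session
run_pipeline(ctx, pipe)                   # stages run as real child processes
g <- trace_lineage(ctx$store, pipe$target)
print(g)
#> provenance graph: 7 file version(s), 4 process(es), 7 read edge(s), 3 write edge(s), 3 spawn edge(s)
#> target: out/stage_03.txt (v0)
```

Seven file versions: two generated inputs, three stage outputs, two tool
scripts (executables are themselves traced inputs). Four processes: three
stages plus the driver script, linked by spawn edges. Export, reconstruct
and replicate:

```r
bundle <- export_bundle(ctx, pipe$target)
session_close(ctx)
cat(reconstruct_script(bundle))
#> #!/bin/sh
#> # reconstructed from recorded provenance
#> set -e
#>
#> mkdir -p 'bin' 'data' 'out'
#>
#> 'bin/tool_merge' 'out/stage_01.txt' 'data/input_2.txt'
#> 'bin/tool_upper' 'out/stage_01.txt' 'out/stage_02.txt'
#> 'bin/tool_merge' 'out/stage_03.txt' 'data/input_1.txt' 'out/stage_02.txt'

report <- replicate_bundle(bundle, tempfile("replica"), inputs_dir = root)
print(report)
#> replication report:
#>   target match: TRUE
#>   processes re-run: 3
#>   environment mismatches: none
```

The driver script is recognised as a wrapper and not re-invoked (its
children are), the three stages re-run in dependency order, and the
replica's target checksum equals the recorded one — byte-identical
replication from the provenance record alone, without the original
driver. Replace a tool with a different build and the report instead
names exactly that executable under `mismatches`, with `target match:
FALSE` if the substitute changes the output.

Rendering and VDFs:

```r
rg <- group_files(g)          # files with identical I/O signatures grouped
cat(graph_to_dot(rg))         # deterministic Graphviz DOT (red/blue/green)

cfg <- default_config(list(vdf_spec(
  "fastq2fasta", "\\.fastq$", ".fasta",
  "awk 'NR % 4 == 1 || NR % 4 == 2' {source} | sed 's/^@/>/'")))
ctx <- mount_session(dir_with_fastqs, config = cfg)
list_directory("", ctx)       # every x.fastq accompanied by x.fastq.fasta
h <- vfs_open(ctx, "reads.fastq.fasta", "r")   # first read launches the command
```

## Command line

A thin launcher over the same API is installed at `exec/provtrace`:

```
provtrace record <source_root> [--db FILE] -- <command> [args...]
provtrace export <db> <target-path> -o bundle.json
provtrace graph  (<db> <target> | bundle.json) [--format dot|json] [--expand PROC]
provtrace script bundle.json
provtrace verify bundle.json [--root DIR] [--json]
provtrace replicate bundle.json --workdir DIR [--inputs DIR]
```

Exit codes: 0 success; 1 usage/runtime error; 2 replication target
mismatch; 3 verification found mismatches.

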