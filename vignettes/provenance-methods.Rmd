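---
title: "Recording, tracing and replicating workflow provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recording, tracing and replicating workflow provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provtrace)
```

## The problem

Computational analyses — bioinformatics pipelines especially — are chains of
tool invocations whose output depends on tool versions, command-line
parameters, reference data and intermediate files. Reproducing a result
months later, or on another machine, requires knowing *exactly* which
process produced each file, what that process read, and which executable
build it ran. `provtrace` records that history at the file-operation level,
reconstructs the causal lineage of any file, re-executes the recorded
workflow elsewhere, and verifies software identity by executable checksum.
It also serves *virtual dynamic files* (VDFs): derived views (a FASTA
projection of every FASTQ, a sorted view of every table) that appear in
directory listings and are materialised on demand by configured commands
through a block cache.

## Architecture: the monitored session

Recording is organised as a *monitored session* over a real directory tree
(`mount_session()`). The session exposes a POSIX-like operation surface —
`vfs_open`, `vfs_read`, `vfs_write`, `vfs_close`, `vfs_create`,
`vfs_rename`, `vfs_unlink`, `vfs_truncate`, `vfs_stat`, `vfs_readdir` —
behind which each operation is (1) recorded in the provenance store with
the identity of the issuing process and (2) routed either to the
underlying file system (a faithful passthrough) or, for virtual paths, to
the VDF engine. This operation interface is deliberately the module
boundary: it is exactly the set of callbacks a userspace-filesystem
(FUSE-style) backend would invoke, so the entire provenance/VDF core runs
and is tested in-process, with simulated or real event sources, and a
kernel mount backend can be layered on top without touching the core. The
command-line interface therefore offers `record` — run a real command
under a monitored session — as its capture entry point.

Two event sources are built in:

* **Simulated callers.** Tests and replayed logs submit operations with an
  explicit `process_record`, giving full control over timing, interleaving
  and adversarial orderings.
* **`session_exec()`.** Runs a real command as a child process and records
  it: the live pid, the resolved executable and its SHA-256 checksum, the
  command line and working directory, read events for declared inputs plus
  any argument token that names an existing file (and the executable
  itself when it lives in the tree), and write events (with content
  checksums) for declared outputs plus files observed changed by a
  before/after tree snapshot. This is the contract of the event source:
  reads a tool performs on files it was never pointed at (config files
  discovered at runtime, say) are visible to a kernel-level interceptor
  but not to the snapshot heuristic. The lineage, replication and
  rendering machinery downstream is agnostic to which source fed it.

Operations issued by the session itself (the daemon) and by the store are
flagged and excluded from recording, preventing self-referential
provenance.

## The provenance store

One SQLite database per session holds processes, file versions and I/O
events. Primitive reads and writes arrive at far higher rates than
anything else, so consecutive same-kind operations by one process on one
file version are *coalesced* into a single event carrying `t_first`,
`t_last`, a primitive count and a byte total; an intervening operation of
a different kind by that process on that file breaks the run. The
in-memory buffer flushes at a configurable threshold (default 10,000
events, a value large enough to amortise insert cost while bounding
memory). A still-open run is persisted at flush but remains extendable —
later primitives update the same row — so query results never depend on
when flushes happened. Coalescing conserves counts: the `count` sums over
coalesced rows always equal the number of primitive operations.

**File versions.** Provenance points at content, not names, so each path
carries a version counter. A new version starts when a path is created or
truncated, and when it is reopened for writing after its previous version
had at least one reader or a completed writer — this keeps read edges
pointing at the bytes actually read. Renames transfer identity (the path
changes, versions and keys are kept). A version's content checksum is
computed once, when its last writer closes, since per-write hashing would
be prohibitive. Versions with no recorded writer are *external*: content
that entered the tree from outside (network, another file system, the
keyboard) — these are the roots at which lineage recursion terminates.

**Timestamps** come from a single monotonic clock owned by the store
(sub-millisecond, strictly increasing), which makes the temporal
constraint below well defined across interleaved recorders.

## Lineage: the two-query closure

`trace_lineage()` reconstructs the provenance of a target file version by
alternating two queries until closure:

1. *Who wrote this file?* — all write/create/truncate events on the
   version, bounded (for recursive steps) to those beginning before the
   dependent read.
2. *What did that process read earlier?* — all read events by the writer
   beginning before the write.

Each file returned by query 2 seeds a new iteration of query 1 with its
read time as the bound. In place of an (infeasible) dataflow analysis of
the programs themselves, output is assumed to depend on everything the
process read earlier; the *temporal constraint* — only reads that began
before the write's first byte, and only writes that began before the
dependent read, are admitted — is what keeps that assumption sound. A
writer that modified an input *after* the dependent process read it is
excluded. "Before the write" is anchored at the write event's `t_first`
(the first byte written): conservative, and well defined on coalesced
events. Each recursion step moves strictly backward in time, so the trace
terminates on any finite record, and the time-oriented graph is acyclic.
Recorded process ancestry is attached as spawn edges, so shell scripts
appear as parents of the tool processes they launched.

The correctness case rests on redundancy: `brute_force_trace()` computes
the same closure by naive repeated scanning of the raw primitive stream
(it never touches a store), and the synthetic-log generator computes
ground truth at generation time by an exhaustive fixpoint — three
independent implementations whose agreement is asserted over hundreds of
randomized logs, including planted temporal-exclusion cases, multi-writer
files, burst runs and pid reuse. Because the store coalesces, both
oracles anchor the temporal rule at *burst starts* (the first primitive
of a maximal same-kind run per process/file pair), which is exactly what
coalesced `t_first` exposes.

One interpretive choice: only data reads create dependency edges;
`stat`/`readdir` traffic is not provenance-relevant and is not persisted.
Environment variables are not part of the recorded process context.

## Rendering

`group_files()` renders a traced graph the way a person wants to read it:
file nodes with identical (reader set, writer set) signatures collapse
into one counted group node, and spawned children are hidden under their
parent script in the default top-level view (`expand_process()` reveals
them, re-attaching their I/O edges; collapsing restores the prior
rendering exactly). The target is never absorbed into a group, so the
anchor of the lineage stays visible. Grouping conserves files — member
counts sum to the original file count — and the grouped edge set is the
signature-quotient of the original, both asserted against naive
recomputations. `graph_to_dot()` emits deterministic Graphviz DOT
(processes red, files blue, the target green, ordering stable so equal
renderings are byte-equal); `graph_to_json()` mirrors the structure for
programmatic use.

## Replication

`export_bundle()` packages a trace into a self-contained JSON document:
file versions with checksums, full process records (command line, working
directory, executable path and SHA-256, recorded with the algorithm name),
all edges, and the external inputs with their checksums. Paths are
mount-relative — recorded once against the session root — so bundles are
relocatable. Serialisation is canonical: export → write → read → write is
byte-identical, and import is gated on a schema version.

`reconstruct_script()` emits a POSIX shell script that re-invokes every
*leaf* process with its recorded command line, topologically ordered by
the writes-before-reads dependency relation with recorded start time as
tie-break. Shell-interpreter processes whose children were captured are
wrappers: re-invoking both the script and its children would run the work
twice, so wrappers are skipped and their children re-executed directly —
which is also why a workflow replicates even when the original driver
script was never copied.

`verify_environment()` resolves each recorded executable (recorded path
first — relative paths against the replication directory — then the
search path), checksums it and reports every mismatch or absence.
`replicate_bundle()` stages the external inputs into a clean directory,
verifies, re-executes in dependency order (under a fresh monitored
session, so the replica gains its own provenance record), and compares
the produced target's checksum with the recorded one. Checksum equality
is the tool's fidelity criterion. Version mismatches warn but do not
abort: a rebuilt tool may still produce identical output, and the report
then shows `target_match` true with the warning retained; an
output-altering substitute shows both the mismatch and a failed target
check.

## Virtual dynamic files

A VDF rule (`vdf_spec()`) names a source pattern, an extension appended to
the *full* source name (`reads.fastq` → `reads.fastq.fasta`, which avoids
collisions between sources differing only in extension), a command
template with `{source}` (and `{output}` for file-channel commands), and
an output channel. Rules sharing an extension would produce colliding
virtual names, so duplicates are rejected at configuration load. Rules
chain: a rule matching `.fasta` applies to the virtual FASTA of a FASTQ.

The first read of a missing block launches the command — exactly once per
(rule, source version) — and its output streams into a two-tier block
cache. Completed blocks become ready in the memory tier as bytes arrive;
readers of not-yet-produced blocks wait (the engine polls the task's
output stream) until their block is ready, production ends (end-of-data:
an empty read), or the task fails (the error surfaces to every waiting
reader, with a configurable timeout as backstop). When memory occupancy
exceeds the limit, ready blocks spill to the disk tier oldest-first —
least recently accessed, production order as tie-break — and spilled
blocks promote back to memory on access. Ready blocks never change. The
cache key is the source file *version*, so editing the source invalidates
the cache and the next access runs a fresh task; the disk tier is
session-local (regeneration, not persistence, is the contract), and VDFs
are read-only.

Defaults: 128 KiB blocks, 256 MiB memory tier — sized so that typical
text-conversion VDFs stay memory-resident while a pathological output
still degrades to disk gracefully; both are configurable, and the content
identity of the served bytes is invariant under any block-size/limit
combination (asserted down to 32-byte blocks with a 64-byte memory tier).
An unmaterialised VDF reports its bytes-produced-so-far as its size (0
before the first read); consumers must treat short reads as end-of-data,
which stream-copying tools do. Task provenance is recorded — the
generating command as a process, its read of the source, its write of the
virtual file — so lineage flows through VDFs.

## The synthetic workloads

Everything is testable offline because the package generates its own
study conditions, all pure functions of a seed:

* `gen_pipeline(n_stages, branching, seed)` builds multi-stage workflows
  (1–8 stages, branching 1–3 in the shipped checks) from five small POSIX
  tool scripts (sort, case-map, substitute, truncate, concatenate) over
  generated word-list inputs. The tools are deterministic by construction
  (no timestamps, fixed locale), so replication must be byte-exact; the
  expected target checksum is frozen by a single reference execution in a
  scratch directory at generation time, and the expected lineage topology
  is derived analytically from the stage list. The tools live in the
  monitored tree as ordinary files, which makes them both checksummable
  executables for mismatch experiments and external inputs for
  replication.
* `gen_event_log(n_procs, n_files, seed)` emits primitive event streams
  with planted adversarial shapes: a guaranteed post-read writer, multi-
  writer files, same-kind bursts (exercising coalescing), never-written
  external roots, pid reuse, and spawn links — with ground truth computed
  at generation time by an algorithm (`rle`-based fixpoint saturation)
  deliberately unlike either tracer.
* `gen_vdf_fixtures(dir, seed)` writes FASTQ-like records and delimited
  tables plus rules covering both channels, and returns a `direct()`
  oracle that runs each rule's command outside the engine for comparison.

These workloads emulate the *structure* of real pipelines (fan-in,
fan-out, wrappers, version churn), not their scale or their biology: no
real aligner's I/O pattern, no memory-mapped access, no concurrent
multi-host writers. Passing them demonstrates the bookkeeping is exact
under the recorded event model, not that every access pattern of every
tool is captured — that boundary lives in the event source, as discussed
above.

## Numerical and degenerate-input choices

* Checksums are SHA-256 throughout, stored with the algorithm name;
  unavailable checksums (unreadable executable, raced exit) are recorded
  as `"unavailable"`, never invented.
* The store clock advances by at least 1 microsecond per draw, so equal
  timestamps cannot arise within a session; replayed logs may carry their
  own (strictly increasing) times.
* Empty VDF sources produce empty virtual files (a zero-length read, not
  an error); reads past end-of-data return empty; a deleted-then-recreated
  path continues its version numbering.
* An external-origin target exports a bundle with zero processes;
  reconstructing a script from it is an error stating why.
* Problem sizes in the shipped checks — 100 randomized logs up to 100
  processes / 500 files, four pipeline shapes up to 8 stages × branching
  3, a 10,000-operation mixed workload — were chosen as the smallest sizes
  that exercise every planted adversarial shape several times over.

## Known limitations

* Without a kernel-mount backend, capture via `session_exec()` sees
  declared and argument-named inputs plus snapshot-detected outputs, not
  every syscall of an uncooperative tool.
* Provenance does not cross sessions or file systems; bundles are
  self-contained precisely so they can.
* Replication re-executes commands; tools that are themselves
  nondeterministic (timestamps in output, unseeded randomness) cannot
  replicate byte-identically — the report will say so via the checksum
  comparison, which is the correct answer, but distinguishing "tool is
  nondeterministic" from "environment differs" is up to the reader of the
  mismatch report.
* Verification compares whole-file checksums; it does not diff outputs or
  attribute a mismatch to a particular stage beyond the executables it
  names.

## A worked example

```{r example, eval = FALSE}
pipe <- gen_pipeline(n_stages = 3, branching = 2, seed = 42)
root <- tempfile("workflow")
materialize_pipeline(pipe, root)

ctx <- mount_session(root)
run_pipeline(ctx, pipe)
bundle <- export_bundle(ctx, pipe$target)
session_close(ctx)

cat(reconstruct_script(bundle))
report <- replicate_bundle(bundle, tempfile("replica"), inputs_dir = root)
report$target_match          # TRUE: byte-identical replication
```
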