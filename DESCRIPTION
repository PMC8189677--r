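Package: provtrace
Title: File-System Provenance Capture, Lineage Tracing, Workflow
    Replication and Virtual Dynamic Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Records complete file and process provenance for workflows run
    under a monitored directory tree: every file operation is captured
    together with the identity of the process that issued it (command line,
    working directory, executable checksum) and persisted in an embedded SQL
    database with in-memory coalescing of high-throughput reads and writes.
    The lineage of any file can be reconstructed by an iterative two-query
    trace with a temporal-correctness constraint, rendered as a grouped
    provenance graph (DOT or JSON), exported as a portable replication
    bundle, and re-executed elsewhere with software-version verification by
    executable checksum. Also serves virtual dynamic files: on-demand views
    computed by configured shell commands and streamed through a two-tier
    (memory/disk) block cache with blocking reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    digest,
    jsonlite,
    processx,
    ps,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
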