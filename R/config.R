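## Configuration: VDF rules, cache limits, store and logging settings.

#' Define a virtual-dynamic-file rule
#'
#' A VDF rule declares that every real file whose name matches
#' `source_pattern` is accompanied by a virtual file named
#' `<source name><extension>`, whose content is produced on demand by
#' `command_template`. The template must contain the placeholder `{source}`;
#' when `output_channel = "file"` it must also contain `{output}`, the path
#' the command writes its result to (stdout-channel commands stream their
#' standard output instead).
#'
#' @param name Unique rule identifier.
#' @param source_pattern Regular expression matched against the source file
#'   name (not its directory part).
#' @param extension Suffix appended to the full source name; must begin
#'   with `"."`.
#' @param command_template Shell command with `{source}` (and `{output}` for
#'   file-channel rules) placeholders.
#' @param output_channel `"stdout"` or `"file"`.
#' @return A `vdf_spec` object.
#' @export
#' @examples
#' vdf_spec("fastq2fasta", "\\.fastq$", ".fasta",
#'          "awk 'NR % 4 == 1 || NR % 4 == 2' {source} | sed 's/^@/>/'")
vdf_spec <- function(name, source_pattern, extension, command_template,
                     output_channel = c("stdout", "file")) {
  output_channel <- match.arg(output_channel)
  if (!is_scalar_string(name) || !nzchar(name))
    stop("VDF rule needs a non-empty name", call. = FALSE)
  if (!is_scalar_string(extension) || !startsWith(extension, ".") || nchar(extension) < 2)
    stop(sprintf("rule '%s': extension must be non-empty and begin with '.'", name),
         call. = FALSE)
  if (!is_scalar_string(command_template) || !grepl("{source}", command_template, fixed = TRUE))
    stop(sprintf("rule '%s': command template must contain the {source} placeholder", name),
         call. = FALSE)
  if (output_channel == "file" && !grepl("{output}", command_template, fixed = TRUE))
    stop(sprintf("rule '%s': file-channel command template must contain the {output} placeholder",
                 name), call. = FALSE)
  structure(list(name = name, source_pattern = source_pattern,
                 extension = extension, command_template = command_template,
                 output_channel = output_channel),
            class = "vdf_spec")
}

#' Default configuration
#'
#' Cache defaults: 128 KiB blocks, 256 MiB memory tier. Store default:
#' coalescing buffer flushed every 10,000 events.
#'
#' @param vdf_rules List of [vdf_spec()] objects.
#' @return A `provtrace_config` object.
#' @export
default_config <- function(vdf_rules = list()) {
  cfg <- structure(list(
    vdf_rules = vdf_rules,
    cache = list(block_size = 131072L, memory_limit = 268435456, disk_tier = NULL),
    store = list(db_path = NULL, flush_threshold = 10000L),
    log = list(level = "warn", destination = "stderr")
  ), class = "provtrace_config")
  validate_config(cfg)
}

#' Parse a configuration file
#'
#' The configuration is YAML with sections `vdf` (a list of rules with keys
#' `name`, `pattern`, `extension`, `command`, `channel`), `cache`
#' (`block_size`, `memory_limit`, `disk_tier`), `store` (`db_path`,
#' `flush_threshold`) and `log` (`level`, `destination`). Omitted cache and
#' store fields take the defaults of [default_config()]. Malformed rules
#' (duplicate names, duplicate extensions, empty extension, missing
#' placeholder) are load-time errors naming the offending rule.
#'
#' @param text Configuration text, or a path to a file when `file = TRUE`.
#' @param file Treat `text` as a file path.
#' @return A validated `provtrace_config`.
#' @export
parse_config <- function(text, file = FALSE) {
  raw <- if (file) yaml::read_yaml(text) else yaml::yaml.load(text)
  raw <- raw %||% list()
  rules <- lapply(raw$vdf %||% list(), function(r) {
    vdf_spec(name = r$name %||% "", source_pattern = r$pattern %||% "",
             extension = r$extension %||% "", command_template = r$command %||% "",
             output_channel = r$channel %||% "stdout")
  })
  cfg <- default_config()
  cfg$vdf_rules <- rules
  for (k in intersect(names(raw$cache %||% list()), names(cfg$cache)))
    cfg$cache[[k]] <- raw$cache[[k]]
  for (k in intersect(names(raw$store %||% list()), names(cfg$store)))
    cfg$store[[k]] <- raw$store[[k]]
  for (k in intersect(names(raw$log %||% list()), names(cfg$log)))
    cfg$log[[k]] <- raw$log[[k]]
  validate_config(cfg)
}

## Plain-list view of a config (for JSON snapshots).
config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$vdf_rules <- lapply(out$vdf_rules, unclass)
  out
}

validate_config <- function(cfg) {
  nm <- vapply(cfg$vdf_rules, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicate VDF rule name: ", nm[duplicated(nm)][1], call. = FALSE)
  ## Two rules with the same appended extension produce the same virtual
  ## name for any source both patterns match; reject outright.
  ext <- vapply(cfg$vdf_rules, `[[`, "", "extension")
  if (anyDuplicated(ext))
    stop("VDF rules '", paste(nm[ext == ext[duplicated(ext)][1]], collapse = "', '"),
         "' share extension '", ext[duplicated(ext)][1],
         "' and would produce colliding virtual names", call. = FALSE)
  for (f in c("block_size", "memory_limit"))
    if (!is.numeric(cfg$cache[[f]]) || cfg$cache[[f]] <= 0)
      stop("cache ", f, " must be a positive number", call. = FALSE)
  if (!is.numeric(cfg$store$flush_threshold) || cfg$store$flush_threshold < 1)
    stop("store flush_threshold must be >= 1", call. = FALSE)
  cfg
}
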