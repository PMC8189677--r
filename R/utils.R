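#' @keywords internal
"_PACKAGE"

CHECKSUM_ALGO <- "sha256"

## SHA-256 of a file; NA_character_ when unreadable/absent.
file_checksum <- function(path) {
  if (!file.exists(path) || dir.exists(path)) return(NA_character_)
  out <- tryCatch(digest::digest(path, algo = CHECKSUM_ALGO, file = TRUE),
                  error = function(e) NA_character_)
  out
}

## Normalise a path to forward slashes without resolving symlinks.
norm_slash <- function(p) gsub("\\\\", "/", p)

## Join and collapse a mount-relative path; reject escapes above the root.
rel_clean <- function(path) {
  path <- norm_slash(path)
  path <- sub("^\\./", "", path)
  path <- sub("^/", "", path)
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  parts <- parts[parts != "" & parts != "."]
  out <- character(0)
  for (p in parts) {
    if (p == "..") {
      if (length(out) == 0L) stop("path escapes the monitored tree: ", path, call. = FALSE)
      out <- out[-length(out)]
    } else out <- c(out, p)
  }
  paste(out, collapse = "/")
}

## Stable short identifier for a mount session.
new_session_id <- function() {
  paste0(format(Sys.time(), "%Y%m%d%H%M%S"), "-",
         paste(sample(c(letters, 0:9), 8, replace = TRUE), collapse = ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Minimal structured logger: "<iso time> <level> [<session>] <msg>".
pt_log <- function(ctx_or_level, ..., level = NULL) {
  if (inherits(ctx_or_level, "mount_ctx")) {
    ctx <- ctx_or_level
    lvl <- level %||% "info"
    conf <- ctx$config$log
    sess <- ctx$session_id
  } else {
    ctx <- NULL
    lvl <- ctx_or_level
    conf <- list(level = "warn", destination = "stderr")
    sess <- "-"
  }
  ranks <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (ranks[[lvl]] < ranks[[conf$level %||% "warn"]]) return(invisible(NULL))
  line <- sprintf("%s %-5s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  toupper(lvl), sess, paste0(..., collapse = ""))
  dest <- conf$destination %||% "stderr"
  if (identical(dest, "stderr")) message(line) else cat(line, "\n", file = dest, append = TRUE)
  invisible(NULL)
}
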