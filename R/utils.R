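# Internal helpers shared across readers.

# A single string is treated as a file path when it exists on disk and does
# not look like inline content; otherwise as literal text.
looks_like_path <- function(x) {
  length(x) == 1L && is.character(x) && !grepl("[\n<>]", x) && file.exists(x)
}

# Return the lines of `x`, which may be a file path, a single string with
# embedded newlines, or an already-split character vector.
as_text_lines <- function(x) {
  if (looks_like_path(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  x
}

# Strip a leading "something:" qualifier (e.g. organism code, "rn:", "ec:")
# from identifiers, preserving case of the identifier proper.
strip_prefix <- function(x) {
  sub("^[A-Za-z0-9._-]+:", "", x)
}

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
  invisible(x)
}

assert_numeric_finite <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", name))
  }
  bad <- if (allow_na) !is.na(x) & !is.finite(x) else !is.finite(x)
  if (any(bad)) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}
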