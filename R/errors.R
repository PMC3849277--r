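# Classed conditions so callers (and the CLI) can map failures to exit codes.

gf_error <- function(msg, class) {
  stop(structure(
    class = c(class, "gf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# Accept a file path, a single string with embedded newlines, or a character
# vector of lines.
.gf_read_lines <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) {
      return(readLines(x, warn = FALSE))
    }
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  }
  as.character(x)
}
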