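# Classed error/warning conditions so the CLI can map error families to
# distinct exit codes and tests can assert on the failure class.

ko_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("crisprko_", class), "crisprko_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

ko_warning <- function(class, message) {
  warning(structure(
    class = c(paste0("crisprko_", class), "crisprko_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# 1-based inclusive substring; the single point where coordinates meet strings
subseq1 <- function(seq, start, end) {
  substr(seq, start, end)
}
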