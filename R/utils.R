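#' @keywords internal
"_PACKAGE"

## internal assertion helpers -------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(class = c("beatformer_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("beatformer_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("beatformer_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
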