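#' @keywords internal
#' Signal a classed error.
#'
#' All user-facing failures in the package raise conditions whose class
#' vector contains both a specific class (e.g. "nirparity_missing_file")
#' and the umbrella class "nirparity_error", so callers can test for either.
#' @noRd
np_stop <- function(class, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "nirparity_error"),
                      call = call))
}

#' @noRd
np_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) np_stop(class, msg, ..., call = sys.call(-2))
  invisible(TRUE)
}
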