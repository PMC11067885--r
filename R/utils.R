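#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of distinct pull rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pchisq sd setNames
NULL

# Condition helpers: every user-facing failure carries a scramblr_* class so
# callers (and tests) can distinguish parse, validation, configuration and
# domain errors.
stop_parse <- function(msg, ...) {
  abort(msg, class = c("scramblr_parse_error", "scramblr_error"), ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = c("scramblr_validation_error", "scramblr_error"), ...)
}

stop_config <- function(msg, ...) {
  abort(msg, class = c("scramblr_config_error", "scramblr_error"), ...)
}

stop_domain <- function(msg, ...) {
  abort(msg, class = c("scramblr_domain_error", "scramblr_error"), ...)
}

notify <- function(msg) {
  inform(msg, class = "scramblr_notice")
}

# Width of 0-based half-open intervals.
iv_width <- function(start, end) end - start

# TRUE where half-open [s1,e1) and [s2,e2) share at least one base.
iv_overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Count, for each half-open interval [s,e), how many of the sorted points p
# fall strictly inside (s < p < e).  Coordinates are integers.
points_strictly_inside <- function(start, end, points_sorted) {
  if (length(points_sorted) == 0L || length(start) == 0L) {
    return(integer(length(start)))
  }
  findInterval(end - 1L, points_sorted) - findInterval(start, points_sorted)
}

# Deterministic integer formatting for file output.
fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

`%&&%` <- function(x, y) if (is.null(x)) NULL else y
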