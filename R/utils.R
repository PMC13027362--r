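#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "rorscreen_validation_error", ...)
}

chk_flag <- function(x, name) {
  if (!rlang::is_bool(x)) abort_validation(sprintf("`%s` must be TRUE or FALSE.", name))
  x
}

chk_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    abort_validation(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

chk_prob <- function(x, name, lower = 0, upper = 1,
                     open_lower = TRUE, open_upper = TRUE, n = 1L) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_validation(sprintf("`%s` must be numeric with no missing values.", name))
  }
  if (!is.null(n) && length(x) != n) {
    abort_validation(sprintf("`%s` must have length %d.", name, n))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!all(lo_ok & hi_ok)) {
    abort_validation(sprintf(
      "`%s` must lie in %s%g, %g%s.", name,
      if (open_lower) "(" else "[", lower, upper, if (open_upper) ")" else "]"
    ))
  }
  as.numeric(x)
}

chk_cells <- function(a, b, c, d) {
  cells <- list(a = a, b = b, c = c, d = d)
  for (nm in names(cells)) {
    x <- cells[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort_validation(sprintf("Cell `%s` must contain non-negative integers.", nm))
    }
  }
  ns <- lengths(cells)
  if (!all(ns %in% c(1L, max(ns)))) {
    abort_validation("Cells a, b, c, d must have equal length (or length 1).")
  }
  invisible(NULL)
}

# round() uses banker's rounding; published tables use half-up at 3 d.p.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
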