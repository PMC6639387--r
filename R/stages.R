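#' Cognitive stage from the MMSE total
#'
#' Fixed cut points (not data-driven tertiles): T3 for 28-30, T2 for 25-27,
#' T1 for 24 and below.
#'
#' @param mmse_total integer vector of MMSE totals in [0, 30].
#' @return Factor with levels `T3`, `T2`, `T1` (declining cognition).
#' @export
#' @examples
#' assign_stage(c(30, 28, 27, 25, 24, 0))
assign_stage <- function(mmse_total) {
  m <- as.numeric(mmse_total)
  if (any(!is.finite(m)) || any(m < 0 | m > 30) || any(m != round(m)))
    stop("MMSE totals must be integers in [0, 30]", call. = FALSE)
  factor(ifelse(m >= 28, "T3", ifelse(m >= 25, "T2", "T1")),
         levels = c("T3", "T2", "T1"))
}
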