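#' Regulatory thresholds for the four deterioration indices
#'
#' Defaults: acid value 5 mg/g, total polar compounds 27\%, triacylglycerol
#' polymers 10\%, trans fatty acids 2\%.
#'
#' @param av,tpc,tgp,tfa positive per-index limits.
#' @return Named numeric vector of thresholds.
#' @export
default_thresholds <- function(av = 5, tpc = 27, tgp = 10, tfa = 2) {
  th <- c(av = av, tpc = tpc, tgp = tgp, tfa = tfa)
  if (any(!is.finite(th)) || any(th <= 0)) stop("thresholds must be positive")
  th
}

#' Deterioration verdict for an indicator vector
#'
#' The oil is declared deteriorated when at least one index surpasses its
#' threshold. "Surpasses" is read as strict inequality: a value exactly at the
#' regulatory limit is still compliant (limits are phrased "no more than").
#' Set \code{strict = FALSE} to trigger at equality instead.
#'
#' @param v numeric vector or one-row data frame with entries \code{av},
#'   \code{tpc}, \code{tgp}, \code{tfa}. Negative predicted values are allowed
#'   and simply never trigger.
#' @param thresholds see \code{\link{default_thresholds}}.
#' @param strict use \code{>} (default) rather than \code{>=}.
#' @return A list with \code{deteriorated} (logical), \code{triggered}
#'   (character subset of the four index names) and \code{margins}
#'   (value minus threshold, per index).
#' @export
#' @examples
#' classify_deterioration(c(av = 2.4, tpc = 17.7, tgp = 10.12, tfa = 0.14))
classify_deterioration <- function(v, thresholds = default_thresholds(),
                                   strict = TRUE) {
  if (is.data.frame(v)) v <- unlist(v[1, INDICATORS])
  v <- v[INDICATORS]
  if (any(!is.finite(v))) stop("non-finite indicator values")
  thresholds <- thresholds[INDICATORS]
  margins <- v - thresholds
  hit <- if (strict) margins > 0 else margins >= 0
  list(deteriorated = any(hit),
       triggered = INDICATORS[hit],
       margins = margins)
}
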