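#' Rank-based probit (normal-scores) transformation
#'
#' Maps values onto an approximately standard-normal scale by passing their
#' midranks through the standard-normal quantile function.  The transform is
#' rank-invariant: any strictly increasing distortion of the input leaves the
#' scores unchanged, which is what makes the probit-shift AUC correction
#' applicable to arbitrarily skewed biomarkers.
#'
#' The empirical CDF is offset so that scores are always finite:
#' \describe{
#'   \item{`"vdw"`}{van der Waerden scores, \eqn{\Phi^{-1}\{r/(n+1)\}} (default);}
#'   \item{`"blom"`}{Blom scores, \eqn{\Phi^{-1}\{(r-3/8)/(n+1/4)\}}.}
#' }
#' Ties receive midranks and therefore identical scores, consistent with the
#' tie handling of the Mann-Whitney AUC estimator.
#'
#' @param x Numeric vector of at least two finite values.
#' @param convention ECDF offset convention, `"vdw"` or `"blom"`.
#' @return A numeric vector of finite probit scores, same length and order
#'   as `x`.
#' @examples
#' normal_scores(c(1, 2, 3))           # -0.674, 0, 0.674
#' normal_scores(c(10, 10))            # full tie -> both 0
#' normal_scores(exp(c(1, 2, 3)))      # rank invariance: same as first call
#' @export
normal_scores <- function(x, convention = c("vdw", "blom")) {
  convention <- match.arg(convention)
  .check_finite(x, "x")
  n <- length(x)
  if (n < 2L) {
    stop("`x` must contain at least 2 values to define an empirical scale.",
         call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  p <- switch(convention,
    vdw  = r / (n + 1),
    blom = (r - 3 / 8) / (n + 1 / 4)
  )
  stats::qnorm(p)
}
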