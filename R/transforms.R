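# SNP-array signal transforms: theta, B-allele fraction, log R ratio.
# These operate marker-wise on the two allele-channel intensities of a SNP
# array and are the formula layer underneath HMM/segmentation CNV callers.

#' Allelic-contrast theta transform
#'
#' Maps the two channel intensities of a SNP marker to a bounded allelic
#' contrast: \code{theta = 2/pi * atan(num/den)}, a value in [0, 1] that is 0
#' when the numerator channel is silent and 1 when the denominator channel
#' is silent.
#'
#' The \code{orientation} argument selects which channel is the numerator.
#' \code{"A_over_B"} computes \code{2/pi * atan(R_A/R_B)}, which increases
#' with the A allele; \code{"B_over_A"} is the conventional orientation in
#' which theta increases with the B allele so that genotype cluster medians
#' satisfy \code{theta_AA < theta_AB < theta_BB} as required by
#' \code{\link{baf_from_theta}}.  Both are exposed because published
#' formulations differ; the default is \code{"A_over_B"}.
#'
#' @param R_A,R_B non-negative channel intensities (vectors recycle).
#' @param orientation \code{"A_over_B"} or \code{"B_over_A"}.
#' @return theta values in [0, 1].
#' @examples
#' theta_transform(1, 1)              # 0.5
#' theta_transform(1, 0)              # 1
#' @export
theta_transform <- function(R_A, R_B,
                            orientation = c("A_over_B", "B_over_A")) {
  orientation <- match.arg(orientation)
  if (any(R_A < 0 | R_B < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (any(R_A == 0 & R_B == 0)) {
    stop("both channel intensities are zero", call. = FALSE)
  }
  num <- if (orientation == "A_over_B") R_A else R_B
  den <- if (orientation == "A_over_B") R_B else R_A
  ifelse(den == 0, 1, 2 / pi * atan(num / den))
}

#' B-allele fraction from theta
#'
#' Piecewise-linear interpolation of an observed theta against the three
#' genotype-specific cluster medians \code{theta_AA < theta_AB < theta_BB}
#' (medians of theta over all samples for each called genotype):
#' \itemize{
#'   \item 0 below \code{theta_AA};
#'   \item \code{0.5 * (theta - theta_AA) / (theta_AB - theta_AA)} between
#'     \code{theta_AA} and \code{theta_AB};
#'   \item \code{0.5 + 0.5 * (theta - theta_AB) / (theta_BB - theta_AB)}
#'     between \code{theta_AB} and \code{theta_BB};
#'   \item 1 above \code{theta_BB}.
#' }
#' The cluster boundaries themselves are assigned by continuity (the linear
#' branches attain 0, 0.5 and 1 there).  The result is monotone in theta and
#' deviates from {0, 0.5, 1} inside CNVs.
#'
#' @param theta observed theta values.
#' @param theta_AA,theta_AB,theta_BB genotype cluster medians, strictly
#'   increasing.
#' @return BAF values in [0, 1].
#' @examples
#' baf_from_theta(0.35, 0.2, 0.5, 0.8)  # 0.25
#' @export
baf_from_theta <- function(theta, theta_AA, theta_AB, theta_BB) {
  if (!(theta_AA < theta_AB && theta_AB < theta_BB)) {
    stop("cluster medians must satisfy theta_AA < theta_AB < theta_BB",
         call. = FALSE)
  }
  low <- 0.5 * (theta - theta_AA) / (theta_AB - theta_AA)
  high <- 0.5 + 0.5 * (theta - theta_AB) / (theta_BB - theta_AB)
  out <- ifelse(theta <= theta_AA, 0,
         ifelse(theta <= theta_AB, low,
         ifelse(theta <= theta_BB, high, 1)))
  out
}

#' Log R ratio
#'
#' Marker-wise log2 ratio of observed total intensity to its expectation:
#' \code{log2(R_obs) - log2(R_exp)}.  Negative under a deletion, positive
#' under a duplication; the basic input of all array CNV callers.
#'
#' @param R_obs,R_exp positive total intensities (vectors recycle).
#' @return LRR values (log2 units).
#' @examples
#' log2_ratio(2, 1)   # 1
#' log2_ratio(1, 2)   # -1
#' @export
log2_ratio <- function(R_obs, R_exp) {
  if (any(R_obs <= 0) || any(R_exp <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  log2(R_obs) - log2(R_exp)
}
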