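#' Fiducial registration error
#'
#' Mean Euclidean distance, after applying the estimated device-to-MRI
#' transform, between the digitized MEG fiducials and the fiducials marked
#' on the MRI — the standard proxy for coregistration error.
#'
#' @param T Estimated `ng_transform` (device to MRI world).
#' @param fids_meg,fids_mri 3 x 3 matrices with rows `nasion`, `lpa`, `rpa`,
#'   or `ng_points` objects containing the three fiducials.
#' @return Mean distance in mm.
#' @export
fiducial_registration_error <- function(T, fids_meg, fids_mri) {
  if (inherits(fids_meg, "ng_points")) fids_meg <- fiducial_matrix(fids_meg)
  if (inherits(fids_mri, "ng_points")) fids_mri <- fiducial_matrix(fids_mri)
  fids_meg <- as.matrix(fids_meg)
  fids_mri <- as.matrix(fids_mri)
  if (!all(dim(fids_meg) == c(3, 3)) || !all(dim(fids_mri) == c(3, 3)))
    stop("three fiducials required on each side")
  if (!is.null(rownames(fids_meg)) && !is.null(rownames(fids_mri)))
    fids_mri <- fids_mri[rownames(fids_meg), , drop = FALSE]
  mapped <- apply_transform(T, fids_meg)
  mean(sqrt(rowSums((mapped - fids_mri)^2)))
}

#' Exclude anterior-inferior (nose) points from a head point set
#'
#' Removes exactly the points with y > 0 and z < 0 (strict inequalities) in
#' the MEG head frame, i.e. anterior to the fiducial-defined origin and
#' below the LPA-RPA-nasion plane — the region where nose points live.
#' Fiducials are never removed. The rule is frame-dependent, so the input
#' must be tagged as being in the head frame.
#'
#' @param pts `ng_points` in the `head` frame.
#' @return `ng_points` with the rule-matching non-fiducial points removed.
#' @export
exclude_nose_points <- function(pts) {
  stopifnot(inherits(pts, "ng_points"))
  if (!identical(pts$frame, "head"))
    stop("nose-point exclusion is defined in the 'head' frame; got '",
         pts$frame, "'")
  is_fid <- pts$labels %in% c("nasion", "lpa", "rpa")
  drop <- pts$points[, 2] > 0 & pts$points[, 3] < 0 & !is_fid
  subset_points(pts, !drop)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-tailed signed-rank test: zero differences are dropped, tied absolute
#' differences get mid-ranks, the null distribution of the positive-rank sum
#' is computed exactly (generating-function convolution over the realized
#' ranks, which handles ties) for n <= 25 and by normal approximation with
#' continuity correction (tie-corrected variance) above.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return An `ng_stat` list: `statistic` (positive-rank sum minus its null
#'   mean, so swapping x and y negates it), `w_plus`, `p_value`, `n`
#'   (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test undefined")
  if (n < 5) stop("fewer than 5 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  S <- n * (n + 1) / 2
  if (n <= 25) {
    # exact null distribution of W+ over the 2^n sign assignments via
    # polynomial convolution on doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    probs <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs[seq_len(length(probs) - ri)])
      probs <- (probs + shifted) / 2
    }
    support <- (seq_along(probs) - 1) / 2
    wl <- min(W, S - W)
    lo <- sum(probs[support <= wl + 1e-9])
    hi <- sum(probs[support >= S - wl - 1e-9])
    p <- min(1, if (S - wl - wl < 1e-9) 1 else lo + hi)
    method <- "wilcoxon signed-rank (exact)"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (W - S / 2)
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "wilcoxon signed-rank (normal approximation)"
  }
  structure(list(statistic = W - S / 2, w_plus = W, p_value = p, n = n,
                 method = method), class = "ng_stat")
}

#' Welch t test
#'
#' Two-sided t test: unpaired with Welch-Satterthwaite degrees of freedom
#' (unequal variances), or a one-sample t on the differences when
#' `paired = TRUE`.
#'
#' @param x,y Numeric samples (paired requires equal length).
#' @param paired Treat as paired samples.
#' @return An `ng_stat` list: `statistic` (t), `df`, `p_value`, `n`, `method`.
#' @export
welch_t <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    d <- x - y
    n <- length(d)
    if (n < 2) stop("need at least 2 pairs")
    s <- sd(d)
    if (s == 0) stop("zero variance: t undefined")
    t <- mean(d) / (s / sqrt(n))
    df <- n - 1
    method <- "paired t"
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
    v1 <- var(x); v2 <- var(y)
    if (v1 == 0 && v2 == 0) stop("zero variance in both groups: t undefined")
    se2 <- v1 / n1 + v2 / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    method <- "Welch two-sample t"
  }
  p <- 2 * pt(-abs(t), df)
  structure(list(statistic = t, df = df, p_value = p,
                 n = if (paired) length(x) else c(length(x), length(y)),
                 method = method), class = "ng_stat")
}

#' @export
print.ng_stat <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g%s, p = %.4g, n = %s\n", x$method,
              x$statistic,
              if (!is.null(x$df)) sprintf(", df %.3g", x$df) else "",
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' JZS Bayes factor for the null (BF01)
#'
#' Jeffreys-Zellner-Siow Bayes factor comparing the point null against a
#' Cauchy(0, rscale) prior on standardized effect size for a one-sample /
#' paired t statistic, computed by adaptive quadrature of the marginal
#' likelihood over the Zellner g (inverse-gamma(1/2, rscale^2/2)) mixing
#' parameter. Values above 1 favour the null.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design).
#' @param rscale Cauchy prior scale; default `sqrt(2)/2`, the conventional
#'   "medium" scale.
#' @return BF01 (scalar, > 0).
#' @export
jzs_bf01 <- function(t, n, rscale = sqrt(2) / 2) {
  if (!is.finite(t)) stop("t must be finite")
  if (n < 2) stop("n must be at least 2")
  if (rscale <= 0) stop("rscale must be positive")
  nu <- n - 1
  # BF10 = integral over g of exp(loginteg(g)); the null density is factored
  # into the integrand so the integral is the likelihood ratio directly.
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  loginteg <- function(g) {
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) -
      log_null +
      log(rscale) - 0.5 * log(2 * pi) - 1.5 * log(g) - rscale^2 / (2 * g)
  }
  # peak-normalized adaptive quadrature on (0, Inf)
  gmax <- exp(stats::optimize(function(lg) loginteg(exp(lg)),
                              c(-12, 12), maximum = TRUE)$maximum)
  lpeak <- loginteg(gmax)
  bf10 <- integrate(function(g) exp(loginteg(g) - lpeak), 0, Inf,
                    rel.tol = 1e-10, abs.tol = 0)$value * exp(lpeak)
  1 / bf10
}
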