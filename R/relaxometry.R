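# Fast backbone dynamics: exponential R1/R2 decay fits, heteronuclear NOE
# ratios, and flagging of slow-motion candidates from R2/R1 ratios.

#' Relaxation decay series
#'
#' @param probe A [residue_probe()].
#' @param delays Relaxation delays, s (>= 4, non-negative, strictly
#'   increasing).
#' @param intensities Peak intensities (arbitrary units).
#' @param sigma Per-point uncertainties (same units); optional.
#' @param kind `"R1"` or `"R2"`.
#' @return Object of class `decay_series`.
#' @export
decay_series <- function(probe, delays, intensities, sigma = NULL,
                         kind = c("R1", "R2")) {
  stopifnot(inherits(probe, "residue_probe"))
  kind <- match.arg(kind)
  if (length(delays) < 4L) abort_field("delays", "need >= 4 delays")
  if (any(delays < 0) || any(diff(delays) <= 0))
    abort_field("delays", "must be non-negative and strictly increasing")
  if (length(intensities) != length(delays))
    abort_field("intensities", "length must match delays")
  structure(list(probe = probe, delays = as.numeric(delays),
                 intensities = as.numeric(intensities), sigma = sigma,
                 kind = kind), class = "decay_series")
}

#' Saturated/reference intensity pair for the heteronuclear NOE
#' @param probe A [residue_probe()].
#' @param i_sat,i_ref Saturated and reference intensities (`i_ref != 0`).
#' @param sigma_sat,sigma_ref Their uncertainties.
#' @return Object of class `noe_pair`.
#' @export
noe_pair <- function(probe, i_sat, i_ref, sigma_sat = 0, sigma_ref = 0) {
  stopifnot(inherits(probe, "residue_probe"))
  if (!is.finite(i_ref) || i_ref == 0) abort_field("i_ref", "must be non-zero")
  structure(list(probe = probe, i_sat = i_sat, i_ref = i_ref,
                 sigma_sat = sigma_sat, sigma_ref = sigma_ref),
            class = "noe_pair")
}

#' Fit a single-exponential relaxation rate
#'
#' Two-parameter fit `I(t) = I0 * exp(-R * t)` by Levenberg-Marquardt,
#' initialized from a log-linear regression.  A non-decaying series is still
#' fitted and reported, with a warning flag.
#'
#' @param series A [decay_series()].
#' @return List with `rate` (1/s), `sigma`, `i0`, `warning` (`NA` or a
#'   message for non-decaying data).
#' @export
fit_exponential_rate <- function(series) {
  stopifnot(inherits(series, "decay_series"))
  t <- series$delays; y <- series$intensities
  w <- if (is.null(series$sigma)) rep(1, length(y)) else 1 / series$sigma
  pos <- y > 0
  init <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    c(i0 = exp(cf[[1]]), rate = -cf[[2]])
  } else c(i0 = max(abs(y)), rate = 1)
  fit <- minpack.lm::nls.lm(
    par = list(i0 = unname(init["i0"]), rate = unname(init["rate"])),
    fn = function(p) w * (y - p$i0 * exp(-p$rate * t)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  cov <- tryCatch(solve(fit$hessian) * fit$deviance / max(length(y) - 2L, 1L),
                  error = function(e) matrix(NA_real_, 2, 2))
  warn <- if (est$rate <= 0) "non-decaying series: fitted rate <= 0"
          else if (est$rate * (max(t) - min(t)) < 0.02)
            "essentially constant series: rate ~ 0"
          else NA_character_
  if (!is.na(warn)) warning(warn, call. = FALSE)
  list(rate = est$rate, sigma = sqrt(abs(cov[2, 2])), i0 = est$i0,
       warning = warn)
}

#' Heteronuclear NOE ratio with propagated error
#'
#' `hetNOE = I_sat / I_ref`;
#' `sigma = |ratio| * sqrt((s_sat/I_sat)^2 + (s_ref/I_ref)^2)`.
#'
#' @param pair A [noe_pair()].
#' @return List with `ratio` and `sigma`.
#' @export
compute_hetnoe <- function(pair) {
  stopifnot(inherits(pair, "noe_pair"))
  if (abs(pair$i_ref) < 1e-12 * max(abs(pair$i_sat), 1))
    stop("reference intensity is ~0; hetNOE undefined", call. = FALSE)
  ratio <- pair$i_sat / pair$i_ref
  sigma <- if (pair$i_sat == 0) {
    abs(pair$sigma_sat / pair$i_ref)
  } else {
    abs(ratio) * sqrt((pair$sigma_sat / pair$i_sat)^2 +
                        (pair$sigma_ref / pair$i_ref)^2)
  }
  list(ratio = ratio, sigma = sigma)
}

#' Flag slow-motion candidates from R2/R1 ratios
#'
#' A residue is flagged when its R2/R1 ratio exceeds the mean plus one
#' standard deviation of the ratios over all included residues (single pass,
#' outliers included in the statistics -- the cutoff is one horizontal line
#' for the whole set).
#'
#' @param r1_table,r2_table Data frames with columns `residue`, `rate`.
#' @param n_sd SD multiplier (default 1).
#' @return Data frame `residue`, `r1`, `r2`, `ratio`, `flagged`, with
#'   attributes `mean`, `sd`, `cutoff`.
#' @export
flag_r2r1 <- function(r1_table, r2_table, n_sd = 1) {
  tab <- merge(stats::setNames(r1_table[c("residue", "rate")], c("residue", "r1")),
               stats::setNames(r2_table[c("residue", "rate")], c("residue", "r2")),
               by = "residue")
  if (nrow(tab) < 5L)
    stop("R2/R1 flagging needs >= 5 matched residues for a meaningful threshold",
         call. = FALSE)
  tab$ratio <- tab$r2 / tab$r1
  mu <- mean(tab$ratio); sdv <- stats::sd(tab$ratio)
  cutoff <- mu + n_sd * sdv
  tab$flagged <- tab$ratio > cutoff
  attr(tab, "mean") <- mu; attr(tab, "sd") <- sdv; attr(tab, "cutoff") <- cutoff
  tab
}
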