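# Two-state fitting of CEST profiles: per-residue fits with grid-search
# initialization, global group fits with shared (kex, pB), minor-state shift
# reconstruction and comparison against directly observed shifts.

# unconstrained parameterization used by the optimizers
.tx_kex  <- function(kex) log(kex)
.itx_kex <- function(l) exp(l)
.tx_pB   <- function(pB) stats::qlogis(pmin(pmax(pB / 0.5, 1e-8), 1 - 1e-8))
.itx_pB  <- function(q) 0.5 * stats::plogis(q)

.cest_wres <- function(profile, model) {
  sig <- if (is.null(profile$sigma)) rep(1, length(profile$intensity)) else profile$sigma
  sim <- simulate_cest(profile$probe, model, profile$acq)
  (profile$intensity - sim$intensity) / sig
}

.aic_from_wssr <- function(wssr, n, k) n * log(wssr / n) + 2 * k

default_kex_grid <- function() exp(seq(log(10), log(6000), length.out = 7))
default_pB_grid  <- function() c(0.005, 0.02, 0.05, 0.10, 0.16)
default_dW_grid  <- function() { m <- c(0.5, 1, 2, 3, 4.5, 6); c(-rev(m), m) }

#' Fit a single CEST profile to two-state exchange
#'
#' Coarse grid search over (kex, pB, dW) -- kex on a log grid 10-6000 1/s,
#' pB 0.5-20 %, dW up to +/- 6 ppm -- followed by Levenberg-Marquardt
#' refinement of all five parameters (kex, pB, dW, R1, R2) against
#' [simulate_cest()].  A no-exchange (pB = 0) fit of R1 and R2 alone provides
#' the null model; `minor_dip_detected` is `TRUE` when the exchange model is
#' preferred by more than `aic_margin` AIC units.
#'
#' @param profile A [cest_profile()] with at least 15 offsets spanning both
#'   sides of the major-state shift.
#' @param kex_grid,pB_grid,dW_grid Grid-search start values (sensible
#'   defaults).
#' @param n_starts Number of best grid points refined.
#' @param aic_margin AIC difference required to call a minor dip (default 10).
#' @return A list of class `cest_fit` with elements `model` (fitted
#'   [two_state_model()]), `se` (one-sigma uncertainties for kex, pB, dW, R1,
#'   R2), `minor_dip_detected`, `chi2_reduced`, `aic_exchange`,
#'   `aic_no_exchange`, `converged`.
#' @export
fit_cest_residue <- function(profile, kex_grid = default_kex_grid(),
                             pB_grid = default_pB_grid(),
                             dW_grid = default_dW_grid(),
                             n_starts = 3L, aic_margin = 10) {
  stopifnot(inherits(profile, "cest_profile"))
  off <- profile$acq$offsets
  if (length(off) < 15)
    stop("CEST fit requires >= 15 offsets", call. = FALSE)
  if (!any(off < profile$probe$omega_major) || !any(off > profile$probe$omega_major))
    stop("CEST offsets must span both sides of omega_major", call. = FALSE)
  sig <- if (is.null(profile$sigma)) rep(1, length(off)) else profile$sigma
  n <- length(off)

  # crude R1 from the profile edges (far off-resonance I/I0 ~ exp(-R1 t_sat))
  edge <- mean(c(profile$intensity[1], profile$intensity[n]))
  r1_0 <- max(-log(min(max(edge, 0.05), 0.999)) / profile$acq$t_sat, 0.05)
  r2_0 <- 10

  # null model: no exchange, fit (R1, R2)
  null_fit <- group_lm(numeric(0), list(c(log(r1_0), log(r2_0))),
                       function(shared, blk, i) safe_resid({
                         m <- two_state_model(0, 0, 0, exp(blk[1]), exp(blk[2]))
                         .cest_wres(profile, m)
                       }, n), max_iter = 50L)
  aic_null <- .aic_from_wssr(null_fit$ssr, n, 2L)
  r1_0 <- exp(null_fit$blocks[[1]][1])

  # grid search with R1/R2 held at their null estimates
  grid <- expand.grid(kex = kex_grid, pB = pB_grid, dW = dW_grid)
  grid$ssr <- vapply(seq_len(nrow(grid)), function(i) {
    m <- two_state_model(grid$kex[i], grid$pB[i], grid$dW[i], r1_0, r2_0)
    sum(.cest_wres(profile, m)^2)
  }, numeric(1))
  ord <- order(grid$ssr)

  best <- NULL
  for (i in ord[seq_len(min(n_starts, nrow(grid)))]) {
    blk0 <- c(.tx_kex(grid$kex[i]), .tx_pB(grid$pB[i]), grid$dW[i],
              log(r1_0), log(r2_0))
    fit <- group_lm(numeric(0), list(blk0), function(shared, blk, j) safe_resid({
      m <- two_state_model(.itx_kex(blk[1]), .itx_pB(blk[2]), blk[3],
                           exp(blk[4]), exp(blk[5]))
      .cest_wres(profile, m)
    }, n), max_iter = 60L)
    if (is.null(best) || fit$ssr < best$ssr) best <- fit
  }
  if (is.null(best) || !all(is.finite(best$blocks[[1]])))
    stop(sprintf("CEST fit did not converge; best grid point kex=%.3g pB=%.3g dW=%.3g (ssr %.3g)",
                 grid$kex[ord[1]], grid$pB[ord[1]], grid$dW[ord[1]],
                 grid$ssr[ord[1]]), call. = FALSE)

  b <- best$blocks[[1]]
  model <- two_state_model(.itx_kex(b[1]), .itx_pB(b[2]), b[3],
                           exp(b[4]), exp(b[5]))
  # delta-method standard errors on the natural scale
  seb <- best$se_blocks[[1]]
  jac_nat <- c(model$kex, 0.5 * stats::plogis(b[2]) * (1 - stats::plogis(b[2])),
               1, model$R1, model$R2A)
  se <- stats::setNames(seb * abs(jac_nat), c("kex", "pB", "dW", "R1", "R2"))
  aic_ex <- .aic_from_wssr(best$ssr, n, 5L)

  structure(list(model = model, se = se,
                 minor_dip_detected = (aic_null - aic_ex) > aic_margin,
                 chi2_reduced = best$chi2_reduced,
                 aic_exchange = aic_ex, aic_no_exchange = aic_null,
                 converged = best$converged, residue = profile$probe$residue_id),
            class = "cest_fit")
}

.check_group_acq <- function(profiles) {
  b1 <- vapply(profiles, function(p) p$acq$b1_field, numeric(1))
  ts <- vapply(profiles, function(p) p$acq$t_sat, numeric(1))
  if (length(unique(b1)) > 1L || length(unique(ts)) > 1L)
    stop("inconsistent acquisition metadata within group (b1_field / t_sat)",
         call. = FALSE)
}

#' Globally fit CEST profiles in groups
#'
#' Within each group the exchange rate `kex` and minor population `pB` are
#' shared across residues while `dW`, `R1` and `R2` stay per-residue, as in a
#' grouped global analysis of exchange data.  Initialization comes from
#' per-residue fits ([fit_cest_residue()]); refinement uses a block-sparse
#' Levenberg-Marquardt.  Parameter uncertainties come from `n_mc` seeded
#' Monte-Carlo noise resamples (set `n_mc = 0` for covariance-based errors).
#'
#' @param profiles List of [cest_profile()] objects.
#' @param membership Data frame with columns `residue`, `group` (a single
#'   group id is recycled); residues absent from it are an error.
#' @param n_mc Monte-Carlo replicates for parameter errors (default 200).
#' @param mc_seed Seed for the Monte-Carlo resampling.
#' @return Named list of `group_fit_result` objects, one per group, each with
#'   `members`, `shared` (kex, pB), `shared_se`, `per_residue` (dW, R1, R2
#'   and their errors), `chi2_reduced`, `n_mc`, `converged`.
#' @export
fit_cest_group <- function(profiles, membership = NULL, n_mc = 200L,
                           mc_seed = 1L) {
  stopifnot(length(profiles) >= 1L)
  resid_ids <- vapply(profiles, function(p) p$probe$residue_id, integer(1))
  if (is.null(membership))
    membership <- data.frame(residue = resid_ids, group = "group1")
  if (!all(resid_ids %in% membership$residue))
    stop("membership map is missing residues: ",
         paste(setdiff(resid_ids, membership$residue), collapse = ", "),
         call. = FALSE)
  groups <- split(seq_along(profiles),
                  membership$group[match(resid_ids, membership$residue)])
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    .fit_cest_one_group(profiles[idx], g, n_mc = n_mc, mc_seed = mc_seed)
  })
  stats::setNames(out, names(groups))
}

.fit_cest_one_group <- function(profiles, group_name, n_mc = 200L,
                                mc_seed = 1L) {
  .check_group_acq(profiles)
  members <- vapply(profiles, function(p) p$probe$residue_id, integer(1))
  m <- length(profiles)

  rfits <- lapply(profiles, fit_cest_residue, n_starts = 2L)
  kex0 <- stats::median(vapply(rfits, function(f) f$model$kex, numeric(1)))
  pB0 <- stats::median(vapply(rfits, function(f) f$model$pB, numeric(1)))

  shared0 <- c(.tx_kex(kex0), .tx_pB(max(pB0, 1e-4)))
  blocks0 <- lapply(rfits, function(f)
    c(f$model$dW, log(max(f$model$R1, 1e-3)), log(max(f$model$R2A, 1e-3))))

  make_resid <- function(profs) function(shared, blk, i) safe_resid({
    model <- two_state_model(.itx_kex(shared[1]), .itx_pB(shared[2]), blk[1],
                             exp(blk[2]), exp(blk[3]))
    .cest_wres(profs[[i]], model)
  }, length(profs[[i]]$intensity))
  fit <- group_lm(shared0, blocks0, make_resid(profiles), max_iter = 80L)

  kex <- .itx_kex(fit$shared[1]); pB <- .itx_pB(fit$shared[2])
  per <- data.frame(residue = members,
                    dW = vapply(fit$blocks, `[`, numeric(1), 1L),
                    R1 = exp(vapply(fit$blocks, `[`, numeric(1), 2L)),
                    R2 = exp(vapply(fit$blocks, `[`, numeric(1), 3L)))

  if (n_mc > 0) {
    set.seed(mc_seed)
    draws <- matrix(NA_real_, n_mc, 2L)
    for (r in seq_len(n_mc)) {
      noisy <- lapply(profiles, function(p) {
        sig <- if (is.null(p$sigma)) rep(1e-2, length(p$intensity)) else p$sigma
        p$intensity <- p$intensity + stats::rnorm(length(p$intensity), 0, sig)
        p
      })
      refit <- group_lm(fit$shared, fit$blocks, make_resid(noisy),
                        max_iter = 6L)
      draws[r, ] <- c(.itx_kex(refit$shared[1]), .itx_pB(refit$shared[2]))
    }
    shared_se <- c(kex = stats::sd(draws[, 1]), pB = stats::sd(draws[, 2]))
  } else {
    jac <- c(kex, 0.5 * stats::plogis(fit$shared[2]) *
               (1 - stats::plogis(fit$shared[2])))
    shared_se <- stats::setNames(fit$se_shared * abs(jac), c("kex", "pB"))
  }

  per$dW_se <- vapply(fit$se_blocks, `[`, numeric(1), 1L)
  per$R1_se <- vapply(seq_len(m), function(i) fit$se_blocks[[i]][2] * per$R1[i],
                      numeric(1))
  per$R2_se <- vapply(seq_len(m), function(i) fit$se_blocks[[i]][3] * per$R2[i],
                      numeric(1))

  structure(list(group = group_name, members = members,
                 shared = c(kex = kex, pB = pB), shared_se = shared_se,
                 per_residue = per, chi2_reduced = fit$chi2_reduced,
                 n_mc = as.integer(n_mc), converged = fit$converged),
            class = "group_fit_result")
}

#' @export
print.group_fit_result <- function(x, ...) {
  cat(sprintf("<group_fit_result> %s: %d residues, kex = %.4g +/- %.2g /s, pB = %.4g +/- %.2g, chi2_red = %.3g\n",
              x$group, length(x$members), x$shared["kex"], x$shared_se["kex"],
              x$shared["pB"], x$shared_se["pB"], x$chi2_reduced))
  invisible(x)
}

#' Reconstruct the minor-state chemical shift
#'
#' `omega_B = omega_A + dW` with the fitted, sign-resolved shift difference.
#'
#' @param probe A [residue_probe()] carrying the major-state shift.
#' @param model A fitted [two_state_model()].
#' @return Minor-state shift, ppm.
#' @export
reconstruct_minor_shift <- function(probe, model) {
  stopifnot(inherits(probe, "residue_probe"), inherits(model, "two_state_model"))
  probe$omega_major + model$dW
}

#' Compare reconstructed minor-state shifts to reference shifts
#'
#' @param reconstructed,reference Data frames with columns `residue`,
#'   `shift` (ppm); e.g. CEST-derived minor shifts of one variant vs the
#'   directly observed shifts of another.
#' @return Data frame with `residue`, `reconstructed`, `reference`,
#'   `abs_diff` (ppm) for matched residues; residues present in only one
#'   table are kept with `NA` and listed in the `unmatched` attribute.
#'   Attributes `max_abs_diff` and `mean_abs_diff` summarize the match.
#' @export
compare_minor_to_reference <- function(reconstructed, reference) {
  stopifnot(all(c("residue", "shift") %in% names(reconstructed)),
            all(c("residue", "shift") %in% names(reference)))
  tab <- merge(stats::setNames(reconstructed[c("residue", "shift")],
                               c("residue", "reconstructed")),
               stats::setNames(reference[c("residue", "shift")],
                               c("residue", "reference")),
               by = "residue", all = TRUE)
  tab$abs_diff <- abs(tab$reconstructed - tab$reference)
  unmatched <- tab$residue[is.na(tab$reconstructed) | is.na(tab$reference)]
  attr(tab, "unmatched") <- unmatched
  attr(tab, "max_abs_diff") <- suppressWarnings(max(tab$abs_diff, na.rm = TRUE))
  attr(tab, "mean_abs_diff") <- mean(tab$abs_diff, na.rm = TRUE)
  tab
}
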