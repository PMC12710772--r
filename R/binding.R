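# Binding and population quantitation: combined chemical-shift perturbations,
# fast-exchange K_D titration fitting, slow-exchange peak-volume populations,
# and free-energy / fold-affinity arithmetic.

#' Combined 1H/15N chemical-shift perturbation
#'
#' `d = sqrt(dH^2 + (alpha * dN)^2)` with the conventional 15N weighting
#' `alpha = 0.14`.
#'
#' @param delta_h,delta_n Amide 1H and 15N shift changes, ppm.
#' @param alpha 15N weighting factor.
#' @return Combined CSP, ppm (vectorized).
#' @export
compute_csp <- function(delta_h, delta_n, alpha = 0.14) {
  sqrt(delta_h^2 + (alpha * delta_n)^2)
}

#' Titration series for one residue
#'
#' @param probe A [residue_probe()].
#' @param protein_conc Total protein concentration, M.
#' @param ligand_concs Total ligand concentrations, M; non-negative,
#'   increasing, first point apo (0).
#' @param delta_h,delta_n Shift changes vs the apo point, ppm (either these
#'   or `csp` directly).
#' @param csp Combined CSP per point, ppm (computed from `delta_h`/`delta_n`
#'   when omitted).
#' @param sigma Per-point CSP uncertainty, ppm.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(probe, protein_conc, ligand_concs,
                             delta_h = NULL, delta_n = NULL, csp = NULL,
                             sigma = NULL) {
  stopifnot(inherits(probe, "residue_probe"))
  if (!is.finite(protein_conc) || protein_conc <= 0)
    abort_field("protein_conc", "must be > 0")
  if (any(ligand_concs < 0) || any(diff(ligand_concs) <= 0))
    abort_field("ligand_concs", "must be non-negative and increasing")
  if (ligand_concs[1] != 0)
    abort_field("ligand_concs", "first titration point must be apo (0)")
  if (is.null(csp)) {
    if (is.null(delta_h) || is.null(delta_n))
      abort_field("csp", "supply either csp or both delta_h and delta_n")
    csp <- compute_csp(delta_h, delta_n)
  }
  if (length(csp) != length(ligand_concs))
    abort_field("csp", "length must match ligand_concs")
  structure(list(probe = probe, protein_conc = protein_conc,
                 ligand_concs = as.numeric(ligand_concs),
                 delta_h = delta_h, delta_n = delta_n,
                 csp = as.numeric(csp), sigma = sigma),
            class = "titration_series")
}

#' Single-site quadratic binding isotherm
#'
#' Bound fraction of protein at total protein `P`, total ligand `L` and
#' dissociation constant `KD` (all in M):
#' `((P + L + KD) - sqrt((P + L + KD)^2 - 4 P L)) / (2 P)`.
#'
#' @param L Total ligand concentrations, M.
#' @param P Total protein concentration, M.
#' @param KD Dissociation constant, M.
#' @return Bound fraction in [0, 1].
#' @export
binding_isotherm <- function(L, P, KD) {
  s <- P + L + KD
  (s - sqrt(pmax(s^2 - 4 * P * L, 0))) / (2 * P)
}

#' Global fast-exchange K_D fit of CSP titrations
#'
#' Fits `CSP([L]) = ddmax * f_bound([L]; P, KD)` with a single shared `KD`
#' across residues and a per-residue amplitude `ddmax`.  Because `ddmax`
#' enters linearly it is profiled out exactly (weighted linear least squares
#' per residue), leaving a one-dimensional optimization over `log KD`.
#'
#' @param series_list List of [titration_series()] (one also accepted).
#' @param kd_range Search interval for KD, M.
#' @return List of class `kd_fit`: `KD` (M), `KD_se`, `per_residue`
#'   (`ddmax` and errors), `chi2_reduced`, `saturation` (bound fraction at
#'   the top ligand point), `warning` (set when saturation < 50 %).
#' @export
fit_kd_fast_exchange <- function(series_list, kd_range = c(1e-8, 1)) {
  if (inherits(series_list, "titration_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L)
  if (any(vapply(series_list, function(s) length(s$ligand_concs), integer(1)) < 5L))
    stop("K_D fit requires >= 5 titration points per residue", call. = FALSE)
  P <- series_list[[1]]$protein_conc

  profile_ssr <- function(lkd) {
    kd <- exp(lkd)
    ssr <- 0
    for (s in series_list) {
      f <- binding_isotherm(s$ligand_concs, s$protein_conc, kd)
      w <- if (is.null(s$sigma)) rep(1, length(f)) else 1 / s$sigma
      dd <- sum(w^2 * f * s$csp) / sum(w^2 * f^2)
      ssr <- ssr + sum((w * (s$csp - dd * f))^2)
    }
    ssr
  }
  opt <- stats::optimize(profile_ssr, log(kd_range), tol = 1e-10)
  KD <- exp(opt$minimum)

  per <- do.call(rbind, lapply(series_list, function(s) {
    f <- binding_isotherm(s$ligand_concs, s$protein_conc, KD)
    w <- if (is.null(s$sigma)) rep(1, length(f)) else 1 / s$sigma
    dd <- sum(w^2 * f * s$csp) / sum(w^2 * f^2)
    data.frame(residue = s$probe$residue_id, ddmax = dd,
               ddmax_se = 1 / sqrt(sum(w^2 * f^2)))
  }))

  npts <- sum(vapply(series_list, function(s) length(s$csp), integer(1)))
  dof <- max(npts - (1L + nrow(per)), 1L)
  chi2_red <- opt$objective / dof
  # curvature-based error on log KD
  h <- 0.01
  d2 <- (profile_ssr(opt$minimum + h) - 2 * opt$objective +
           profile_ssr(opt$minimum - h)) / h^2
  KD_se <- if (is.finite(d2) && d2 > 0) KD * sqrt(2 * chi2_red * dof / dof / d2) else NA_real_

  max_sat <- max(vapply(series_list, function(s)
    max(binding_isotherm(s$ligand_concs, s$protein_conc, KD)), numeric(1)))
  warn <- if (max_sat < 0.5) {
    w <- sprintf("saturation only %.0f%% at the top ligand point; K_D poorly bounded",
                 100 * max_sat)
    warning(w, call. = FALSE)
    w
  } else NA_character_

  structure(list(KD = KD, KD_se = KD_se, per_residue = per,
                 chi2_reduced = chi2_red, saturation = max_sat,
                 warning = warn),
            class = "kd_fit")
}

#' Peak-volume pair for a slow-exchange reporter residue
#' @param probe A [residue_probe()].
#' @param v_major,v_minor Major- and minor-state peak volumes (>= 0, not
#'   both zero).
#' @param sigma_major,sigma_minor Volume uncertainties.
#' @return Object of class `peak_volume_pair`.
#' @export
peak_volume_pair <- function(probe, v_major, v_minor,
                             sigma_major = 0, sigma_minor = 0) {
  stopifnot(inherits(probe, "residue_probe"))
  if (v_major < 0) abort_field("v_major", "must be >= 0")
  if (v_minor < 0) abort_field("v_minor", "must be >= 0")
  structure(list(probe = probe, v_major = v_major, v_minor = v_minor,
                 sigma_major = sigma_major, sigma_minor = sigma_minor),
            class = "peak_volume_pair")
}

#' Quantify the minor (open) state population from peak volumes
#'
#' Per reporter residue `p_open = v_minor / (v_minor + v_major)`; the
#' aggregate is the mean and SD over reporters.  Residues with both volumes
#' zero are excluded with a warning.
#'
#' @param pairs List of [peak_volume_pair()] (>= 2 reporters).
#' @return List with `per_residue` (data frame `residue`, `p_open`),
#'   `mean`, `sd`, `n`.
#' @export
quantify_open_population <- function(pairs) {
  stopifnot(length(pairs) >= 2L)
  rows <- lapply(pairs, function(p) {
    tot <- p$v_major + p$v_minor
    if (tot == 0) {
      warning(sprintf("residue %d: both volumes zero; excluded",
                      p$probe$residue_id), call. = FALSE)
      return(NULL)
    }
    data.frame(residue = p$probe$residue_id, p_open = p$v_minor / tot)
  })
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(per_residue = per, mean = mean(per$p_open), sd = stats::sd(per$p_open),
       n = nrow(per))
}

#' Free-energy difference from a population or affinity fold change
#'
#' `ddG = -R T ln(fold_change)` with R = 1.987e-3 kcal/(mol K); a 2-fold
#' shift at 298 K gives -0.41 kcal/mol.
#'
#' @param fold_change Ratio of populations or equilibrium constants (> 0).
#' @param temperature_K Temperature, K (default 298).
#' @return Free-energy difference, kcal/mol.
#' @export
delta_delta_g <- function(fold_change, temperature_K = 298) {
  if (any(fold_change <= 0)) abort_field("fold_change", "must be > 0")
  if (any(temperature_K <= 0)) abort_field("temperature_K", "must be > 0")
  -1.987e-3 * temperature_K * log(fold_change)
}

#' Fold difference between two dissociation constants
#' @param kd_a,kd_b Dissociation constants, M (> 0).
#' @return `kd_a / kd_b`.
#' @export
fold_affinity <- function(kd_a, kd_b) {
  if (any(kd_a <= 0)) abort_field("kd_a", "must be > 0")
  if (any(kd_b <= 0)) abort_field("kd_b", "must be > 0")
  kd_a / kd_b
}
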