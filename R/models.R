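# Domain types: probes, exchange models, acquisition schemes.

GAMMA_15N_OVER_1H <- 0.101364  # |gamma(15N)/gamma(1H)|

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Backbone amide probe
#'
#' Describes one observed backbone 15N nucleus: its position in the sequence,
#' the chemical shift of the major conformational state and the static-field
#' context in which it was (or is to be) measured.
#'
#' @param residue_id Integer sequence position.
#' @param omega_major Major-state chemical shift of the observed nucleus, ppm.
#' @param residue_name Three-letter residue code (metadata only).
#' @param nucleus Observed nucleus label; only `"15N"` is supported.
#' @param spectrometer_freq_1H Proton Larmor frequency, MHz.
#' @param nucleus_freq Larmor frequency of the observed nucleus, MHz.  By
#'   default derived from `spectrometer_freq_1H` and the 15N/1H gyromagnetic
#'   ratio (81.1 MHz at 800 MHz 1H).  This is the Hz-per-ppm conversion used
#'   throughout.
#' @return An object of class `residue_probe`.
#' @export
residue_probe <- function(residue_id, omega_major, residue_name = "XXX",
                          nucleus = "15N", spectrometer_freq_1H = 800,
                          nucleus_freq = NULL) {
  if (!is.numeric(residue_id) || length(residue_id) != 1L || residue_id <= 0)
    abort_field("residue_id", "must be a positive integer")
  if (!identical(nucleus, "15N"))
    abort_field("nucleus", "only \"15N\" is supported")
  if (!is.finite(omega_major))
    abort_field("omega_major", "must be finite")
  if (!is.finite(spectrometer_freq_1H) || spectrometer_freq_1H <= 0)
    abort_field("spectrometer_freq_1H", "must be > 0")
  if (is.null(nucleus_freq))
    nucleus_freq <- spectrometer_freq_1H * GAMMA_15N_OVER_1H
  if (!is.finite(nucleus_freq) || nucleus_freq <= 0)
    abort_field("nucleus_freq", "must be > 0")
  structure(list(residue_id = as.integer(residue_id),
                 residue_name = residue_name, nucleus = nucleus,
                 omega_major = omega_major,
                 spectrometer_freq_1H = spectrometer_freq_1H,
                 nucleus_freq = nucleus_freq),
            class = "residue_probe")
}

#' Two-state exchange model
#'
#' Parameters of a two-site exchange process A (major) <-> B (minor):
#' `kex = k_AB + k_BA`, minor population `pB`, and the signed chemical-shift
#' difference `dW = omega_B - omega_A` in ppm.  Detailed balance fixes
#' `k_AB = pB * kex` and `k_BA = (1 - pB) * kex`.
#'
#' @param kex Exchange rate k_AB + k_BA, 1/s.
#' @param pB Minor-state population, in [0, 0.5).
#' @param dW Chemical-shift difference omega_B - omega_A, ppm (signed).
#' @param R1 Longitudinal relaxation rate shared by both states, 1/s.
#' @param R2A,R2B Transverse relaxation rates of states A and B, 1/s.
#' @return An object of classes `two_state_model`, `exchange_model`.
#' @export
two_state_model <- function(kex, pB, dW, R1 = 1.3, R2A = 12, R2B = R2A) {
  if (!is.finite(kex) || kex < 0) abort_field("kex", "must be >= 0")
  if (!is.finite(pB) || pB < 0 || pB >= 0.5)
    abort_field("pB", "must lie in [0, 0.5): A is the major state")
  if (!is.finite(dW)) abort_field("dW", "must be finite")
  if (!is.finite(R1) || R1 < 0) abort_field("R1", "must be >= 0")
  if (!is.finite(R2A) || R2A < 0) abort_field("R2A", "must be >= 0")
  if (!is.finite(R2B) || R2B < 0) abort_field("R2B", "must be >= 0")
  structure(list(kex = kex, pB = pB, dW = dW, R1 = R1, R2A = R2A, R2B = R2B),
            class = c("two_state_model", "exchange_model"))
}

#' Linear three-state exchange model
#'
#' Linear topology B <-> A <-> C with no direct B <-> C exchange.  Each leg is
#' parameterized like the two-state model: `kex_AB = k_AB + k_BA` with
#' pairwise detailed balance, so that `kex_AC = 0, pC = 0` reduces exactly to
#' [two_state_model()] behaviour.
#'
#' @param kex_AB,kex_AC Exchange rates of the two legs, 1/s.
#' @param pB,pC Minor-state populations; `pB + pC < 0.5`.
#' @param dW_AB,dW_AC Shift differences relative to A, ppm (signed).
#' @param R1 Shared longitudinal rate, 1/s.
#' @param R2 Transverse rates: scalar (shared) or length-3 vector (A, B, C).
#' @return An object of classes `three_state_model`, `exchange_model`.
#' @export
three_state_model <- function(kex_AB, pB, dW_AB, kex_AC, pC, dW_AC,
                              R1 = 1.3, R2 = 12) {
  if (!is.finite(kex_AB) || kex_AB < 0) abort_field("kex_AB", "must be >= 0")
  if (!is.finite(kex_AC) || kex_AC < 0) abort_field("kex_AC", "must be >= 0")
  if (!is.finite(pB) || pB < 0) abort_field("pB", "must be >= 0")
  if (!is.finite(pC) || pC < 0) abort_field("pC", "must be >= 0")
  if (pB + pC >= 0.5)
    abort_field("pB", "pB + pC must be < 0.5: A is the major state")
  if (!is.finite(dW_AB)) abort_field("dW_AB", "must be finite")
  if (!is.finite(dW_AC)) abort_field("dW_AC", "must be finite")
  if (!is.finite(R1) || R1 < 0) abort_field("R1", "must be >= 0")
  if (!length(R2) %in% c(1L, 3L) || any(!is.finite(R2)) || any(R2 < 0))
    abort_field("R2", "must be a non-negative scalar or length-3 vector")
  if (length(R2) == 1L) R2 <- rep(R2, 3L)
  structure(list(kex_AB = kex_AB, pB = pB, dW_AB = dW_AB,
                 kex_AC = kex_AC, pC = pC, dW_AC = dW_AC,
                 R1 = R1, R2 = R2),
            class = c("three_state_model", "exchange_model"))
}

#' Stationary populations of an exchange model
#' @param model An exchange model.
#' @return Numeric vector (pA, pB[, pC]).
#' @export
model_populations <- function(model) {
  if (inherits(model, "two_state_model")) c(1 - model$pB, model$pB)
  else c(1 - model$pB - model$pC, model$pB, model$pC)
}

#' State chemical shifts relative to the major state
#' @param model An exchange model.
#' @return Numeric vector of shift offsets from state A, ppm (first entry 0).
#' @export
model_dshifts <- function(model) {
  if (inherits(model, "two_state_model")) c(0, model$dW)
  else c(0, model$dW_AB, model$dW_AC)
}

model_r2 <- function(model) {
  if (inherits(model, "two_state_model")) c(model$R2A, model$R2B)
  else model$R2
}

#' Build the first-order exchange-rate matrix
#'
#' Returns the kinetic matrix K with off-diagonal entries `K[j, i]` equal to
#' the rate constant for the i -> j transition and diagonal entries chosen so
#' every column sums to zero; `dM/dt = K M` conserves total magnetization and
#' has the model populations as its stationary distribution.
#'
#' For the linear three-state topology the direct B <-> C entries are exactly
#' zero.
#'
#' @param model A [two_state_model()] or [three_state_model()].
#' @return Square numeric matrix over states (2 x 2 or 3 x 3).
#' @export
build_rate_matrix <- function(model) {
  if (inherits(model, "two_state_model")) {
    kAB <- model$pB * model$kex
    kBA <- (1 - model$pB) * model$kex
    matrix(c(-kAB, kAB, kBA, -kBA), nrow = 2,
           dimnames = list(c("A", "B"), c("A", "B")))
  } else if (inherits(model, "three_state_model")) {
    pA <- 1 - model$pB - model$pC
    sAB <- pA + model$pB
    sAC <- pA + model$pC
    kAB <- if (sAB > 0) model$kex_AB * model$pB / sAB else 0
    kBA <- if (sAB > 0) model$kex_AB * pA / sAB else 0
    kAC <- if (sAC > 0) model$kex_AC * model$pC / sAC else 0
    kCA <- if (sAC > 0) model$kex_AC * pA / sAC else 0
    K <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    K["B", "A"] <- kAB; K["A", "B"] <- kBA
    K["C", "A"] <- kAC; K["A", "C"] <- kCA
    diag(K) <- -colSums(K)
    K
  } else {
    abort_field("model", "must be a two_state_model or three_state_model")
  }
}

#' CEST acquisition scheme
#'
#' @param b1_field Saturation field strength, Hz.
#' @param t_sat Saturation duration, s.
#' @param offsets Saturation carrier offsets, strictly monotone, in the unit
#'   given by `offset_unit` (`"ppm"` absolute shifts by convention here).
#' @param offset_unit `"ppm"` (default) or `"hz"` (converted by readers).
#' @return An object of class `cest_acquisition`.
#' @export
cest_acquisition <- function(b1_field, t_sat, offsets, offset_unit = "ppm") {
  if (!is.finite(b1_field) || b1_field <= 0) abort_field("b1_field", "must be > 0")
  if (!is.finite(t_sat) || t_sat <= 0) abort_field("t_sat", "must be > 0")
  if (length(offsets) == 0) abort_field("offsets", "must be non-empty")
  d <- diff(offsets)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    abort_field("offsets", "must be strictly monotone")
  offset_unit <- match.arg(offset_unit, c("ppm", "hz"))
  structure(list(b1_field = b1_field, t_sat = t_sat,
                 offsets = as.numeric(offsets), offset_unit = offset_unit),
            class = "cest_acquisition")
}

#' CPMG acquisition scheme
#'
#' Constant-time relaxation period `t_relax` and refocusing frequencies
#' `nu_cpmg = 1/(4 tau)`.  Each frequency must fit an integer number of echo
#' blocks into the constant-time period (`t_relax * nu` integer), which makes
#' the number of 180-degree pulses per period (`2 * t_relax * nu`) a positive
#' even integer.
#'
#' @param t_relax Constant-time relaxation period, s.
#' @param nu_cpmg CPMG frequencies, Hz.
#' @return An object of class `cpmg_acquisition`.
#' @export
cpmg_acquisition <- function(t_relax, nu_cpmg) {
  if (!is.finite(t_relax) || t_relax <= 0) abort_field("t_relax", "must be > 0")
  if (length(nu_cpmg) == 0 || any(!is.finite(nu_cpmg)) || any(nu_cpmg <= 0))
    abort_field("nu_cpmg", "must all be > 0")
  nblk <- t_relax * nu_cpmg
  if (any(abs(nblk - round(nblk)) > 1e-8) || any(round(nblk) < 1))
    abort_field("nu_cpmg",
                "each nu must give a positive integer number of echo blocks in t_relax")
  structure(list(t_relax = t_relax, nu_cpmg = as.numeric(nu_cpmg)),
            class = "cpmg_acquisition")
}

#' @export
print.residue_probe <- function(x, ...) {
  cat(sprintf("<residue_probe> %s%d  %s  omega_A = %.2f ppm  (%.1f MHz)\n",
              x$residue_name, x$residue_id, x$nucleus, x$omega_major,
              x$nucleus_freq))
  invisible(x)
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf(
    "<two_state_model> kex = %.4g /s  pB = %.4g  dW = %.4g ppm  R1 = %.3g  R2A = %.3g  R2B = %.3g\n",
    x$kex, x$pB, x$dW, x$R1, x$R2A, x$R2B))
  invisible(x)
}

#' @export
print.three_state_model <- function(x, ...) {
  cat(sprintf(
    "<three_state_model> B<->A<->C  kex_AB = %.4g /s (pB = %.4g, dW_AB = %.4g ppm)  kex_AC = %.4g /s (pC = %.4g, dW_AC = %.4g ppm)\n",
    x$kex_AB, x$pB, x$dW_AB, x$kex_AC, x$pC, x$dW_AC))
  invisible(x)
}
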