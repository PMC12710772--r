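# Synthetic-data generation with known ground truth and seeded noise.
#
# Scenario presets carry benchmark conditions for an SH2-domain
# conformational-exchange analysis: CEST groups in slow exchange
# (kex ~ 104 and 45 1/s), CEST-constrained three-state CPMG (fast leg
# kex_AC ~ 2600 1/s), fast two-state CPMG groups, p-Tyr CSP titrations
# (K_D 250-400 uM), slow-exchange open/closed peak volumes (15 % / 31 %
# open) and toy multi-model ensembles with prescribed strand-pair distances.

#' Default CEST acquisition used by the generators
#'
#' 25 Hz saturation field applied for 0.4 s at 61 offsets spanning +/- 6 ppm
#' around the major-state shift; 15N at 81.1 MHz (800 MHz 1H).
#'
#' @param omega_major Center of the offset grid, ppm.
#' @param half_width Half-width of the grid, ppm.
#' @param n_offsets Number of offsets.
#' @param b1_field,t_sat Saturation field (Hz) and time (s).
#' @return A [cest_acquisition()].
#' @export
default_cest_acq <- function(omega_major, half_width = 6, n_offsets = 61,
                             b1_field = 25, t_sat = 0.4) {
  cest_acquisition(b1_field, t_sat,
                   seq(omega_major - half_width, omega_major + half_width,
                       length.out = n_offsets))
}

#' Default CPMG acquisition used by the generators
#'
#' 40 ms constant-time period with 14 frequencies, 25-1000 Hz, all multiples
#' of 25 Hz so the echo-block count is integral.
#'
#' @param t_relax Constant-time period, s.
#' @return A [cpmg_acquisition()].
#' @export
default_cpmg_acq <- function(t_relax = 0.04) {
  cpmg_acquisition(t_relax, c(25, 50, 75, 100, 150, 200, 250, 300,
                              400, 500, 600, 700, 850, 1000))
}

#' Named synthetic scenarios
#'
#' Each scenario fixes the ground-truth parameters, the acquisition and the
#' noise level for one dataset family; `seed` controls the noise stream.
#' Available names are listed by [nmr_scenarios()].
#'
#' @param name Scenario name.
#' @param seed Integer seed stored in the config.
#' @return A list of class `scenario_config`.
#' @export
nmr_scenario <- function(name, seed = 1L) {
  scen <- .scenarios()[[name]]
  if (is.null(scen))
    stop(sprintf("unknown scenario \"%s\"; see nmr_scenarios()", name),
         call. = FALSE)
  scen$name <- name
  scen$seed <- as.integer(seed)
  class(scen) <- "scenario_config"
  scen
}

#' @rdname nmr_scenario
#' @export
nmr_scenarios <- function() names(.scenarios())

.scenarios <- function() list(
  # CEST, 1P-GAB1-bound N-SH2 WT: slow zipping exchange
  bound_wt_cest_group1 = list(kind = "cest", kex = 104, pB = 0.11,
                              n_residues = 28L, noise = 0.01),
  bound_wt_cest_group2 = list(kind = "cest", kex = 45, pB = 0.16,
                              n_residues = 2L, noise = 0.01),
  # bound T42A: exchange quenched, no second-state dip
  bound_t42a_cest = list(kind = "cest", kex = 0, pB = 0,
                         n_residues = 10L, noise = 0.01),
  # CPMG two-state groups (populations in the fast, underdetermined regime)
  bound_wt_cpmg_group2 = list(kind = "cpmg2", kex = 1740, pB = 0.05,
                              n_residues = 6L, noise = 0.01),
  bound_wt_cpmg_group3 = list(kind = "cpmg2", kex = 5000, pB = 0.05,
                              n_residues = 2L, noise = 0.01),
  apo_wt_cpmg_group1 = list(kind = "cpmg2", kex = 3550, pB = 0.05,
                            n_residues = 8L, noise = 0.01),
  apo_wt_cpmg_group2 = list(kind = "cpmg2", kex = 7000, pB = 0.05,
                            n_residues = 4L, noise = 0.01),
  apo_t42a_cpmg_group1 = list(kind = "cpmg2", kex = 1260, pB = 0.05,
                              n_residues = 4L, noise = 0.01),
  # linear three-state: slow zipping leg from CEST + fast beta_D leg
  bound_wt_cpmg_3state = list(kind = "cpmg3", kex_AB = 104, pB = 0.11,
                              kex_AC = 2600, pC = 0.05,
                              n_residues = 6L, noise = 0.01),
  ile54_cpmg_3state = list(kind = "cpmg3", kex_AB = 45, pB = 0.16,
                           kex_AC = 1830, pC = 0.05,
                           n_residues = 1L, noise = 0.01),
  # p-Tyr CSP titrations (fast exchange)
  titration_wt_ptyr = list(kind = "titration", KD = 400e-6,
                           protein_conc = 0.2e-3, n_residues = 8L,
                           n_points = 10L, noise = 0.03),
  titration_t42s_ptyr = list(kind = "titration", KD = 330e-6,
                             protein_conc = 0.2e-3, n_residues = 8L,
                             n_points = 10L, noise = 0.03),
  titration_t42a_ptyr = list(kind = "titration", KD = 250e-6,
                             protein_conc = 0.2e-3, n_residues = 8L,
                             n_points = 10L, noise = 0.03),
  # slow-exchange open/closed reporters of full-length SHP2
  shp2_wt_volumes = list(kind = "volumes", p_open = 0.15, n_residues = 6L,
                         noise = 0.10),
  shp2_e139d_volumes = list(kind = "volumes", p_open = 0.31, n_residues = 6L,
                            noise = 0.10),
  # backbone relaxation (R1, R2, hetNOE) with flexible-loop residues
  nsh2_relaxation = list(kind = "relaxation", n_residues = 20L,
                         flexible = c(5L, 6L, 13L, 14L, 15L),
                         broadened = c(9L, 10L), noise = 0.01),
  # toy multi-model ensembles (strand-pair distances, A)
  bound_wt_ensemble = list(kind = "ensemble",
                           distances = c(rep(4.5, 10), rep(4.2, 4),
                                         rep(4.8, 2), rep(3.0, 3), 2.9),
                           hbond = NULL, jitter = 0),
  bound_t42a_ensemble = list(kind = "ensemble",
                             distances = rep(2.95, 20),
                             hbond = rep(2.6, 20), jitter = 0)
)

.spread <- function(lo, hi, n) if (n == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = n)

# deterministic per-residue truths (spread of dW, R1, R2, omega_major)
.cest_truth_table <- function(cfg) {
  n <- cfg$n_residues
  data.frame(residue = seq_len(n),
             omega_major = .spread(108, 126, n),
             dW = (-1)^(seq_len(n)) * .spread(1.2, 3.5, n),
             R1 = .spread(1.1, 1.5, n),
             R2 = .spread(9, 14, n))
}

#' Generate a synthetic CEST dataset
#'
#' Simulates two-state CEST profiles for `cfg$n_residues` probes at the
#' scenario's shared (kex, pB) with a deterministic per-residue spread of
#' dW, R1, R2 and major-state shifts, then adds seeded multiplicative
#' Gaussian intensity noise (`sigma = noise * |I|`).
#'
#' @param cfg A `scenario_config` from [nmr_scenario()] with kind `"cest"`.
#' @param noise Override for the fractional intensity noise.
#' @return List with `profiles` (list of [cest_profile()]), `truth`
#'   (shared parameters + per-residue table) and `config`.
#' @export
gen_cest_dataset <- function(cfg, noise = cfg$noise) {
  stopifnot(cfg$kind == "cest")
  tt <- .cest_truth_table(cfg)
  set.seed(cfg$seed)
  profiles <- lapply(seq_len(nrow(tt)), function(i) {
    probe <- residue_probe(tt$residue[i], tt$omega_major[i])
    model <- two_state_model(cfg$kex, cfg$pB, tt$dW[i], tt$R1[i], tt$R2[i])
    acq <- default_cest_acq(tt$omega_major[i])
    prof <- simulate_cest(probe, model, acq)
    if (noise > 0) {
      sig <- pmax(noise * abs(prof$intensity), 1e-4)
      prof <- cest_profile(probe, acq,
                           prof$intensity * (1 + stats::rnorm(length(sig), 0, noise)),
                           sigma = sig)
    }
    prof
  })
  list(profiles = profiles,
       truth = list(kex = cfg$kex, pB = cfg$pB, per_residue = tt,
                    noise = noise),
       config = cfg)
}

.cpmg_truth_table <- function(cfg) {
  n <- cfg$n_residues
  tt <- data.frame(residue = seq_len(n),
                   omega_major = .spread(108, 126, n),
                   R2 = .spread(9, 14, n))
  if (cfg$kind == "cpmg2") {
    tt$dW <- .spread(1.0, 2.8, n)
  } else {
    tt$dW_AB <- (-1)^(seq_len(n)) * .spread(1.2, 3.0, n)
    tt$dW_AC <- .spread(1.2, 2.6, n)
  }
  tt
}

#' Generate a synthetic CPMG dataset
#'
#' Simulates constant-time dispersions from the scenario's two-state or
#' linear three-state truth, converts to intensities
#' `I = exp(-R2eff * t_relax)`, adds seeded fractional intensity noise and
#' converts back with [compute_r2eff()] (so sigma is propagated the same way
#' as for measured data).
#'
#' @param cfg A `scenario_config` with kind `"cpmg2"` or `"cpmg3"`.
#' @param noise Override for the fractional intensity noise.
#' @return List with `profiles` (list of [cpmg_profile()]), `truth`,
#'   `config`.
#' @export
gen_cpmg_dataset <- function(cfg, noise = cfg$noise) {
  stopifnot(cfg$kind %in% c("cpmg2", "cpmg3"))
  tt <- .cpmg_truth_table(cfg)
  acq <- default_cpmg_acq()
  set.seed(cfg$seed)
  profiles <- lapply(seq_len(nrow(tt)), function(i) {
    probe <- residue_probe(tt$residue[i], tt$omega_major[i])
    model <- if (cfg$kind == "cpmg2") {
      two_state_model(cfg$kex, cfg$pB, tt$dW[i], R2A = tt$R2[i])
    } else {
      three_state_model(cfg$kex_AB, cfg$pB, tt$dW_AB[i],
                        cfg$kex_AC, cfg$pC, tt$dW_AC[i], R2 = tt$R2[i])
    }
    r2 <- simulate_cpmg(probe, model, acq)$r2eff
    if (noise > 0) {
      ival <- exp(-r2 * acq$t_relax) * (1 + stats::rnorm(length(r2), 0, noise))
      conv <- compute_r2eff(ival, 1, acq$t_relax,
                            sigma_intensity = noise * exp(-r2 * acq$t_relax))
      cpmg_profile(probe, acq, conv$r2eff, conv$sigma)
    } else {
      cpmg_profile(probe, acq, r2)
    }
  })
  truth <- c(cfg[intersect(names(cfg), c("kex", "pB", "kex_AB", "dW_AB",
                                         "kex_AC", "pC"))],
             list(per_residue = tt, noise = noise))
  list(profiles = profiles, truth = truth, config = cfg)
}

#' Generate a synthetic CSP titration dataset
#'
#' Closed-form quadratic-isotherm CSPs for `n_residues` probes with a
#' deterministic spread of per-residue amplitudes, plus seeded Gaussian
#' noise of SD `noise * ddmax` per point.
#'
#' @param cfg A `scenario_config` with kind `"titration"`.
#' @param noise Override for the fractional CSP noise.
#' @return List with `series` (list of [titration_series()]), `truth`,
#'   `config`.
#' @export
gen_titration_dataset <- function(cfg, noise = cfg$noise) {
  stopifnot(cfg$kind == "titration")
  n <- cfg$n_residues
  ligand <- c(0, 0.1, 0.2, 0.4, 0.8, 1.2, 1.8, 2.6, 3.8, 5.0)[seq_len(cfg$n_points)] * 1e-3
  ddmax <- .spread(0.05, 0.25, n)  # combined CSP amplitude, ppm
  set.seed(cfg$seed)
  series <- lapply(seq_len(n), function(i) {
    probe <- residue_probe(i, .spread(108, 126, n)[i])
    f <- binding_isotherm(ligand, cfg$protein_conc, cfg$KD)
    sig <- rep(noise * ddmax[i], length(f))
    csp <- ddmax[i] * f + if (noise > 0) stats::rnorm(length(f), 0, sig) else 0
    titration_series(probe, cfg$protein_conc, ligand, csp = csp,
                     sigma = if (noise > 0) sig else NULL)
  })
  list(series = series,
       truth = list(KD = cfg$KD, ddmax = ddmax, noise = noise),
       config = cfg)
}

#' Generate synthetic slow-exchange peak-volume pairs
#'
#' Major/minor volumes for `n_residues` reporters at the scenario's open
#' fraction, with seeded multiplicative volume noise.
#'
#' @param cfg A `scenario_config` with kind `"volumes"`.
#' @param noise Override for the fractional volume noise.
#' @return List with `pairs` (list of [peak_volume_pair()]), `truth`,
#'   `config`.
#' @export
gen_volume_dataset <- function(cfg, noise = cfg$noise) {
  stopifnot(cfg$kind == "volumes")
  n <- cfg$n_residues
  v0 <- .spread(0.8, 1.6, n)  # total volume per reporter, a.u.
  set.seed(cfg$seed)
  pairs <- lapply(seq_len(n), function(i) {
    probe <- residue_probe(i, 120)
    vmaj <- v0[i] * (1 - cfg$p_open)
    vmin <- v0[i] * cfg$p_open
    if (noise > 0) {
      vmaj <- max(vmaj * (1 + stats::rnorm(1, 0, noise)), 0)
      vmin <- max(vmin * (1 + stats::rnorm(1, 0, noise)), 0)
    }
    peak_volume_pair(probe, vmaj, vmin,
                     sigma_major = noise * vmaj, sigma_minor = noise * vmin)
  })
  list(pairs = pairs, truth = list(p_open = cfg$p_open, noise = noise),
       config = cfg)
}

#' Generate synthetic backbone-relaxation data
#'
#' R1 and R2 decay series (8 delays each) and hetNOE saturated/reference
#' pairs for `n_residues` probes.  Residues listed in `cfg$flexible` carry
#' extra fast motion (lower hetNOE via a scaled saturated intensity, lower
#' R2); residues in `cfg$broadened` carry microsecond-millisecond exchange
#' broadening (elevated R2, the population the R2/R1 flag should find).
#' Seeded fractional intensity noise throughout.
#'
#' @param cfg A `scenario_config` with kind `"relaxation"`.
#' @param noise Override for the fractional intensity noise.
#' @return List with `r1_series`, `r2_series`, `noe_pairs`, `truth`,
#'   `config`.
#' @export
gen_relaxation_dataset <- function(cfg, noise = cfg$noise) {
  stopifnot(cfg$kind == "relaxation")
  n <- cfg$n_residues
  flex <- seq_len(n) %in% cfg$flexible
  broad <- seq_len(n) %in% cfg$broadened
  r1 <- .spread(1.1, 1.5, n) + 0.3 * flex
  r2 <- .spread(11, 15, n) * ifelse(flex, 0.6, 1) * ifelse(broad, 1.8, 1)
  hetnoe <- ifelse(flex, 0.55, 0.82)
  d1 <- seq(0.02, 1.2, length.out = 8)
  d2 <- seq(0.004, 0.12, length.out = 8)
  set.seed(cfg$seed)
  mk <- function(i, rate, delays, kind) {
    y <- exp(-rate * delays)
    if (noise > 0) y <- y + stats::rnorm(length(y), 0, noise)
    decay_series(residue_probe(i, 120), delays, y,
                 sigma = rep(noise, length(y)), kind = kind)
  }
  r1_series <- lapply(seq_len(n), function(i) mk(i, r1[i], d1, "R1"))
  r2_series <- lapply(seq_len(n), function(i) mk(i, r2[i], d2, "R2"))
  noe_pairs <- lapply(seq_len(n), function(i) {
    iref <- 1 + if (noise > 0) stats::rnorm(1, 0, noise) else 0
    isat <- hetnoe[i] + if (noise > 0) stats::rnorm(1, 0, noise) else 0
    noe_pair(residue_probe(i, 120), isat, iref, noise, noise)
  })
  list(r1_series = r1_series, r2_series = r2_series, noe_pairs = noe_pairs,
       truth = list(R1 = r1, R2 = r2, hetnoe = hetnoe, flexible = flex,
                    broadened = broad, noise = noise),
       config = cfg)
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                           occ = 1, b = 0) {
  elem <- substr(name, 1, 1)
  name4 <- sprintf(" %-3s", name)
  paste0("ATOM  ", sprintf("%5d", serial), " ", name4, " ",
         sprintf("%3s", resname), " ", chain, sprintf("%4d", resno), "    ",
         sprintf("%8.3f%8.3f%8.3f", xyz[1], xyz[2], xyz[3]),
         sprintf("%6.2f%6.2f", occ, b), "          ", sprintf("%2s", elem))
}

#' Write a toy multi-model ensemble with prescribed pair distances
#'
#' Builds a minimal, strictly formatted multi-MODEL PDB in which the
#' Phe41-N to Ile56-O distance of model k equals `distances[k]` (to better
#' than 1e-3 A) and, optionally, the Tyr66-OH to Asp40-OD1 distance equals
#' `hbond[k]` (OD2 is placed farther, so nearest-OD selection returns OD1).
#' Decoy CA atoms receive the configured coordinate jitter; the named atoms
#' are exact.
#'
#' @param cfg A `scenario_config` with kind `"ensemble"`, or a numeric
#'   vector of Phe41N-Ile56O distances.
#' @param file Optional path to write; the PDB text (character vector of
#'   lines) is always returned invisibly.
#' @return Character vector of PDB lines, invisibly when `file` is given.
#' @export
gen_toy_ensemble <- function(cfg, file = NULL) {
  if (is.numeric(cfg)) cfg <- list(kind = "ensemble", distances = cfg,
                                   hbond = NULL, jitter = 0, seed = 1L)
  stopifnot(cfg$kind == "ensemble")
  if (any(cfg$distances <= 0))
    abort_field("distances", "prescribed distances must be > 0")
  if (!is.null(cfg$hbond) && length(cfg$hbond) != length(cfg$distances))
    abort_field("hbond", "length must match distances")
  set.seed(if (is.null(cfg$seed)) 1L else cfg$seed)
  jit <- function() if (is.null(cfg$jitter) || cfg$jitter == 0) c(0, 0, 0)
                    else stats::rnorm(3, 0, cfg$jitter)
  lines <- c("HEADER    TOY SH2 STRAND-PAIR ENSEMBLE (SYNTHETIC)",
             "REMARK    GENERATED BY nmrdyn::gen_toy_ensemble")
  for (k in seq_along(cfg$distances)) {
    d <- cfg$distances[k]
    lines <- c(lines, sprintf("MODEL     %4d", k))
    s <- 0L
    add <- function(name, resname, resno, xyz) {
      s <<- s + 1L
      lines <<- c(lines, .pdb_atom_line(s, name, resname, "A", resno, xyz))
    }
    add("CA", "ASP", 40L, c(-2.0, 1.5, 0.5) + jit())
    if (!is.null(cfg$hbond)) {
      dh <- cfg$hbond[k]
      add("OD1", "ASP", 40L, c(0, 10 + dh, 0))
      add("OD2", "ASP", 40L, c(0.8, 10 + dh + 1.0, 0.4))
    }
    add("N", "PHE", 41L, c(0, 0, 0))
    add("CA", "PHE", 41L, c(1.46, 0.2, 0.1) + jit())
    add("CA", "ILE", 56L, c(d + 1.4, 0.8, -0.3) + jit())
    add("O", "ILE", 56L, c(d, 0, 0))
    add("CA", "TYR", 66L, c(-1.2, 9.0, 0.7) + jit())
    add("OH", "TYR", 66L, c(0, 10, 0))
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
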