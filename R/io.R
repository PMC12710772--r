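# Delimited-text readers/writers for every data family, JSON ground-truth
# sidecars, and YAML run configuration.  All tables are whitespace-delimited
# with '#'-commented metadata lines (key: value) above an uncommented column
# header naming units.

.write_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  utils::write.table(format(df, digits = 10, scientific = NA, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_meta <- function(path) {
  lines <- readLines(path)
  mlines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in mlines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z0-9_.]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

.read_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body_idx)) stop(sprintf("%s: no data rows", path), call. = FALSE)
  nf <- vapply(strsplit(trimws(lines[body_idx]), "\\s+"), length, integer(1))
  if (any(nf != nf[1])) {
    bad <- body_idx[which(nf != nf[1])[1]]
    stop(sprintf("%s: parse error at line %d (expected %d fields, found %d)",
                 path, bad, nf[1], nf[which(nf != nf[1])[1]]), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  attr(df, "meta") <- .read_meta(path)
  df
}

.meta_num <- function(meta, key, default = NULL) {
  if (!is.null(meta[[key]])) as.numeric(strsplit(meta[[key]], "\\s+")[[1]])
  else default
}

#' Write / read CEST profile tables
#'
#' Columns: `residue`, `omega_major_ppm`, `offset_ppm`, `intensity_ratio`,
#' `sigma`; acquisition metadata (`b1_hz`, `t_sat_s`, `nucleus_freq_mhz`) in
#' commented header lines.
#'
#' @param profiles List of [cest_profile()] objects (or a `gen_cest_dataset()`
#'   result, whose `$profiles` is used).
#' @param path Output/input file path.
#' @return `write_cest_table`: the path, invisibly.  `read_cest_table`: a
#'   list of [cest_profile()] objects.
#' @export
write_cest_table <- function(profiles, path) {
  if (!is.null(profiles$profiles)) profiles <- profiles$profiles
  p1 <- profiles[[1]]
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = p$probe$residue_id,
               omega_major_ppm = p$probe$omega_major,
               offset_ppm = p$acq$offsets,
               intensity_ratio = p$intensity,
               sigma = if (is.null(p$sigma)) NA_real_ else p$sigma)))
  .write_table(df, path, meta = list(
    data = "cest normalized intensity (I/I0) vs saturation offset",
    b1_hz = p1$acq$b1_field, t_sat_s = p1$acq$t_sat,
    nucleus_freq_mhz = p1$probe$nucleus_freq))
}

#' @rdname write_cest_table
#' @export
read_cest_table <- function(path) {
  df <- .read_table(path, c("residue", "omega_major_ppm", "offset_ppm",
                            "intensity_ratio", "sigma"))
  meta <- attr(df, "meta")
  b1 <- .meta_num(meta, "b1_hz"); ts <- .meta_num(meta, "t_sat_s")
  fn <- .meta_num(meta, "nucleus_freq_mhz", 81.1)
  if (is.null(b1) || is.null(ts))
    stop(path, ": header must carry b1_hz and t_sat_s", call. = FALSE)
  lapply(split(df, df$residue), function(d) {
    d <- d[order(d$offset_ppm), ]
    probe <- residue_probe(d$residue[1], d$omega_major_ppm[1],
                           nucleus_freq = fn)
    acq <- cest_acquisition(b1, ts, d$offset_ppm)
    sig <- if (all(is.na(d$sigma))) NULL else d$sigma
    cest_profile(probe, acq, d$intensity_ratio, sig)
  })
}

#' Write / read CPMG dispersion tables
#'
#' Columns: `residue`, `omega_major_ppm`, `nu_cpmg_hz`, `r2eff`, `sigma`;
#' metadata `t_relax_s`, `nucleus_freq_mhz`.
#'
#' @param profiles List of [cpmg_profile()] (or a `gen_cpmg_dataset()`
#'   result).
#' @param path File path.
#' @return `write_cpmg_table`: the path, invisibly.  `read_cpmg_table`: a
#'   list of [cpmg_profile()] objects.
#' @export
write_cpmg_table <- function(profiles, path) {
  if (!is.null(profiles$profiles)) profiles <- profiles$profiles
  p1 <- profiles[[1]]
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(residue = p$probe$residue_id,
               omega_major_ppm = p$probe$omega_major,
               nu_cpmg_hz = p$acq$nu_cpmg,
               r2eff = p$r2eff,
               sigma = if (is.null(p$sigma)) NA_real_ else p$sigma)))
  .write_table(df, path, meta = list(
    data = "cpmg effective transverse rate (1/s) vs refocusing frequency",
    t_relax_s = p1$acq$t_relax, nucleus_freq_mhz = p1$probe$nucleus_freq))
}

#' @rdname write_cpmg_table
#' @export
read_cpmg_table <- function(path) {
  df <- .read_table(path, c("residue", "omega_major_ppm", "nu_cpmg_hz",
                            "r2eff", "sigma"))
  meta <- attr(df, "meta")
  tr <- .meta_num(meta, "t_relax_s")
  fn <- .meta_num(meta, "nucleus_freq_mhz", 81.1)
  if (is.null(tr)) stop(path, ": header must carry t_relax_s", call. = FALSE)
  lapply(split(df, df$residue), function(d) {
    d <- d[order(d$nu_cpmg_hz), ]
    probe <- residue_probe(d$residue[1], d$omega_major_ppm[1],
                           nucleus_freq = fn)
    acq <- cpmg_acquisition(tr, d$nu_cpmg_hz)
    sig <- if (all(is.na(d$sigma))) NULL else d$sigma
    cpmg_profile(probe, acq, d$r2eff, sig)
  })
}

#' Write / read titration tables
#'
#' Columns: `residue`, `ligand_conc_M`, `csp_ppm`, `sigma`; metadata
#' `protein_conc_M`.
#' @param series List of [titration_series()] (or `gen_titration_dataset()`
#'   result).
#' @param path File path.
#' @return Writer: path.  Reader: list of [titration_series()].
#' @export
write_titration_table <- function(series, path) {
  if (!is.null(series$series)) series <- series$series
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(residue = s$probe$residue_id,
               ligand_conc_M = s$ligand_concs, csp_ppm = s$csp,
               sigma = if (is.null(s$sigma)) NA_real_ else s$sigma)))
  .write_table(df, path, meta = list(
    data = "combined chemical-shift perturbation (ppm) vs total ligand (M)",
    protein_conc_M = series[[1]]$protein_conc))
}

#' @rdname write_titration_table
#' @export
read_titration_table <- function(path) {
  df <- .read_table(path, c("residue", "ligand_conc_M", "csp_ppm", "sigma"))
  pc <- .meta_num(attr(df, "meta"), "protein_conc_M")
  if (is.null(pc)) stop(path, ": header must carry protein_conc_M", call. = FALSE)
  lapply(split(df, df$residue), function(d) {
    d <- d[order(d$ligand_conc_M), ]
    titration_series(residue_probe(d$residue[1], 120), pc, d$ligand_conc_M,
                     csp = d$csp_ppm,
                     sigma = if (all(is.na(d$sigma))) NULL else d$sigma)
  })
}

#' Write / read peak-volume tables
#'
#' Columns: `residue`, `v_major`, `v_minor`, `sigma_major`, `sigma_minor`.
#' @param pairs List of [peak_volume_pair()] (or `gen_volume_dataset()`
#'   result).
#' @param path File path.
#' @return Writer: path.  Reader: list of [peak_volume_pair()].
#' @export
write_volume_table <- function(pairs, path) {
  if (!is.null(pairs$pairs)) pairs <- pairs$pairs
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(residue = p$probe$residue_id, v_major = p$v_major,
               v_minor = p$v_minor, sigma_major = p$sigma_major,
               sigma_minor = p$sigma_minor)))
  .write_table(df, path, meta = list(
    data = "slow-exchange major/minor peak volumes (a.u.)"))
}

#' @rdname write_volume_table
#' @export
read_volume_table <- function(path) {
  df <- .read_table(path, c("residue", "v_major", "v_minor",
                            "sigma_major", "sigma_minor"))
  lapply(seq_len(nrow(df)), function(i)
    peak_volume_pair(residue_probe(df$residue[i], 120), df$v_major[i],
                     df$v_minor[i], df$sigma_major[i], df$sigma_minor[i]))
}

#' Write / read relaxation decay and hetNOE tables
#'
#' Decays: columns `residue`, `delay_s`, `intensity`, `sigma` with metadata
#' `kind` (R1/R2).  NOE: `residue`, `i_sat`, `i_ref`, `sigma_sat`,
#' `sigma_ref`.
#' @param series List of [decay_series()].
#' @param pairs List of [noe_pair()].
#' @param path File path.
#' @return Writers: path.  Readers: lists of the corresponding objects.
#' @export
write_decay_table <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(residue = s$probe$residue_id, delay_s = s$delays,
               intensity = s$intensities,
               sigma = if (is.null(s$sigma)) NA_real_ else s$sigma)))
  .write_table(df, path, meta = list(
    data = "relaxation decay intensity (a.u.) vs delay (s)",
    kind = series[[1]]$kind))
}

#' @rdname write_decay_table
#' @export
read_decay_table <- function(path) {
  df <- .read_table(path, c("residue", "delay_s", "intensity", "sigma"))
  kind <- attr(df, "meta")$kind
  if (is.null(kind)) kind <- "R1"
  lapply(split(df, df$residue), function(d) {
    d <- d[order(d$delay_s), ]
    decay_series(residue_probe(d$residue[1], 120), d$delay_s, d$intensity,
                 sigma = if (all(is.na(d$sigma))) NULL else d$sigma,
                 kind = kind)
  })
}

#' @rdname write_decay_table
#' @export
write_noe_table <- function(pairs, path) {
  df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(residue = p$probe$residue_id, i_sat = p$i_sat, i_ref = p$i_ref,
               sigma_sat = p$sigma_sat, sigma_ref = p$sigma_ref)))
  .write_table(df, path, meta = list(
    data = "heteronuclear NOE saturated/reference intensities (a.u.)"))
}

#' @rdname write_decay_table
#' @export
read_noe_table <- function(path) {
  df <- .read_table(path, c("residue", "i_sat", "i_ref", "sigma_sat",
                            "sigma_ref"))
  lapply(seq_len(nrow(df)), function(i)
    noe_pair(residue_probe(df$residue[i], 120), df$i_sat[i], df$i_ref[i],
             df$sigma_sat[i], df$sigma_ref[i]))
}

#' Write / read a ground-truth sidecar (JSON)
#'
#' Generators record the parameters a dataset was built from; recovery tests
#' compare fits against this sidecar.
#' @param truth List of ground-truth values.
#' @param path JSON file path.
#' @return Writer: path.  Reader: the truth list.
#' @export
write_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read a YAML run configuration
#'
#' Keys: input paths (checked to exist), `output_dir`, `seed`, thresholds
#' (`rex_threshold`, `r2r1_sd_multiplier`, `zipped_max`, `unzipped_min`,
#' all positive), acquisition metadata and group-membership table paths.
#' @param path YAML file.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in grep("(_file|_path|_table)$", names(cfg), value = TRUE))
    if (!file.exists(cfg[[k]]))
      stop(sprintf("config %s: path does not exist: %s", k, cfg[[k]]),
           call. = FALSE)
  for (k in c("rex_threshold", "r2r1_sd_multiplier", "zipped_max",
              "unzipped_min"))
    if (!is.null(cfg[[k]]) && cfg[[k]] <= 0)
      stop(sprintf("config %s: must be positive", k), call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a group-membership table
#'
#' Columns `residue`, `group`.
#' @param path File path.
#' @return Data frame.
#' @export
read_membership <- function(path) .read_table(path, c("residue", "group"))
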