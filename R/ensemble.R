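# Multi-model structure ensembles: named atom-pair distances per model,
# zipped/unzipped beta-sheet classification, short-hydrogen-bond summary and
# survey mode over many SH2-domain structures.
#
# The motivating geometry is the beta_C/beta_D strand pair of an SH2 domain:
# the Phe41 amide nitrogen to Ile56 carbonyl oxygen distance distinguishes a
# hydrogen-bonded "zipped" strand conformation (2.7-3.3 A) from an "unzipped"
# one (>= 3.4 A), and the Tyr66 OH - Asp40 carboxylate distance reports a
# short hydrogen bond in the zipped state.

#' Named atom-pair specification
#'
#' @param label Human-readable label, e.g. `"F41N-I56O"`.
#' @param resno_a,resno_b Residue numbers (positive).
#' @param atom_a,atom_b PDB atom names (e.g. `"N"`, `"O"`, `"OH"`).  The
#'   carboxylate pseudo-names `"OD"`/`"OE"` select the nearer of OD1/OD2
#'   (OE1/OE2) in each model.
#' @param chain_a,chain_b Chain identifiers; `NA` means the first chain that
#'   contains the atom.
#' @param resname_a,resname_b Optional residue-name checks.
#' @return Object of class `atom_pair_spec`.
#' @export
atom_pair_spec <- function(label, resno_a, atom_a, resno_b, atom_b,
                           chain_a = NA, chain_b = NA,
                           resname_a = NA, resname_b = NA) {
  if (!nzchar(atom_a)) abort_field("atom_a", "must be non-empty")
  if (!nzchar(atom_b)) abort_field("atom_b", "must be non-empty")
  if (resno_a <= 0) abort_field("resno_a", "must be positive")
  if (resno_b <= 0) abort_field("resno_b", "must be positive")
  structure(list(label = label,
                 a = list(chain = chain_a, resno = as.integer(resno_a),
                          resname = resname_a, atom = atom_a),
                 b = list(chain = chain_b, resno = as.integer(resno_b),
                          resname = resname_b, atom = atom_b)),
            class = "atom_pair_spec")
}

# Resolve one endpoint to atom-row indices of a bio3d pdb object.  Returns
# one index, or several for carboxylate pseudo-names (min distance taken
# later).  Alternate locations: highest occupancy wins, ties go to altLoc
# "A" (blank counts as "A").
.resolve_atom <- function(pdb, ep) {
  at <- pdb$atom
  names_want <- if (ep$atom %in% c("OD", "OE")) paste0(ep$atom, 1:2) else ep$atom
  sel <- at$resno == ep$resno & at$elety %in% names_want
  if (!is.na(ep$resname)) sel <- sel & at$resid == ep$resname
  if (!is.na(ep$chain)) {
    sel <- sel & at$chain == ep$chain
  } else if (any(sel)) {
    sel <- sel & at$chain == at$chain[which(sel)[1]]
  }
  idx <- which(sel)
  if (!length(idx))
    stop(sprintf("atom not found: resno %d atom %s%s", ep$resno, ep$atom,
                 if (is.na(ep$chain)) "" else paste0(" chain ", ep$chain)),
         call. = FALSE)
  # collapse alternate locations per atom name
  out <- integer(0)
  for (nm in unique(at$elety[idx])) {
    ii <- idx[at$elety[idx] == nm]
    if (length(ii) > 1L) {
      occ <- at$o[ii]; occ[is.na(occ)] <- 1
      ii <- ii[occ == max(occ)]
      if (length(ii) > 1L) {
        alt <- at$alt[ii]; alt[is.na(alt) | alt == ""] <- "A"
        ii <- ii[order(alt)][1]
      }
    }
    out <- c(out, ii)
  }
  out
}

#' Per-model distances for a named atom pair
#'
#' Computes the Euclidean distance between the two named atoms in every
#' MODEL of a multi-model PDB file (models numbered 1-based in file order).
#' Models missing either atom's coordinates are recorded as `NA` (absent),
#' never as zero.  For carboxylate acceptors the minimum over OD1/OD2 (or
#' OE1/OE2) is taken per model.
#'
#' @param structure Path to a PDB file, or a `bio3d` pdb object read with
#'   `multi = TRUE`.
#' @param pair An [atom_pair_spec()].
#' @param structure_id Identifier for the result (defaults to the file name).
#' @param zipped_max,unzipped_min Classification thresholds, Angstrom.
#' @return Object of class `ensemble_distance_set`: `structure_id`, `pair`,
#'   `distances` (A per model, `NA` = absent), `labels`
#'   (zipped/unzipped/ambiguous), `thresholds`, `n_models`.
#' @export
extract_pair_distances <- function(structure, pair, structure_id = NULL,
                                   zipped_max = 3.3, unzipped_min = 3.4) {
  stopifnot(inherits(pair, "atom_pair_spec"))
  if (is.character(structure)) {
    if (is.null(structure_id)) structure_id <- basename(structure)
    pdb <- suppressWarnings(bio3d::read.pdb(structure, multi = TRUE,
                                            rm.alt = FALSE, verbose = FALSE))
  } else {
    pdb <- structure
    if (is.null(structure_id)) structure_id <- "structure"
  }
  ia <- .resolve_atom(pdb, pair$a)
  ib <- .resolve_atom(pdb, pair$b)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  dist_one <- function(model, i, j) {
    ca <- xyz[model, 3 * (i - 1) + 1:3]
    cb <- xyz[model, 3 * (j - 1) + 1:3]
    if (any(!is.finite(ca)) || any(!is.finite(cb))) return(NA_real_)
    sqrt(sum((ca - cb)^2))
  }
  distances <- vapply(seq_len(n_models), function(m) {
    d <- outer(ia, ib, Vectorize(function(i, j) dist_one(m, i, j)))
    if (all(is.na(d))) NA_real_ else min(d, na.rm = TRUE)
  }, numeric(1))
  labels <- rep(NA_character_, n_models)
  ok <- !is.na(distances) & distances > 0  # degenerate 0-distance stays NA
  labels[ok] <- classify_conformation(distances[ok], zipped_max, unzipped_min)
  structure(list(structure_id = structure_id, pair = pair,
                 distances = distances, labels = labels,
                 thresholds = c(zipped_max = zipped_max,
                                unzipped_min = unzipped_min),
                 n_models = n_models),
            class = "ensemble_distance_set")
}

#' Classify a strand-pair distance as zipped, unzipped or ambiguous
#'
#' Zipped when the donor-acceptor distance allows the cross-strand hydrogen
#' bond (d <= 3.3 A), unzipped when it cannot form (d >= 3.4 A), ambiguous
#' in the narrow band between.
#'
#' @param distance Distances, Angstrom (> 0); vectorized.
#' @param zipped_max,unzipped_min Thresholds, Angstrom.
#' @return Character vector `"zipped"`, `"unzipped"` or `"ambiguous"`.
#' @export
classify_conformation <- function(distance, zipped_max = 3.3,
                                  unzipped_min = 3.4) {
  if (any(distance <= 0, na.rm = TRUE))
    abort_field("distance", "must be > 0")
  ifelse(distance <= zipped_max, "zipped",
         ifelse(distance >= unzipped_min, "unzipped", "ambiguous"))
}

#' Summary of a hydrogen-bond distance set with short-H-bond flag
#'
#' @param distances Donor-acceptor distances, Angstrom (non-empty).
#' @param short_cutoff Mean distance below which the bond is called a short
#'   hydrogen bond (default 2.7 A).
#' @return List with `mean`, `sd`, `n`, `short_hbond`.
#' @export
short_hbond_report <- function(distances, short_cutoff = 2.7) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) abort_field("distances", "must be non-empty")
  m <- mean(distances)
  list(mean = m, sd = if (length(distances) > 1) stats::sd(distances) else 0,
       n = length(distances), short_hbond = m < short_cutoff)
}

#' Survey strand-pair conformations over many structures
#'
#' Applies [extract_pair_distances()] with a per-structure homologous residue
#' pair (e.g. the residues homologous to Phe41 and Ile56 across SH2 domains),
#' takes each structure's minimum pair distance over models, classifies it,
#' and tabulates class counts plus a distance histogram.
#'
#' @param structures Character vector of PDB file paths.
#' @param mapping Data frame with one row per structure: `file`, `resno_a`,
#'   `atom_a`, `resno_b`, `atom_b`, optional `chain`.  Structures whose
#'   mapping cannot be resolved are skipped with a log entry.
#' @param zipped_max,unzipped_min Thresholds, Angstrom.
#' @param bin_width Histogram bin width, Angstrom.
#' @return List with `table` (per-structure distance + label), `counts`
#'   (named vector over classes), `histogram` (bin table) and `skipped`
#'   (log messages for unresolvable structures).
#' @export
survey_sh2 <- function(structures, mapping, zipped_max = 3.3,
                       unzipped_min = 3.4, bin_width = 0.25) {
  empty <- list(table = data.frame(file = character(), distance = numeric(),
                                   label = character()),
                counts = c(zipped = 0L, unzipped = 0L, ambiguous = 0L),
                histogram = data.frame(bin_lo = numeric(), bin_hi = numeric(),
                                       count = integer()),
                skipped = character())
  if (!length(structures)) return(empty)
  rows <- list(); skipped <- character()
  for (f in structures) {
    mrow <- mapping[mapping$file == basename(f) | mapping$file == f, , drop = FALSE]
    if (nrow(mrow) == 0L) {
      skipped <- c(skipped, sprintf("%s: no mapping entry", basename(f)))
      next
    }
    mrow <- mrow[1, ]
    chain <- if ("chain" %in% names(mrow)) mrow$chain else NA
    pair <- atom_pair_spec(sprintf("%s:%d%s-%d%s", basename(f), mrow$resno_a,
                                   mrow$atom_a, mrow$resno_b, mrow$atom_b),
                           mrow$resno_a, mrow$atom_a, mrow$resno_b,
                           mrow$atom_b, chain_a = chain, chain_b = chain)
    eds <- tryCatch(extract_pair_distances(f, pair, zipped_max = zipped_max,
                                           unzipped_min = unzipped_min),
                    error = function(e) e)
    if (inherits(eds, "error")) {
      skipped <- c(skipped, sprintf("%s: %s", basename(f), conditionMessage(eds)))
      next
    }
    d <- suppressWarnings(min(eds$distances, na.rm = TRUE))
    if (!is.finite(d)) {
      skipped <- c(skipped, sprintf("%s: atoms absent in all models", basename(f)))
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(file = basename(f), distance = d,
                 label = classify_conformation(d, zipped_max, unzipped_min))
  }
  if (!length(rows)) { empty$skipped <- skipped; return(empty) }
  tab <- do.call(rbind, rows)
  counts <- c(zipped = sum(tab$label == "zipped"),
              unzipped = sum(tab$label == "unzipped"),
              ambiguous = sum(tab$label == "ambiguous"))
  lo <- floor(min(tab$distance) / bin_width) * bin_width
  hi <- ceiling(max(tab$distance) / bin_width) * bin_width
  breaks <- seq(lo, max(hi, lo + bin_width), by = bin_width)
  h <- graphics::hist(tab$distance, breaks = breaks, plot = FALSE)
  histogram <- data.frame(bin_lo = utils::head(h$breaks, -1),
                          bin_hi = h$breaks[-1], count = h$counts)
  list(table = tab, counts = counts, histogram = histogram, skipped = skipped)
}

#' @export
print.ensemble_distance_set <- function(x, ...) {
  cat(sprintf("<ensemble_distance_set> %s  %s: %d models, %d absent; %s\n",
              x$structure_id, x$pair$label, x$n_models,
              sum(is.na(x$distances)),
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}
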