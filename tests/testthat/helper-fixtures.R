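# Shared fixtures: a standard 15N probe, compact acquisitions for fast
# tests, and a reference truth model.

std_probe <- function(id = 43L, omega = 118) residue_probe(id, omega)

std_cest_acq <- function(omega = 118) default_cest_acq(omega)

std_cpmg_acq <- function() default_cpmg_acq()

group1_model <- function(dW = 2) two_state_model(104, 0.11, dW,
                                                 R1 = 1.2, R2A = 10)

# independent brute-force Euclidean distance from raw PDB text (fixed-width
# columns), bypassing the package's reader
pdb_text_distance <- function(lines, model, resno_a, atom_a, resno_b, atom_b) {
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  block <- lines[(starts[model] + 1):(ends[model] - 1)]
  coord <- function(resno, atom) {
    hit <- block[trimws(substr(block, 13, 16)) == atom &
                   as.integer(substr(block, 23, 26)) == resno]
    c(as.numeric(substr(hit[1], 31, 38)), as.numeric(substr(hit[1], 39, 46)),
      as.numeric(substr(hit[1], 47, 54)))
  }
  sqrt(sum((coord(resno_a, atom_a) - coord(resno_b, atom_b))^2))
}
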