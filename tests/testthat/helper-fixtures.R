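# Shared fixture builders: everything is generated in code at test time.

# small library + counts on a toy protein
toy_counts <- function(length = 60L, depth = 2e5, seed = 7L,
                       selection_strength = 4, error_rate = 1e-6,
                       n_replicates = 2L) {
  seq_aa <- random_protein_sequence(length, seed = seed)
  lib <- generate_library(seq_aa, list(c(2L, length)))
  eff <- sample_true_effects(lib, seed = seed + 1L, protein_length = length)
  cfg <- sim_config(
    depth = depth, regions = list(c(2L, length)), tiles_per_region = 2L,
    selection_strength = selection_strength, error_rate = error_rate,
    n_replicates = n_replicates, seed = seed + 2L
  )
  list(lib = lib, effects = eff, config = cfg, counts = simulate_counts(eff, cfg))
}

# hand-sized count table for arithmetic oracles: one tile, one replicate set,
# counts chosen directly
manual_counts <- function(pre, post, wtctrl, depth = 1000L) {
  n <- length(pre)
  template <- tibble::tibble(
    position = seq_len(n) + 1L,
    wt_aa = rep("A", n),
    alt_aa = rep("V", n),
    var_class = rep("missense", n),
    tile = 1L, replicate = 1L
  )
  dplyr::bind_rows(
    dplyr::mutate(template, condition = "pre", count = pre, depth = depth),
    dplyr::mutate(template, condition = "post", count = post, depth = depth),
    dplyr::mutate(template, condition = "wtctrl", count = wtctrl, depth = depth)
  )
}

# build an atom tibble for one residue: backbone N/CA/C/O plus optional
# sidechain atoms at given offsets from the residue center
toy_residue <- function(residue, aa, center, sidechain = list(CB = c(0.5, 1.2, 0))) {
  bb <- tibble::tibble(
    residue = residue, aa = aa,
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = center[1] + c(0, 0.5, 1, 1.5),
    y = center[2] + c(0, 0, 0.3, 0.3),
    z = center[3]
  )
  if (aa == "G" || length(sidechain) == 0L) {
    return(bb)
  }
  sc <- tibble::tibble(
    residue = residue, aa = aa,
    atom = names(sidechain),
    element = substr(names(sidechain), 1, 1),
    x = center[1] + vapply(sidechain, `[`, 0, 1),
    y = center[2] + vapply(sidechain, `[`, 0, 2),
    z = center[3] + vapply(sidechain, `[`, 0, 3)
  )
  dplyr::bind_rows(bb, sc)
}

# random compact structure: n residues placed on a jittered grid
random_toy_structure <- function(n_res = 20L, seed = 1L, spacing = 5) {
  set.seed(seed)
  aas <- sample(c("A", "L", "S", "G", "V", "K"), n_res, replace = TRUE)
  centers <- cbind(
    spacing * (seq_len(n_res) %% 5) + rnorm(n_res, 0, 0.8),
    spacing * (seq_len(n_res) %/% 5) + rnorm(n_res, 0, 0.8),
    rnorm(n_res, 0, 2)
  )
  atoms <- dplyr::bind_rows(lapply(seq_len(n_res), function(i) {
    toy_residue(i, aas[i], centers[i, ],
      sidechain = if (aas[i] == "G") list() else list(CB = c(0.5, 1.2, 0), CG = c(0.8, 2.2, 0.5))
    )
  }))
  new_protein_structure(atoms)
}

# random proper rotation (det +1) and translation
random_rigid_transform <- function(seed) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  rot <- qr.Q(qr_dec)
  rot <- rot %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rotation = rot, translation = rnorm(3, 0, 20))
}

apply_rigid <- function(structure, transform) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(transform$rotation)
  at$x <- xyz[, 1] + transform$translation[1]
  at$y <- xyz[, 2] + transform$translation[2]
  at$z <- xyz[, 3] + transform$translation[3]
  new_protein_structure(at, conformation = structure$conformation)
}

# fixed-width PDB writer for parser fixtures
pdb_record <- function(serial, name, altLoc, resName, chain, resSeq,
                       x, y, z, occ = 1, elem = "C", rec = "ATOM") {
  sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
    altLoc, resName, chain, resSeq, x, y, z, occ, 0, elem
  )
}

write_toy_pdb <- function(path, with_altloc = FALSE, with_ligand = FALSE,
                          with_water = FALSE) {
  lines <- c(
    pdb_record(1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    if (with_altloc) {
      c(
        pdb_record(2, "CA", "A", "ALA", "A", 1, 1.5, 0, 0, 0.4, "C"),
        pdb_record(3, "CA", "B", "ALA", "A", 1, 1.9, 0.2, 0, 0.6, "C")
      )
    } else {
      pdb_record(2, "CA", " ", "ALA", "A", 1, 1.5, 0, 0, 1, "C")
    },
    pdb_record(4, "C", " ", "ALA", "A", 1, 2.5, 1, 0, 1, "C"),
    pdb_record(5, "O", " ", "ALA", "A", 1, 3.5, 1, 0, 1, "O"),
    pdb_record(6, "CB", " ", "ALA", "A", 1, 1.5, -1.5, 0, 1, "C"),
    pdb_record(7, "N", " ", "GLY", "A", 2, 4, 2, 0, 1, "N"),
    pdb_record(8, "CA", " ", "GLY", "A", 2, 5, 2.5, 0, 1, "C"),
    pdb_record(9, "C", " ", "GLY", "A", 2, 6, 3, 0, 1, "C"),
    pdb_record(10, "O", " ", "GLY", "A", 2, 7, 3, 0, 1, "O"),
    pdb_record(11, "N", " ", "SER", "A", 3, 8, 4, 0, 1, "N"),
    pdb_record(12, "CA", " ", "SER", "A", 3, 9, 4.5, 0, 1, "C"),
    pdb_record(13, "C", " ", "SER", "A", 3, 10, 5, 0, 1, "C"),
    pdb_record(14, "O", " ", "SER", "A", 3, 11, 5, 0, 1, "O"),
    pdb_record(15, "OG", " ", "SER", "A", 3, 9, 6, 0, 1, "O"),
    if (with_water) pdb_record(90, "O", " ", "HOH", "A", 100, 20, 20, 20, 1, "O", "HETATM"),
    if (with_ligand) {
      c(
        pdb_record(91, "C1", " ", "GLC", "A", 200, 9, 2.5, 0, 1, "C", "HETATM"),
        pdb_record(92, "O1", " ", "GLC", "A", 200, 9.5, 3.5, 0, 1, "O", "HETATM")
      )
    },
    "END"
  )
  writeLines(lines, path)
  path
}
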