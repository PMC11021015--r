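# Per-residue structural features from PDB coordinates: solvent
# accessibility (rolling-probe), burial, weighted contact number, ligand
# contacts, inter-domain geometry, and domain labels.

#' Read a single-chain protein structure from a PDB file
#'
#' Parses a (possibly multi-model) PDB file, extracts one chain, resolves
#' alternate locations to the highest-occupancy conformer, drops waters and
#' hydrogens, and keeps named heteroatom groups (ligands) separately.
#'
#' @param pdb_path Path to a PDB file.
#' @param conformation Free-text conformation label carried through to
#'   feature tables (e.g. `"closed"`, `"super-open"`).
#' @param chain Chain identifier; default: the first chain in the file.
#' @return An object of class `protein_structure`: list with `atoms` (tibble:
#'   `residue`, `resid`, `aa`, `atom`, `element`, `x`, `y`, `z`,
#'   `backbone`), `ligands` (same shape plus `ligand` name), `conformation`,
#'   `n_frames`, and `frames` (list of coordinate matrices over the protein
#'   atoms, one per model).
#' @export
read_structure <- function(pdb_path, conformation = "other", chain = NULL) {
  if (!file.exists(pdb_path)) stop("PDB file not found: ", pdb_path)
  pdb <- tryCatch(
    bio3d::read.pdb(pdb_path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse PDB file ", pdb_path, ": ", conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  if (!chain %in% at$chain) {
    stop("chain '", chain, "' not present in ", pdb_path,
      " (available: ", paste(unique(at$chain), collapse = ", "), ")"
    )
  }
  keep <- at$chain == chain
  # drop waters and hydrogens
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  elem <- toupper(trimws(at$elesy))
  keep <- keep & elem != "H" & elem != "D"
  # alternate locations: highest occupancy wins, ties to the first record
  idx <- which(keep)
  alt_key <- paste(at$resno[idx], at$resid[idx], at$elety[idx])
  occ <- ifelse(is.na(at$o[idx]), 1, at$o[idx])
  ord <- idx[order(alt_key, -occ)]
  idx <- ord[!duplicated(paste(at$resno[ord], at$resid[ord], at$elety[ord]))]
  idx <- sort(idx)

  is_prot <- at$type[idx] == "ATOM"
  mk_tbl <- function(i) {
    tibble::tibble(
      residue = at$resno[i],
      resid = at$resid[i],
      aa = unname(.AA_ONE[.capitalize(at$resid[i])]),
      atom = at$elety[i],
      element = toupper(trimws(at$elesy[i])),
      x = at$x[i], y = at$y[i], z = at$z[i],
      backbone = at$elety[i] %in% .BACKBONE_ATOMS
    )
  }
  atoms <- mk_tbl(idx[is_prot])
  lig_idx <- idx[!is_prot]
  ligands <- mk_tbl(lig_idx)
  ligands$ligand <- at$resid[lig_idx]

  n_frames <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  prot_idx <- idx[is_prot]
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[f, ] else as.numeric(pdb$xyz)
    matrix(xyz[bio3d::atom2xyz(prot_idx)], ncol = 3L, byrow = TRUE)
  })

  new_protein_structure(atoms, ligands, conformation, frames)
}

#' Construct a protein structure from atom tables
#'
#' Low-level constructor used to build synthetic structures in code (tests,
#' simulations). `atoms` needs columns `residue`, `aa` (one-letter), `atom`,
#' `element`, `x`, `y`, `z`; `resid` and `backbone` are derived when absent.
#'
#' @param atoms Tibble of protein atoms.
#' @param ligands Optional tibble of ligand atoms with an extra `ligand`
#'   column.
#' @param conformation Conformation label.
#' @param frames Optional list of per-model coordinate matrices (defaults to
#'   the single frame given by `atoms`).
#' @return A `protein_structure`.
#' @export
new_protein_structure <- function(atoms, ligands = NULL, conformation = "other",
                                  frames = NULL) {
  atoms <- tibble::as_tibble(atoms)
  if (!"resid" %in% names(atoms)) atoms$resid <- toupper(aa_three(atoms$aa))
  if (!"backbone" %in% names(atoms)) atoms$backbone <- atoms$atom %in% .BACKBONE_ATOMS
  if (is.unsorted(atoms$residue)) stop("atom records must be ordered by residue index")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(ligands)) {
    ligands <- atoms[0, ]
    ligands$ligand <- character(0)
  }
  if (is.null(frames)) frames <- list(as.matrix(atoms[, c("x", "y", "z")]))
  structure(
    list(
      atoms = atoms, ligands = tibble::as_tibble(ligands),
      conformation = conformation, n_frames = length(frames), frames = frames
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(
    "protein_structure:", length(unique(x$atoms$residue)), "residues,",
    nrow(x$atoms), "heavy atoms,", nrow(x$ligands), "ligand atoms,",
    x$n_frames, "frame(s), conformation:", x$conformation, "\n"
  )
  invisible(x)
}

#' Solvent accessibility per residue
#'
#' Absolute solvent accessible surface area via a rolling-probe
#' (Shrake-Rupley) computation over heavy atoms: each atom is surrounded by
#' an approximately uniform sphere of test points at the solvent-extended
#' radius, and the accessible fraction is the share of points not inside
#' any neighboring atom's solvent-extended sphere. Per-residue SASA is
#' normalized by a theoretical per-residue maximum to give relative solvent
#' accessibility (rASA); residues with rASA at or below `buried_cutoff` are
#' classified as buried. Ligand atoms do not occlude the protein surface.
#'
#' @param structure A `protein_structure`.
#' @param probe_radius Probe sphere radius in angstrom (default 1.4, water).
#' @param n_points Test points per atom (default 960).
#' @param max_asa Named vector of per-residue maximum accessibilities
#'   (default [MAX_ASA_THEORETICAL]).
#' @param buried_cutoff rASA cutoff for burial (default 0.2, inclusive).
#' @return Tibble: `residue`, `aa`, `sasa` (A^2), `rasa`, `buried`.
#' @export
compute_rasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                         max_asa = MAX_ASA_THEORETICAL, buried_cutoff = 0.2) {
  at <- structure$atoms
  missing_aa <- unique(at$aa[!at$aa %in% names(max_asa)])
  if (length(missing_aa) > 0L || anyNA(at$aa)) {
    bad <- unique(at$resid[!at$aa %in% names(max_asa) | is.na(at$aa)])
    stop("residue type(s) absent from the max-ASA table: ", paste(bad, collapse = ", "))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- .vdw_radius(at$element) + probe_radius
  pts <- .fibonacci_sphere(n_points)

  n <- nrow(xyz)
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (radii + radii[i])^2 & seq_len(n) != i)
    p <- pts * radii[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > radii[j]^2
    }
    atom_sasa[i] <- 4 * pi * radii[i]^2 * mean(free)
  }

  res <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      residue = at$residue, aa = at$aa, sasa = atom_sasa
    ), .data$residue, .data$aa),
    sasa = sum(.data$sasa), .groups = "drop"
  )
  res$rasa <- res$sasa / unname(max_asa[res$aa])
  res$buried <- res$rasa <= buried_cutoff
  res
}

#' Weighted contact number per residue
#'
#' `WCN_i = sum_{j != i} s(r_ij)` with the rational switching function
#' `s(r) = (1 - (r/r0)^6) / (1 - (r/r0)^12)`, which simplifies to
#' `1 / (1 + (r/r0)^6)` and so takes the value 1/2 at `r = r0` by analytic
#' continuity. The inter-residue distance `r_ij` is the shortest distance
#' over all heavy-atom pairs when either residue is glycine, and the
#' shortest distance over sidechain heavy-atom pairs otherwise.
#'
#' @param structure A `protein_structure` with at least two residues.
#' @param r0 Switching distance in angstrom (default 7).
#' @return Tibble: `residue`, `aa`, `wcn`.
#' @export
compute_wcn <- function(structure, r0 = 7) {
  if (r0 <= 0) stop("r0 must be positive")
  at <- structure$atoms
  residues <- unique(at$residue)
  nres <- length(residues)
  if (nres < 2L) stop("need at least 2 residues to compute WCN")

  is_gly <- vapply(residues, function(r) at$resid[at$residue == r][1] == "GLY", TRUE)
  all_idx <- lapply(residues, function(r) which(at$residue == r))
  sc_idx <- lapply(residues, function(r) which(at$residue == r & !at$backbone))

  no_sc <- !is_gly & lengths(sc_idx) == 0L
  if (any(no_sc)) {
    warning(
      "non-glycine residue(s) without sidechain heavy atoms skipped in WCN pairs: ",
      paste(residues[no_sc], collapse = ", ")
    )
  }

  xyz <- as.matrix(at[, c("x", "y", "z")])
  rmat <- matrix(NA_real_, nres, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (j <= i) next
      use_all <- is_gly[i] || is_gly[j]
      ii <- if (use_all) all_idx[[i]] else sc_idx[[i]]
      jj <- if (use_all) all_idx[[j]] else sc_idx[[j]]
      if (length(ii) == 0L || length(jj) == 0L) next
      d2 <- outer(seq_along(ii), seq_along(jj), function(a, b) {
        (xyz[ii[a], 1] - xyz[jj[b], 1])^2 +
          (xyz[ii[a], 2] - xyz[jj[b], 2])^2 +
          (xyz[ii[a], 3] - xyz[jj[b], 3])^2
      })
      rmat[i, j] <- rmat[j, i] <- sqrt(min(d2))
    }
  }
  s <- wcn_switch(rmat, r0)
  wcn <- rowSums(s, na.rm = TRUE)
  tibble::tibble(
    residue = residues,
    aa = vapply(all_idx, function(ii) at$aa[ii[1]], ""),
    wcn = wcn
  )
}

#' Switching function used by the weighted contact number
#'
#' @param r Distance(s) in angstrom.
#' @param r0 Switching distance (default 7 angstrom).
#' @return `s(r) = (1 - (r/r0)^6)/(1 - (r/r0)^12) = 1/(1 + (r/r0)^6)`;
#'   `s(r0) = 1/2` by continuity.
#' @export
wcn_switch <- function(r, r0 = 7) {
  if (r0 <= 0) stop("r0 must be positive")
  1 / (1 + (r / r0)^6)
}

#' Flag residues in contact with a named ligand
#'
#' A residue is a ligand contact when the shortest distance between any of
#' its heavy atoms and any heavy atom of the ligand is strictly below
#' `cutoff`.
#'
#' @param structure A `protein_structure` whose `ligands` table contains
#'   `ligand_name`.
#' @param ligand_name Heteroatom group name (e.g. `"GLC"` for glucose).
#' @param cutoff Contact cutoff in angstrom (default 4, strict `<`).
#' @return Tibble: `residue`, `aa`, `min_dist`, `ligand_contact`.
#' @export
ligand_contacts <- function(structure, ligand_name, cutoff = 4) {
  lig <- structure$ligands[structure$ligands$ligand == ligand_name, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop(
      "ligand '", ligand_name, "' not present in structure (available: ",
      paste(unique(structure$ligands$ligand), collapse = ", "), ")"
    )
  }
  at <- structure$atoms
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  per_res <- dplyr::group_by(at, .data$residue)
  res_ids <- dplyr::group_keys(per_res)$residue
  mins <- vapply(dplyr::group_split(per_res), function(g) {
    axyz <- as.matrix(g[, c("x", "y", "z")])
    min(sqrt(pmax(
      outer(rowSums(axyz^2), rowSums(lxyz^2), "+") - 2 * axyz %*% t(lxyz), 0
    )))
  }, numeric(1))
  tibble::tibble(
    residue = res_ids,
    aa = at$aa[match(res_ids, at$residue)],
    min_dist = mins,
    ligand_contact = mins < cutoff
  )
}

#' Inter-domain cleft angle
#'
#' The planar angle (degrees) at the C-alpha atom of the middle residue in
#' `residues`, between the vectors to the C-alpha atoms of the first and
#' last residues. The default triple (109, 233, 229) tracks the opening
#' between the small and large domains of glucokinase. For multi-frame
#' structures one angle per frame is returned.
#'
#' @param structure A `protein_structure`.
#' @param residues Length-3 integer vector `(end, vertex, end)`.
#' @return Numeric vector of angles in degrees, one per frame.
#' @export
cleft_angle <- function(structure, residues = c(109L, 233L, 229L)) {
  stopifnot(length(residues) == 3L)
  ca <- .ca_rows(structure, residues)
  vapply(structure$frames, function(xyz) {
    v1 <- xyz[ca[1], ] - xyz[ca[2], ]
    v2 <- xyz[ca[3], ] - xyz[ca[2], ]
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }, numeric(1))
}

#' Distance between two C-alpha atoms
#'
#' Euclidean C-alpha to C-alpha distance in angstrom, per frame. The default
#' pair (159, 452) tracks the motion of glucokinase helix 13 relative to the
#' active-site loop.
#'
#' @param structure A `protein_structure`.
#' @param residues Length-2 integer vector.
#' @return Numeric vector of distances, one per frame.
#' @export
helix13_distance <- function(structure, residues = c(159L, 452L)) {
  stopifnot(length(residues) == 2L)
  ca <- .ca_rows(structure, residues)
  vapply(structure$frames, function(xyz) {
    sqrt(sum((xyz[ca[1], ] - xyz[ca[2], ])^2))
  }, numeric(1))
}

#' Label residues by structural domain
#'
#' @param n_residues Number of residues to label (residues `1:n_residues`).
#' @param domain_intervals Data frame with columns `domain`, `start`, `end`
#'   (inclusive intervals; must not overlap). Residues not covered by any
#'   interval default to `"hinge"`.
#' @return Tibble: `residue`, `domain`.
#' @export
assign_domains <- function(n_residues, domain_intervals = default_domain_intervals()) {
  di <- as.data.frame(domain_intervals)
  stopifnot(all(c("domain", "start", "end") %in% names(di)))
  if (any(di$start > di$end)) stop("domain intervals must have start <= end")
  ord <- order(di$start)
  di <- di[ord, ]
  if (nrow(di) > 1L && any(di$start[-1] <= di$end[-nrow(di)])) {
    stop("domain intervals overlap")
  }
  domain <- rep("hinge", n_residues)
  for (k in seq_len(nrow(di))) {
    lo <- max(1L, di$start[k])
    hi <- min(n_residues, di$end[k])
    if (lo <= hi) domain[lo:hi] <- di$domain[k]
  }
  tibble::tibble(residue = seq_len(n_residues), domain = domain)
}

#' Default domain intervals for glucokinase
#'
#' Approximate large/small/hinge domain intervals for the 465-residue
#' glucokinase fold, bundled as plain TSV configuration
#' (`extdata/gck_domains.tsv`). The file is a user-replaceable default, not
#' a structural ground truth: analyses of other proteins (or stricter domain
#' definitions) should supply their own interval table.
#'
#' @param path Path to a TSV with columns `domain`, `start`, `end`.
#' @return Data frame of intervals.
#' @export
default_domain_intervals <- function(path = system.file("extdata", "gck_domains.tsv",
                                       package = "mavemech"
                                     )) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Combine per-residue features into one table
#'
#' Convenience wrapper running [compute_rasa()], [compute_wcn()], optionally
#' [ligand_contacts()], and [assign_domains()] on one structure.
#'
#' @param structure A `protein_structure`.
#' @param ligand_name Optional ligand for contact flags.
#' @param domain_intervals Passed to [assign_domains()]; `NULL` labels all
#'   residues `"hinge"`.
#' @param ... Passed to [compute_rasa()].
#' @return Tibble: `residue`, `aa`, `sasa`, `rasa`, `buried`, `wcn`,
#'   `ligand_contact`, `domain`, `conformation`.
#' @export
residue_features <- function(structure, ligand_name = NULL,
                             domain_intervals = NULL, ...) {
  feat <- dplyr::left_join(
    compute_rasa(structure, ...),
    compute_wcn(structure)[, c("residue", "wcn")],
    by = "residue"
  )
  feat$ligand_contact <- if (is.null(ligand_name)) {
    NA
  } else {
    lc <- ligand_contacts(structure, ligand_name)
    lc$ligand_contact[match(feat$residue, lc$residue)]
  }
  dom <- if (is.null(domain_intervals)) {
    tibble::tibble(residue = feat$residue, domain = "hinge")
  } else {
    assign_domains(max(feat$residue), domain_intervals)
  }
  feat$domain <- dom$domain[match(feat$residue, dom$residue)]
  feat$conformation <- structure$conformation
  feat
}

# ---- internal ---------------------------------------------------------------

.ca_rows <- function(structure, residues) {
  at <- structure$atoms
  rows <- vapply(residues, function(r) {
    hit <- which(at$residue == r & at$atom == "CA")
    if (length(hit) == 0L) {
      stop("residue ", r, " has no CA atom in the structure")
    }
    hit[1]
  }, integer(1))
  rows
}

.vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

# near-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.capitalize <- function(x) {
  paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
}
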