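test_that("PDB fixtures round-trip through the parser", {
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), with_water = TRUE, with_ligand = TRUE)
  st <- read_structure(path, conformation = "closed")
  expect_equal(unique(st$atoms$residue), 1:3)
  expect_equal(st$atoms$aa[st$atoms$atom == "CA"], c("A", "G", "S"))
  expect_equal(st$atoms$x[st$atoms$atom == "N"], c(0, 4, 8))
  # waters dropped, ligand kept separately
  expect_false(any(st$atoms$resid == "HOH"))
  expect_false(any(st$ligands$ligand == "HOH"))
  expect_equal(sort(unique(st$ligands$ligand)), "GLC")
  expect_equal(nrow(st$ligands), 2)
  expect_error(read_structure(path, chain = "Z"), "chain 'Z'")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), with_altloc = TRUE)
  st <- read_structure(path)
  ca1 <- st$atoms[st$atoms$residue == 1 & st$atoms$atom == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 1.9) # the 0.6-occupancy B conformer
})

test_that("SASA responds to enclosure and is monotone in occlusion", {
  iso <- new_protein_structure(toy_residue(1, "A", c(0, 0, 0)))
  r_iso <- compute_rasa(iso, n_points = 480)
  expect_gt(r_iso$sasa, 0)
  expect_false(r_iso$buried)

  # fully enclosing shell of atoms: SASA collapses to 0
  shell_pts <- mavemech:::.fibonacci_sphere(200) * 4.5
  shell <- tibble::tibble(
    residue = 2L, aa = "G", atom = "CA", element = "C",
    x = shell_pts[, 1] + 0.9, y = shell_pts[, 2], z = shell_pts[, 3]
  )
  shell$atom <- paste0("CA", seq_len(nrow(shell))) # distinct atom names
  enclosed <- new_protein_structure(dplyr::bind_rows(
    toy_residue(1, "A", c(0, 0, 0)), shell
  ))
  r_enc <- compute_rasa(enclosed, n_points = 480)
  res1 <- r_enc[r_enc$residue == 1, ]
  expect_equal(res1$sasa, 0)
  expect_true(res1$buried)

  # adding atoms never increases SASA of existing residues
  partial <- new_protein_structure(dplyr::bind_rows(
    toy_residue(1, "A", c(0, 0, 0)),
    toy_residue(2, "L", c(4, 0, 0))
  ))
  r_part <- compute_rasa(partial, n_points = 480)
  expect_lte(r_part$sasa[r_part$residue == 1], r_iso$sasa + 1e-9)

  bad <- tibble::tibble(
    residue = 1L, aa = "X", atom = "CA", element = "C", x = 0, y = 0, z = 0
  )
  bad$resid <- "UNK"
  expect_error(compute_rasa(new_protein_structure(bad)), "UNK")
})

test_that("single-residue SASA matches an independent Monte-Carlo surface", {
  # oracle: random-direction rejection sampling instead of the Fibonacci
  # lattice used by the implementation
  st <- new_protein_structure(dplyr::bind_rows(
    toy_residue(1, "A", c(0, 0, 0)),
    toy_residue(2, "V", c(3.5, 1, 0))
  ))
  ours <- compute_rasa(st, n_points = 1920)

  mc_sasa <- function(atoms, probe = 1.4, n = 20000L) {
    set.seed(101)
    radii <- mavemech:::.vdw_radius(atoms$element) + probe
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    vapply(seq_len(nrow(atoms)), function(i) {
      dirs <- matrix(rnorm(3 * n), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      pts <- sweep(dirs * radii[i], 2, xyz[i, ], "+")
      free <- rep(TRUE, n)
      for (j in seq_len(nrow(atoms))[-i]) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 + (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 > radii[j]^2
      }
      4 * pi * radii[i]^2 * mean(free)
    }, numeric(1))
  }
  oracle <- mc_sasa(st$atoms)
  per_res <- tapply(oracle, st$atoms$residue, sum)
  expect_equal(ours$sasa, unname(as.numeric(per_res)), tolerance = 0.02)
})

test_that("WCN matches a brute-force double loop on random structures", {
  for (seed in c(1, 2, 3)) {
    st <- random_toy_structure(n_res = 20, seed = seed)
    ours <- compute_wcn(st, r0 = 7)

    at <- st$atoms
    residues <- unique(at$residue)
    is_gly <- vapply(residues, function(r) at$aa[at$residue == r][1] == "G", TRUE)
    brute <- numeric(length(residues))
    for (i in seq_along(residues)) {
      for (j in seq_along(residues)) {
        if (i == j) next
        use_all <- is_gly[i] || is_gly[j]
        ai <- at[at$residue == residues[i], ]
        aj <- at[at$residue == residues[j], ]
        if (!use_all) {
          ai <- ai[!ai$backbone, ]
          aj <- aj[!aj$backbone, ]
        }
        dmin <- Inf
        for (p in seq_len(nrow(ai))) {
          for (q in seq_len(nrow(aj))) {
            d <- sqrt((ai$x[p] - aj$x[q])^2 + (ai$y[p] - aj$y[q])^2 + (ai$z[p] - aj$z[q])^2)
            dmin <- min(dmin, d)
          }
        }
        x6 <- (dmin / 7)^6
        brute[i] <- brute[i] + if (abs(1 - x6) < 1e-12) 0.5 else (1 - x6) / (1 - x6^2)
      }
    }
    expect_equal(ours$wcn, brute, tolerance = 1e-9)
  }
})

test_that("WCN switching function has the right limits and midpoint", {
  expect_identical(wcn_switch(7, 7), 0.5)
  expect_equal(wcn_switch(1e-9, 7), 1, tolerance = 1e-12)
  expect_lt(wcn_switch(1e4, 7), 1e-15)
  # two single-sidechain residues exactly r0 apart contribute 0.5 each
  at <- dplyr::bind_rows(
    toy_residue(1, "A", c(0, 0, 0), sidechain = list(CB = c(0, 0, 1))),
    toy_residue(2, "A", c(0, 50, 0), sidechain = list(CB = c(0, -43, 1)))
  )
  w <- compute_wcn(new_protein_structure(at))
  expect_equal(w$wcn, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(compute_wcn(new_protein_structure(at), r0 = 0), "positive")
  # non-glycine residue without sidechain atoms triggers a warning
  stub <- dplyr::bind_rows(
    toy_residue(1, "A", c(0, 0, 0), sidechain = list()),
    toy_residue(2, "A", c(5, 0, 0))
  )
  expect_warning(compute_wcn(new_protein_structure(stub)), "without sidechain")
})

test_that("ligand contacts use a strict distance cutoff", {
  base <- toy_residue(1, "A", c(0, 0, 0), sidechain = list(CB = c(0, 0, 0)))
  lig <- tibble::tibble(
    residue = 900L, aa = NA_character_, atom = "C1", element = "C",
    x = 0, y = 3.9, z = 0, ligand = "GLC"
  )
  lig$resid <- "GLC"
  lig$backbone <- FALSE
  st <- new_protein_structure(base, ligands = lig)
  lc <- ligand_contacts(st, "GLC", cutoff = 4)
  expect_true(lc$ligand_contact) # 3.9 < 4

  lig4 <- lig
  lig4$y <- 4.0
  # nearest protein atom to the ligand is CB at the origin: exactly 4.0 away
  st4 <- new_protein_structure(base[base$atom %in% c("CB"), ], ligands = lig4)
  lc4 <- ligand_contacts(st4, "GLC", cutoff = 4)
  expect_false(lc4$ligand_contact) # 4.0 is not < 4

  expect_error(ligand_contacts(st, "ATP"), "ATP")

  # brute-force check on a random structure with a random ligand
  st_r <- random_toy_structure(n_res = 10, seed = 9)
  set.seed(10)
  lig_r <- tibble::tibble(
    residue = 901L, aa = NA_character_,
    atom = paste0("C", 1:4), element = "C",
    x = rnorm(4, 8, 3), y = rnorm(4, 8, 3), z = rnorm(4, 0, 2),
    ligand = "LIG", resid = "LIG", backbone = FALSE
  )
  st_r$ligands <- lig_r
  lc_r <- ligand_contacts(st_r, "LIG", cutoff = 5)
  at <- st_r$atoms
  for (res in unique(at$residue)) {
    sub <- at[at$residue == res, ]
    dmin <- Inf
    for (p in seq_len(nrow(sub))) {
      dmin <- min(dmin, sqrt((sub$x[p] - lig_r$x)^2 +
        (sub$y[p] - lig_r$y)^2 + (sub$z[p] - lig_r$z)^2))
    }
    expect_equal(lc_r$min_dist[lc_r$residue == res], dmin, tolerance = 1e-9)
    expect_equal(lc_r$ligand_contact[lc_r$residue == res], dmin < 5)
  }
})

test_that("cleft angle and helix distance are correct and rigid-invariant", {
  tri <- new_protein_structure(tibble::tibble(
    residue = 1:3, aa = "G", atom = "CA", element = "C",
    x = c(1, 0, 0), y = c(0, 0, 1), z = 0
  ))
  expect_equal(cleft_angle(tri, c(1, 2, 3)), 90)
  coll <- new_protein_structure(tibble::tibble(
    residue = 1:3, aa = "G", atom = "CA", element = "C",
    x = c(-2, 0, 5), y = 0, z = 0
  ))
  expect_equal(cleft_angle(coll, c(1, 2, 3)), 180)

  pair <- new_protein_structure(tibble::tibble(
    residue = c(159L, 452L), aa = "G", atom = "CA", element = "C",
    x = c(0, 3), y = c(0, 4), z = 0
  ))
  expect_equal(helix13_distance(pair), 5)
  same <- new_protein_structure(tibble::tibble(
    residue = c(159L, 452L), aa = "G", atom = "CA", element = "C",
    x = 1, y = 2, z = 3
  ))
  expect_equal(helix13_distance(same), 0)
  expect_error(helix13_distance(tri), "no CA|residue 159")

  st <- random_toy_structure(n_res = 12, seed = 4)
  a0 <- cleft_angle(st, c(2, 6, 9))
  d0 <- helix13_distance(st, c(1, 12))
  for (seed in 1:20) {
    tr <- random_rigid_transform(seed)
    st_t <- apply_rigid(st, tr)
    expect_equal(cleft_angle(st_t, c(2, 6, 9)), a0, tolerance = 1e-9)
    expect_equal(helix13_distance(st_t, c(1, 12)), d0, tolerance = 1e-9)
  }
})

test_that("multi-model PDB files yield one geometry value per frame", {
  mk <- function(shift) {
    c(
      pdb_record(1, "CA", " ", "GLY", "A", 1, 0 + shift, 0, 0),
      pdb_record(2, "CA", " ", "GLY", "A", 2, 3 + shift, 4, 0),
      pdb_record(3, "CA", " ", "GLY", "A", 3, 3 + shift, 4, 7)
    )
  }
  path <- tempfile(fileext = ".pdb")
  writeLines(
    c("MODEL     1", mk(0), "ENDMDL", "MODEL     2", mk(2.5), "ENDMDL", "END"),
    path
  )
  st <- read_structure(path)
  expect_equal(st$n_frames, 2)
  # rigid x-shift between the models: distances and angles unchanged
  expect_equal(helix13_distance(st, c(1, 2)), c(5, 5))
  expect_equal(length(cleft_angle(st, c(1, 2, 3))), 2)
})

test_that("domain assignment labels intervals and rejects overlaps", {
  di <- data.frame(
    domain = c("large", "small"), start = c(2L, 11L), end = c(10L, 20L)
  )
  lab <- assign_domains(25L, di)
  expect_equal(lab$domain[5], "large")
  expect_equal(lab$domain[15], "small")
  expect_equal(lab$domain[1], "hinge")
  expect_equal(lab$domain[23], "hinge")

  bad <- data.frame(domain = c("a", "b"), start = c(2L, 8L), end = c(10L, 12L))
  expect_error(assign_domains(20L, bad), "overlap")

  # bundled default intervals cover a 465-residue protein
  lab465 <- assign_domains(465L)
  expect_equal(nrow(lab465), 465)
  expect_setequal(unique(lab465$domain), c("large", "small", "hinge"))
})

test_that("feature table combines accessibility, contacts, and domains", {
  st <- random_toy_structure(n_res = 8, seed = 5)
  fe <- residue_features(st,
    domain_intervals = data.frame(domain = "large", start = 1L, end = 4L)
  )
  expect_equal(nrow(fe), 8)
  expect_true(all(c("sasa", "rasa", "buried", "wcn", "domain", "conformation") %in% names(fe)))
  expect_equal(fe$domain, rep(c("large", "hinge"), each = 4))

  # burial differs between a compact and a stretched arrangement
  stretched <- st
  stretched$atoms$x <- stretched$atoms$x * 4
  stretched$atoms$y <- stretched$atoms$y * 4
  fe2 <- residue_features(new_protein_structure(stretched$atoms))
  expect_gte(sum(fe$buried), sum(fe2$buried))
})
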