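mk_scores <- function(position, alt, score, wt = "A") {
  tibble::tibble(
    position = position, wt_aa = wt, alt_aa = alt,
    var_class = ifelse(alt == "*", "nonsense", ifelse(alt == wt, "synonymous", "missense")),
    score = score
  )
}

test_that("Rosetta unit conversion divides by 2.9", {
  expect_equal(convert_rosetta_units(5.8), 2)
  expect_equal(convert_rosetta_units(0), 0)
  expect_equal(convert_rosetta_units(-2.9), -1)
  expect_equal(convert_rosetta_units(c(2.9, 29)), c(1, 10))
})

test_that("loop-model averaging handles missing predictions", {
  df <- tibble::tibble(
    position = c(157L, 158L, 159L), wt_aa = "E", alt_aa = "K",
    m1 = c(1, 2, NA), m2 = c(1, 2, NA), m3 = c(1, 3, NA),
    m4 = c(1, 4, NA), m5 = c(1, 5, NA)
  )
  expect_message(out <- average_loop_models(df), "1 variant")
  expect_equal(out$ddg, c(1, 3.2, NA))
  expect_equal(out$n_models, c(5, 5, 0))

  one_missing <- tibble::tibble(
    position = 1L, wt_aa = "A", alt_aa = "V",
    m1 = 1, m2 = 2, m3 = NA, m4 = 4, m5 = 5
  )
  expect_equal(average_loop_models(one_missing)$ddg, 3)
  expect_equal(average_loop_models(one_missing)$n_models, 4)
})

test_that("stability table derives shift and binding scores", {
  st <- stability_table(tibble::tibble(
    position = 1:2, wt_aa = "A", alt_aa = c("V", "L"),
    ddg_closed = c(3.0, 5.0), ddg_superopen = c(0.5, 4.0),
    ddg_closed_holo = c(5.5, 5.5)
  ))
  expect_equal(st$ddg_shift, c(-2.5, -1.0))
  expect_equal(st$binding_diff, c(2.5, 0.5))

  # antisymmetry: swapping the states negates the shift score
  sw <- stability_table(tibble::tibble(
    position = 1:2, wt_aa = "A", alt_aa = c("V", "L"),
    ddg_closed = c(0.5, 4.0), ddg_superopen = c(3.0, 5.0)
  ))
  expect_equal(sw$ddg_shift, -st$ddg_shift)

  ros <- stability_table(
    tibble::tibble(position = 1L, wt_aa = "A", alt_aa = "V", ddg_closed = 5.8),
    units = "rosetta"
  )
  expect_equal(ros$ddg_closed, 2)
})

test_that("merge is an outer join with sequence-consistency checks", {
  ab <- mk_scores(c(2L, 3L, 4L), c("V", "L", "I"), c(1, 0.5, 0.2))
  ac <- mk_scores(c(3L, 4L, 5L), c("L", "I", "F"), c(0.9, 0.1, 0.3))
  m <- suppressMessages(merge_tables(ab, ac))
  expect_equal(nrow(m), 4)
  expect_equal(sum(is.finite(m$abundance_score) & is.finite(m$activity_score)), 2)

  conflicting <- mk_scores(7L, "V", 1, wt = "E")
  ab2 <- dplyr::bind_rows(ab, mk_scores(7L, "V", 1, wt = "K"))
  expect_error(
    suppressMessages(merge_tables(ab2, dplyr::bind_rows(ac, conflicting))),
    "conflicting wild-type"
  )

  dup <- dplyr::bind_rows(ab, ab[1, ])
  expect_error(suppressMessages(merge_tables(dup, ac)), "duplicate")
})

test_that("quadrants use strict thresholds and match reported score pairs", {
  tbl <- tibble::tibble(
    position = c(157L, 161L, 1L, 2L, 3L),
    wt_aa = c("E", "K", "A", "A", "A"),
    alt_aa = c("K", "E", "V", "L", "I"),
    abundance_score = c(0.96, 0.92, 0.58, 0.5, 0.5),
    activity_score = c(-0.13, 0.56, 0.2, 0.66, 0.2)
  )
  out <- classify_quadrants(tbl, t_abund = 0.58, t_act = 0.66)
  # charge-reversal ion-pair variants: hypoactive but normally abundant
  expect_equal(out$quadrant[1], "lowact_normabund") # E157K
  expect_equal(out$quadrant[2], "lowact_normabund") # K161E
  # boundary: a score exactly at the threshold is NOT low (strict <)
  expect_equal(out$quadrant[3], "lowact_normabund")
  expect_equal(out$quadrant[4], "normact_lowabund")
  expect_equal(out$quadrant[5], "lowact_lowabund")
  expect_true(out$loss_of_abundance[5])
  expect_false(any(out$loss_of_abundance[1:4]))
})

test_that("per-position medians summarize unflagged missense variants", {
  sc <- mk_scores(
    position = c(2L, 2L, 2L, 3L, 2L, 2L),
    alt = c("V", "L", "I", "F", "*", "A"),
    score = c(0.2, 0.8, 1.0, 0.4, 0.0, 1.0)
  )
  med <- per_position_median(sc)
  expect_equal(med$median_score[med$position == 2], 0.8) # nonsense+syn excluded
  expect_equal(med$median_score[med$position == 3], 0.4) # single variant

  sc$low_input <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  med2 <- per_position_median(sc)
  expect_equal(med2$median_score[med2$position == 2], 0.6) # median of 0.2, 1.0

  # brute-force recomputation over a random toy table
  set.seed(55)
  toy <- tibble::tibble(
    position = sample(2:6, 60, replace = TRUE),
    wt_aa = "A",
    alt_aa = sample(c("V", "L", "I", "F", "W", "Y", "C", "D", "E", "G", "H", "K"), 60, TRUE),
    var_class = "missense",
    score = runif(60)
  )
  toy <- toy[!duplicated(paste(toy$position, toy$alt_aa)), ]
  med3 <- per_position_median(toy)
  for (p in unique(toy$position)) {
    expect_equal(
      med3$median_score[med3$position == p],
      median(toy$score[toy$position == p])
    )
  }
})

test_that("domain enrichment counts low-median and buried positions", {
  med <- tibble::tibble(
    position = 1:20, n = 1L,
    median_score = c(rep(0.2, 3), rep(0.9, 7), rep(0.2, 4), rep(0.9, 6))
  )
  fe <- tibble::tibble(
    residue = 1:20,
    buried = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8)),
    domain = rep(c("large", "small"), each = 10),
    conformation = "closed"
  )
  out <- domain_enrichment(med, fe, t_abund = 0.58)
  large <- out[out$domain == "large", ]
  expect_equal(large$frac_low, 0.3) # 3 of 10
  expect_equal(large$low_to_buried_ratio, 3 / 8)
  small <- out[out$domain == "small", ]
  expect_equal(small$frac_low, 0.4)
  expect_equal(small$low_to_buried_ratio, 4 / 2)

  # a domain with no scored positions is undefined, not zero
  fe2 <- dplyr::bind_rows(fe, tibble::tibble(
    residue = 21L, buried = FALSE, domain = "hinge", conformation = "closed"
  ))
  out2 <- domain_enrichment(med, fe2, t_abund = 0.58)
  expect_true(is.na(out2$frac_low[out2$domain == "hinge"]))
})

test_that("conformational-shift and binding rules apply their thresholds", {
  st <- stability_table(tibble::tibble(
    position = 1:4, wt_aa = "A", alt_aa = c("V", "L", "I", "F"),
    ddg_closed = c(3.0, 5.0, 1.0, 2.0),
    ddg_superopen = c(0.5, 4.0, 1.0, 0.0),
    ddg_closed_holo = c(5.5, 5.9, 3.0, 2.0)
  ))
  out <- conformational_shift_candidates(st, t_shift = 2, t_superopen_cap = 2)
  expect_equal(out$conformational_shift_candidate, c(TRUE, FALSE, FALSE, TRUE))
  # row 2: shift only -1; also super-open cap exceeded. row 3: shift 0.

  bind <- binding_affinity_flags(st, t_bind = 2)
  expect_equal(bind$binding_affinity_decrease, c(TRUE, FALSE, TRUE, FALSE))
  # row 3: diff exactly 2.0 is flagged (inclusive); row 4: diff 0

  # monotonicity: relaxing t_abund never removes a loss_of_abundance label
  tbl <- tibble::tibble(
    position = 1:50, wt_aa = "A", alt_aa = "V",
    abundance_score = seq(0, 1, length.out = 50),
    activity_score = 0.1
  )
  lab1 <- classify_quadrants(tbl, t_abund = 0.4)$loss_of_abundance
  lab2 <- classify_quadrants(tbl, t_abund = 0.7)$loss_of_abundance
  expect_true(all(lab2[lab1]))
})

test_that("quadrant summary counts and conditional percentages are exact", {
  tbl <- tibble::tibble(
    position = 1:4, wt_aa = "A", alt_aa = c("V", "L", "I", "F"),
    abundance_score = c(0.1, 0.9, 0.1, 0.9),
    activity_score = c(0.1, 0.1, 0.9, 0.9)
  )
  qs <- quadrant_summary(classify_quadrants(tbl))
  expect_equal(qs$counts$pct, rep(25, 4))
  expect_equal(qs$n_total, 4)

  # hand-counted 10-variant table
  set.seed(77)
  tbl10 <- tibble::tibble(
    position = 1:10, wt_aa = "A", alt_aa = "V",
    abundance_score = c(0.2, 0.2, 0.2, 0.9, 0.9, 0.9, 0.9, 0.2, 0.9, NA),
    activity_score = c(0.1, 0.1, 0.9, 0.1, 0.1, 0.9, 0.9, 0.1, NA, 0.5)
  )
  out <- suppressMessages(classify_quadrants(tbl10))
  qs10 <- quadrant_summary(out)
  expect_equal(qs10$n_total, 8) # two incomplete rows dropped
  cn <- qs10$counts
  expect_equal(cn$n[cn$quadrant == "lowact_lowabund"], 3)
  expect_equal(cn$n[cn$quadrant == "lowact_normabund"], 2)
  expect_equal(cn$n[cn$quadrant == "normact_lowabund"], 1)
  expect_equal(cn$n[cn$quadrant == "normact_normabund"], 2)
  # 3 of 5 low-activity variants are low-abundance
  expect_equal(qs10$conditional$pct_lowact_lowabund, 60)
  # 1 of 4 low-abundance variants is not low-activity
  expect_equal(qs10$conditional$pct_lowabund_not_lowact, 25)
  # quadrant counts sum to the complete-case total
  expect_equal(sum(cn$n), qs10$n_total)

  expect_error(quadrant_summary(tibble::tibble(quadrant = NA_character_)), "no variants")
})
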