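# Merging abundance, activity, stability, and structure tables and
# classifying the mechanism behind each variant's behavior.

#' Convert Rosetta energy units to kcal/mol
#'
#' @param values Numeric vector of Rosetta energies.
#' @param factor Division factor (default 2.9).
#' @return `values / factor`.
#' @export
convert_rosetta_units <- function(values, factor = 2.9) {
  values / factor
}

#' Average stability predictions over structural models
#'
#' When a flexible region is modeled as an ensemble (several structural
#' models of the same state), stability changes are predicted per model and
#' averaged per variant. Missing predictions are dropped from the mean; the
#' number of contributing models is recorded.
#'
#' @param per_model_ddg Data frame with key columns `position`, `wt_aa`,
#'   `alt_aa` and one numeric column per structural model.
#' @return Tibble: keys, `ddg` (mean over models), `n_models`.
#' @export
average_loop_models <- function(per_model_ddg) {
  keys <- c("position", "wt_aa", "alt_aa")
  stopifnot(all(keys %in% names(per_model_ddg)))
  model_cols <- setdiff(names(per_model_ddg), keys)
  if (length(model_cols) == 0L) stop("need at least one model column")
  m <- as.matrix(per_model_ddg[model_cols])
  n_models <- rowSums(is.finite(m))
  ddg <- rowMeans(m, na.rm = TRUE)
  ddg[n_models == 0L] <- NA_real_
  if (any(n_models == 0L)) {
    message(sum(n_models == 0L), " variant(s) missing from all models; ddg left missing")
  }
  out <- tibble::as_tibble(per_model_ddg[keys])
  out$ddg <- ddg
  out$n_models <- n_models
  out
}

#' Build a stability table with derived conformational scores
#'
#' @param ddg Data frame with keys `position`, `wt_aa`, `alt_aa` and columns
#'   `ddg_closed`, `ddg_closed_holo`, `ddg_superopen` (any may be absent).
#' @param units `"kcal/mol"` (default) or `"rosetta"`; Rosetta values are
#'   converted with [convert_rosetta_units()].
#' @return Tibble with the input columns in kcal/mol plus `ddg_shift`
#'   (`ddg_superopen - ddg_closed`; negative values destabilize the closed
#'   state more, favoring a shift to the super-open state) and
#'   `binding_diff` (`ddg_closed_holo - ddg_closed`; large values flag a
#'   reduced ligand binding affinity).
#' @export
stability_table <- function(ddg, units = c("kcal/mol", "rosetta")) {
  units <- match.arg(units)
  out <- tibble::as_tibble(ddg)
  val_cols <- intersect(c("ddg_closed", "ddg_closed_holo", "ddg_superopen"), names(out))
  if (length(val_cols) == 0L) stop("no ddg columns found")
  if (units == "rosetta") {
    for (cl in val_cols) out[[cl]] <- convert_rosetta_units(out[[cl]])
  }
  if (all(c("ddg_closed", "ddg_superopen") %in% names(out))) {
    out$ddg_shift <- out$ddg_superopen - out$ddg_closed
  }
  if (all(c("ddg_closed", "ddg_closed_holo") %in% names(out))) {
    out$binding_diff <- out$ddg_closed_holo - out$ddg_closed
  }
  out
}

#' Merge abundance, activity, stability, and structure tables
#'
#' Outer join keyed on `(position, wt_aa, alt_aa)`; per-position features
#' join on `position`. Duplicate variant keys within a table and conflicting
#' wild-type residues across tables are hard errors (they indicate a
#' sequence mismatch, not missing data). Join statistics are reported via
#' `message()`.
#'
#' @param abundance Score table whose `score` column becomes
#'   `abundance_score`.
#' @param activity Score table whose `score` column becomes
#'   `activity_score`.
#' @param stability Optional [stability_table()].
#' @param features Optional per-position feature table (from
#'   [residue_features()]); its `buried`/`domain` columns join by position.
#' @return Unified variant tibble.
#' @export
merge_tables <- function(abundance, activity, stability = NULL, features = NULL) {
  keys <- c("position", "wt_aa", "alt_aa")
  ab <- .check_variant_table(abundance, keys, "abundance")
  ac <- .check_variant_table(activity, keys, "activity")
  ab <- dplyr::rename(ab, abundance_score = "score")
  ac <- dplyr::rename(ac, activity_score = "score")
  ac <- ac[, c(keys, "activity_score")]

  merged <- dplyr::full_join(ab, ac, by = keys, suffix = c("", ".activity"))
  .check_wt_consistency(merged)

  if (!is.null(stability)) {
    st <- .check_variant_table(stability, keys, "stability", require_score = FALSE)
    merged <- dplyr::full_join(merged, st, by = keys, suffix = c("", ".stability"))
    .check_wt_consistency(merged)
  }
  if (!is.null(features)) {
    fe <- dplyr::rename(features, position = "residue")
    merged <- dplyr::left_join(merged, fe, by = "position", suffix = c("", ".features"))
  }
  n_complete <- sum(is.finite(merged$abundance_score) & is.finite(merged$activity_score))
  message(
    "merged ", nrow(merged), " variants; ", n_complete,
    " with both abundance and activity scores"
  )
  merged
}

#' Classify variants into abundance/activity quadrants
#'
#' Low abundance means `abundance_score < t_abund` and low activity means
#' `activity_score < t_act` (both strict). Variants missing either score get
#' an `NA` quadrant and are excluded from counts. Variants that are both
#' low-activity and low-abundance are labeled `loss_of_abundance`.
#'
#' @param table Merged variant table with `abundance_score` and
#'   `activity_score` columns.
#' @param t_abund Low-abundance threshold (default 0.58, typically from
#'   [fit_mixture()]).
#' @param t_act Low-activity threshold (default 0.66).
#' @return The table with added `low_abundance`, `low_activity`, `quadrant`,
#'   and `loss_of_abundance` columns.
#' @export
classify_quadrants <- function(table, t_abund = 0.58, t_act = 0.66) {
  out <- table
  out$low_abundance <- out$abundance_score < t_abund
  out$low_activity <- out$activity_score < t_act
  out$quadrant <- dplyr::case_when(
    out$low_activity & out$low_abundance ~ "lowact_lowabund",
    out$low_activity & !out$low_abundance ~ "lowact_normabund",
    !out$low_activity & out$low_abundance ~ "normact_lowabund",
    !out$low_activity & !out$low_abundance ~ "normact_normabund"
  )
  n_dropped <- sum(is.na(out$quadrant))
  if (n_dropped > 0L) {
    message(n_dropped, " variant(s) missing a score; excluded from quadrant counts")
  }
  out$loss_of_abundance <- !is.na(out$quadrant) & out$quadrant == "lowact_lowabund"
  out
}

#' Per-position median score
#'
#' The per-position summary used for heatmap MED rows and along-sequence
#' profiles: by default the median over unflagged missense variants at each
#' position (nonsense variants are displayed separately, synonymous are
#' anchors).
#'
#' @param scores Score table with `position`, `var_class`, `score`, and
#'   (optionally) flag columns.
#' @param classes Variant classes included (default `"missense"`).
#' @param use_flagged Include flagged variants (default `FALSE`).
#' @return Tibble: `position`, `n`, `median_score`; positions without any
#'   usable variant are omitted.
#' @export
per_position_median <- function(scores, classes = "missense", use_flagged = FALSE) {
  use <- scores$var_class %in% classes & is.finite(scores$score)
  if (!use_flagged) {
    for (fl in c("low_input", "replicate_disagreement", "unscored")) {
      if (fl %in% names(scores)) use <- use & !scores[[fl]]
    }
  }
  dplyr::summarise(
    dplyr::group_by(scores[use, , drop = FALSE], .data$position),
    n = dplyr::n(),
    median_score = stats::median(.data$score),
    .groups = "drop"
  )
}

#' Domain enrichment of low-scoring positions
#'
#' Per domain: the fraction of positions whose median score falls below
#' `t_abund`, and the ratio of low-median positions to buried positions
#' (burial evaluated separately under each conformation's features). The
#' ratio normalizes low-abundance enrichment for how much of a domain is
#' buried.
#'
#' @param medians Output of [per_position_median()].
#' @param features Per-position feature table with `residue`, `buried`,
#'   `domain`, `conformation` (rows may span several conformations).
#' @param t_abund Low-score threshold (strict `<`).
#' @return Tibble keyed by `domain` and `conformation` with `n_positions`,
#'   `n_low`, `frac_low`, `n_buried`, `low_to_buried_ratio`. Domains with no
#'   scored positions are reported with `NA` (undefined), not zero.
#' @export
domain_enrichment <- function(medians, features, t_abund = 0.58) {
  fe <- dplyr::rename(features, position = "residue")
  df <- dplyr::inner_join(
    medians, fe[, c("position", "buried", "domain", "conformation")],
    by = "position"
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$domain, .data$conformation),
    n_positions = dplyr::n(),
    n_low = sum(.data$median_score < t_abund),
    frac_low = .data$n_low / .data$n_positions,
    n_buried = sum(.data$buried),
    low_to_buried_ratio = ifelse(.data$n_buried > 0, .data$n_low / .data$n_buried, NA_real_),
    .groups = "drop"
  )
  all_domains <- unique(fe$domain)
  missing_domains <- setdiff(all_domains, out$domain)
  if (length(missing_domains) > 0L) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      domain = missing_domains, conformation = NA_character_,
      n_positions = 0L, n_low = NA_integer_, frac_low = NA_real_,
      n_buried = NA_integer_, low_to_buried_ratio = NA_real_
    ))
  }
  out
}

#' Flag conformational-shift candidates from stability differences
#'
#' A variant is predicted to shift the conformational equilibrium toward
#' the inactive (super-open) state when it destabilizes the closed state
#' much more than the super-open state (`ddg_shift <= -t_shift`) while not
#' severely destabilizing the super-open state itself
#' (`ddg_superopen <= t_superopen_cap`), which would instead reduce
#' abundance.
#'
#' @param stability A [stability_table()] with `ddg_shift` and
#'   `ddg_superopen`.
#' @param t_shift Minimum closed-vs-super-open destabilization difference in
#'   kcal/mol (default 2).
#' @param t_superopen_cap Maximum tolerated super-open destabilization in
#'   kcal/mol (default 2).
#' @return Logical vector `conformational_shift_candidate` (as a column if a
#'   data frame is supplied).
#' @export
conformational_shift_candidates <- function(stability, t_shift = 2,
                                            t_superopen_cap = 2) {
  flag <- stability$ddg_shift <= -t_shift &
    stability$ddg_superopen <= t_superopen_cap
  out <- stability
  out$conformational_shift_candidate <- !is.na(flag) & flag
  out
}

#' Flag variants predicted to reduce ligand binding affinity
#'
#' A variant is predicted to decrease substrate binding when its stability
#' change is at least `t_bind` kcal/mol larger in the ligand-bound (holo)
#' structure than in the ligand-free structure (inclusive threshold).
#'
#' @param stability A [stability_table()] with `binding_diff`.
#' @param t_bind Threshold in kcal/mol (default 2, inclusive `>=`).
#' @return The table with a logical `binding_affinity_decrease` column.
#' @export
binding_affinity_flags <- function(stability, t_bind = 2) {
  flag <- stability$binding_diff >= t_bind
  out <- stability
  out$binding_affinity_decrease <- !is.na(flag) & flag
  out
}

#' Quadrant counts, percentages, and conditional shares
#'
#' @param mechanism_table Output of [classify_quadrants()].
#' @return A list with `counts` (tibble: quadrant, n, pct), `n_total`
#'   (complete-case variants), and `conditional`: full-precision and
#'   integer-rounded percentages of low-activity variants that are also
#'   low-abundance (`pct_lowact_lowabund`) and of low-abundance variants
#'   that are not low-activity (`pct_lowabund_not_lowact`).
#' @export
quadrant_summary <- function(mechanism_table) {
  q <- mechanism_table$quadrant[!is.na(mechanism_table$quadrant)]
  if (length(q) == 0L) stop("no variants with both scores; cannot summarize quadrants")
  levels <- c(
    "lowact_lowabund", "lowact_normabund",
    "normact_lowabund", "normact_normabund"
  )
  n <- vapply(levels, function(l) sum(q == l), integer(1))
  counts <- tibble::tibble(
    quadrant = levels, n = unname(n), pct = unname(100 * n / length(q))
  )
  n_lowact <- n[["lowact_lowabund"]] + n[["lowact_normabund"]]
  n_lowabund <- n[["lowact_lowabund"]] + n[["normact_lowabund"]]
  pct_ll <- if (n_lowact > 0) 100 * n[["lowact_lowabund"]] / n_lowact else NA_real_
  pct_ln <- if (n_lowabund > 0) 100 * n[["normact_lowabund"]] / n_lowabund else NA_real_
  list(
    counts = counts,
    n_total = length(q),
    conditional = list(
      pct_lowact_lowabund = pct_ll,
      pct_lowact_lowabund_rounded = round(pct_ll),
      pct_lowabund_not_lowact = pct_ln,
      pct_lowabund_not_lowact_rounded = round(pct_ln)
    )
  )
}

# ---- internal ---------------------------------------------------------------

.check_variant_table <- function(df, keys, what, require_score = TRUE) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(keys, names(df))
  if (length(missing_cols) > 0L) {
    stop(what, " table is missing key column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (require_score && !"score" %in% names(df)) {
    stop(what, " table has no 'score' column")
  }
  key <- paste(df$position, df$alt_aa)
  if (anyDuplicated(key)) {
    stop(what, " table has duplicate variant keys, e.g. position ",
      df$position[duplicated(key)][1]
    )
  }
  df
}

.check_wt_consistency <- function(merged) {
  wt_cols <- grep("^wt_aa", names(merged), value = TRUE)
  if (length(wt_cols) < 2L) {
    # after a full join on keys there is one wt column; check across positions
    chk <- stats::aggregate(wt_aa ~ position, data = merged, FUN = function(v) length(unique(v)))
    bad <- chk$position[chk$wt_aa > 1L]
    if (length(bad) > 0L) {
      stop(
        "conflicting wild-type residues at position(s) ",
        paste(utils::head(bad, 5L), collapse = ", "),
        "; the tables describe different sequences"
      )
    }
  }
  invisible(TRUE)
}
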