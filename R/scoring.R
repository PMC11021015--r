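# From tile-seq counts to normalized abundance scores.
#
# The scoring chain is: wild-type background subtraction on the frequency
# scale -> log-enrichment per replicate -> anchoring on synonymous (1) and
# nonsense (0) medians -> replicate filtering -> Baldi-Long regularization of
# the replicate standard error against a regression-based prior.

#' Subtract the wild-type-control background from variant frequencies
#'
#' Converts counts to frequencies per tile/replicate/condition and removes
#' the spurious-variant background measured in the wild-type-template control
#' channel: `f_corrected = max(0, count/depth - count_wtctrl/depth_wtctrl)`,
#' computed separately for the pre- and post-selection channels.
#'
#' @param counts Count tibble with the schema produced by
#'   [simulate_counts()]: `position`, `wt_aa`, `alt_aa`, `var_class`, `tile`,
#'   `replicate`, `condition` (`pre`/`post`/`wtctrl`), `count`, `depth`.
#'   `var_class = "wt"` remainder rows are ignored.
#' @return One row per variant/tile/replicate with corrected frequencies
#'   `f_pre`, `f_post`, raw counts `pre_count`, `post_count`, and channel
#'   depths `depth_pre`, `depth_post`.
#' @export
subtract_wt_background <- function(counts) {
  need <- c(
    "position", "wt_aa", "alt_aa", "var_class", "tile", "replicate",
    "condition", "count", "depth"
  )
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0L) {
    stop("count table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- dplyr::filter(counts, .data$var_class != "wt")

  have <- dplyr::distinct(counts, .data$tile, .data$replicate, .data$condition)
  chk <- tidyr::pivot_wider(
    dplyr::mutate(have, present = TRUE),
    names_from = "condition", values_from = "present", values_fill = FALSE
  )
  for (cond in c("pre", "post", "wtctrl")) {
    if (!cond %in% names(chk)) chk[[cond]] <- FALSE
    bad <- chk[!chk[[cond]], , drop = FALSE]
    if (nrow(bad) > 0L) {
      stop(
        "condition '", cond, "' missing for tile ", bad$tile[1],
        ", replicate ", bad$replicate[1]
      )
    }
  }

  wide <- tidyr::pivot_wider(
    dplyr::mutate(counts, freq = .data$count / .data$depth),
    id_cols = c("position", "wt_aa", "alt_aa", "var_class", "tile", "replicate"),
    names_from = "condition", values_from = c("count", "freq", "depth")
  )
  tibble::tibble(
    position = wide$position, wt_aa = wide$wt_aa, alt_aa = wide$alt_aa,
    var_class = wide$var_class, tile = wide$tile, replicate = wide$replicate,
    pre_count = wide$count_pre, post_count = wide$count_post,
    depth_pre = wide$depth_pre, depth_post = wide$depth_post,
    f_pre = pmax(0, wide$freq_pre - wide$freq_wtctrl),
    f_post = pmax(0, wide$freq_post - wide$freq_wtctrl)
  )
}

#' Per-replicate log-enrichment scores
#'
#' `rho = log((f_post + eps_post) / (f_pre + eps_pre))` in natural-log
#' units. The pseudofrequency bounds scores for variants that drop to zero
#' reads after selection; by default it is `1 / (10 * depth)` of the
#' respective channel.
#'
#' @param frequencies Output of [subtract_wt_background()].
#' @param pseudofrequency A single positive pseudofrequency applied to both
#'   channels, or `NULL` (default) for the depth-scaled rule.
#' @return The input with an added `rho` column.
#' @export
raw_scores <- function(frequencies, pseudofrequency = NULL) {
  if (is.null(pseudofrequency)) {
    eps_pre <- 1 / (10 * frequencies$depth_pre)
    eps_post <- 1 / (10 * frequencies$depth_post)
  } else {
    if (length(pseudofrequency) != 1L || !is.finite(pseudofrequency) ||
      pseudofrequency <= 0) {
      stop("pseudofrequency must be a single positive number")
    }
    eps_pre <- eps_post <- pseudofrequency
  }
  dplyr::mutate(frequencies,
    rho = log((.data$f_post + eps_post) / (.data$f_pre + eps_pre))
  )
}

#' Anchor log-enrichment scores on synonymous and nonsense medians
#'
#' Per replicate, maps `rho` affinely so that the median of unexcluded
#' nonsense variants is 0 and the median of unexcluded synonymous variants
#' is 1:
#' `phi = (rho - median_nonsense) / (median_synonymous - median_nonsense)`.
#'
#' @param rho_table Output of [raw_scores()].
#' @param exclude Optional logical vector (same length as `rho_table` rows)
#'   marking rows to exclude from the anchor medians (they are still scored).
#' @param min_anchor Minimum number of usable synonymous and of nonsense
#'   variants per replicate (default 10).
#' @return The input with an added `phi` column.
#' @export
normalize_scores <- function(rho_table, exclude = NULL, min_anchor = 10L) {
  if (is.null(exclude)) exclude <- rep(FALSE, nrow(rho_table))
  stopifnot(length(exclude) == nrow(rho_table))
  out <- rho_table
  out$phi <- NA_real_
  for (r in unique(rho_table$replicate)) {
    in_rep <- rho_table$replicate == r
    syn <- in_rep & !exclude & rho_table$var_class == "synonymous"
    non <- in_rep & !exclude & rho_table$var_class == "nonsense"
    if (sum(syn) < min_anchor || sum(non) < min_anchor) {
      stop(
        "replicate ", r, ": need at least ", min_anchor,
        " unexcluded synonymous and nonsense variants to anchor scores (have ",
        sum(syn), " and ", sum(non), ")"
      )
    }
    m_syn <- stats::median(rho_table$rho[syn])
    m_non <- stats::median(rho_table$rho[non])
    if (m_syn == m_non) {
      stop(
        "replicate ", r, ": synonymous and nonsense medians coincide (",
        m_syn, "); selection is degenerate and scores cannot be anchored"
      )
    }
    out$phi[in_rep] <- (rho_table$rho[in_rep] - m_non) / (m_syn - m_non)
  }
  out
}

#' Flag variants with low input counts or discordant replicates
#'
#' @param score_wide Per-variant tibble with columns `min_pre_count`
#'   (smallest pre-selection count over replicates) and per-replicate score
#'   columns `phi_1`, `phi_2`, ...
#' @param min_pre_count A variant is flagged `low_input` when its
#'   pre-selection count falls below this in any replicate (default 10).
#' @param max_replicate_delta A variant is flagged `replicate_disagreement`
#'   when the largest pairwise difference between replicate scores exceeds
#'   this (default 1 score unit).
#' @return `score_wide` with logical columns `low_input` and
#'   `replicate_disagreement` added.
#' @export
filter_variants <- function(score_wide, min_pre_count = 10L,
                            max_replicate_delta = 1.0) {
  phi_cols <- grep("^phi_[0-9]+$", names(score_wide), value = TRUE)
  if (length(phi_cols) == 0L) stop("no per-replicate score columns (phi_<r>) found")
  phis <- as.matrix(score_wide[phi_cols])
  delta <- apply(phis, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2L) 0 else diff(range(v))
  })
  score_wide$low_input <- score_wide$min_pre_count < min_pre_count
  score_wide$replicate_disagreement <- delta > max_replicate_delta
  score_wide
}

#' Fit the regression prior for score standard errors
#'
#' Ordinary least squares of the log empirical standard error on the log
#' mean pre-selection count and the score itself, fitted on unflagged
#' variants with at least two replicates. The fitted values give the prior
#' standard-error estimate `sigma0` per variant used by
#' [regularize_error()].
#'
#' @param score_wide Per-variant tibble with columns `s` (empirical standard
#'   error), `mean_pre_count`, `phi`, and the flag columns from
#'   [filter_variants()].
#' @param v0 Prior degrees of freedom attached to the regression estimate
#'   (default 4).
#' @param min_variants Minimum number of usable variants (default 50).
#' @return An object of class `error_model` with elements `coefficients`
#'   (intercept, log count, score), `v0`, and `n_fit`.
#' @export
fit_error_prior <- function(score_wide, v0 = 4, min_variants = 50L) {
  if (v0 <= 0) stop("v0 must be positive")
  use <- !score_wide$low_input & !score_wide$replicate_disagreement &
    is.finite(score_wide$s) & score_wide$s > 0 &
    is.finite(score_wide$phi) & score_wide$mean_pre_count > 0
  if (sum(use) < min_variants) {
    stop(
      "only ", sum(use), " unflagged variants with replicate information; ",
      "need ", min_variants, ". Lower min_variants or supply sigma0/v0 directly."
    )
  }
  fit <- stats::lm(
    log(s) ~ log(mean_pre_count) + phi,
    data = score_wide[use, c("s", "mean_pre_count", "phi")]
  )
  structure(
    list(
      coefficients = stats::setNames(
        stats::coef(fit), c("intercept", "log_pre_count", "score")
      ),
      v0 = v0,
      n_fit = sum(use)
    ),
    class = "error_model"
  )
}

#' Predict the prior standard error for each variant
#'
#' @param object An `error_model` from [fit_error_prior()].
#' @param mean_pre_count,phi Per-variant mean pre-selection count and score.
#' @param ... Unused.
#' @return Numeric vector of prior standard errors `sigma0` (positive for
#'   finite inputs).
#' @export
predict.error_model <- function(object, mean_pre_count, phi, ...) {
  b <- object$coefficients
  exp(b[["intercept"]] + b[["log_pre_count"]] * log(pmax(mean_pre_count, 1)) +
    b[["score"]] * phi)
}

#' @export
print.error_model <- function(x, ...) {
  cat("Standard-error prior (log-linear regression, n =", x$n_fit, ")\n")
  print(x$coefficients)
  cat("prior degrees of freedom v0 =", x$v0, "\n")
  invisible(x)
}

#' Baldi-Long regularization of the empirical standard error
#'
#' Shrinks the empirical replicate standard error `s` towards the prior
#' estimate `sigma0` using the inverse-gamma posterior formula
#' `sigma^2 = (v0 * sigma0^2 + (n - 1) * s^2) / (v0 + n - 2)`,
#' where `v0` is the degrees of freedom given to the prior and `n` is the
#' number of replicates. With few replicates the prior dominates; as
#' `v0 -> Inf` the result tends to `sigma0`.
#'
#' @param s Empirical standard error(s), non-negative.
#' @param sigma0 Prior standard error(s), non-negative.
#' @param v0 Prior degrees of freedom; `v0 + n` must exceed 2.
#' @param n Number of replicates.
#' @return Regularized standard error(s) `sigma`.
#' @examples
#' regularize_error(s = 2, sigma0 = 1, v0 = 4, n = 2) # sqrt(2)
#' @export
regularize_error <- function(s, sigma0, v0 = 4, n = 2L) {
  if (any(v0 + n <= 2)) stop("v0 + n must exceed 2 for the posterior variance to exist")
  if (any(s < 0, na.rm = TRUE) || any(sigma0 < 0, na.rm = TRUE)) {
    stop("s and sigma0 must be non-negative")
  }
  sqrt((v0 * sigma0^2 + (n - 1) * s^2) / (v0 + n - 2))
}

#' Score a count table end to end
#'
#' Runs the full scoring chain: background subtraction, per-replicate
#' log-enrichment, two-pass anchoring on synonymous/nonsense medians
#' (flagged variants are dropped from the anchors in the second pass and the
#' combined score is re-anchored so the anchor medians are exact), replicate
#' filtering, and Baldi-Long error regularization.
#'
#' @param counts Count tibble (see [subtract_wt_background()]).
#' @param pseudofrequency Passed to [raw_scores()].
#' @param min_pre_count,max_replicate_delta Passed to [filter_variants()].
#' @param v0 Prior degrees of freedom for [regularize_error()].
#' @param min_anchor Passed to [normalize_scores()].
#' @param fit_prior If `FALSE`, skip the error-prior regression (the
#'   `se_prior`/`se_regularized` columns are then `NA`).
#' @return A score table: one row per variant with columns `position`,
#'   `wt_aa`, `alt_aa`, `var_class`, `hgvs_pro`, per-replicate scores
#'   `phi_1`..., combined `score`, `se_empirical`, `se_prior`,
#'   `se_regularized`, `n_replicates`, `mean_pre_count`, `min_pre_count`,
#'   and flags `low_input`, `replicate_disagreement`, `unscored`. The fitted
#'   `error_model` is attached as attribute `error_model`.
#' @export
score_counts <- function(counts, pseudofrequency = NULL, min_pre_count = 10L,
                         max_replicate_delta = 1.0, v0 = 4, min_anchor = 10L,
                         fit_prior = TRUE) {
  freqs <- subtract_wt_background(counts)
  rho <- raw_scores(freqs, pseudofrequency)

  # pass 1: anchor with only low-input variants excluded, to get provisional
  # per-replicate scores for the disagreement filter
  low_by_var <- dplyr::summarise(
    dplyr::group_by(rho, .data$position, .data$wt_aa, .data$alt_aa),
    min_pre_count = min(.data$pre_count),
    mean_pre_count = mean(.data$pre_count),
    .groups = "drop"
  )
  rho <- dplyr::left_join(
    rho, low_by_var,
    by = c("position", "wt_aa", "alt_aa")
  )
  excl1 <- rho$min_pre_count < min_pre_count
  pass1 <- normalize_scores(rho, exclude = excl1, min_anchor = min_anchor)

  wide <- .widen_scores(pass1)
  wide <- filter_variants(wide,
    min_pre_count = min_pre_count,
    max_replicate_delta = max_replicate_delta
  )

  # pass 2: re-anchor with all flagged variants excluded
  flagged_keys <- wide[wide$low_input | wide$replicate_disagreement,
    c("position", "wt_aa", "alt_aa"),
    drop = FALSE
  ]
  excl2 <- interaction(rho$position, rho$wt_aa, rho$alt_aa) %in%
    interaction(flagged_keys$position, flagged_keys$wt_aa, flagged_keys$alt_aa)
  pass2 <- normalize_scores(rho, exclude = excl2, min_anchor = min_anchor)

  wide2 <- .widen_scores(pass2)
  wide2$low_input <- wide$low_input[match(
    .variant_key(wide2), .variant_key(wide)
  )]
  wide2$replicate_disagreement <- wide$replicate_disagreement[match(
    .variant_key(wide2), .variant_key(wide)
  )]

  # final affine re-anchoring so that the combined score's anchor medians are
  # exactly 0 and 1 (per-replicate anchoring alone leaves the median of the
  # replicate mean slightly off)
  ok <- !wide2$low_input & !wide2$replicate_disagreement
  m_non <- stats::median(wide2$phi[ok & wide2$var_class == "nonsense"])
  m_syn <- stats::median(wide2$phi[ok & wide2$var_class == "synonymous"])
  if (m_syn == m_non) stop("degenerate selection: anchor medians coincide")
  scale <- m_syn - m_non
  phi_cols <- grep("^phi_[0-9]+$", names(wide2), value = TRUE)
  for (cl in phi_cols) wide2[[cl]] <- (wide2[[cl]] - m_non) / scale
  wide2$phi <- (wide2$phi - m_non) / scale
  wide2$s <- wide2$s / abs(scale)

  out <- dplyr::rename(wide2, score = "phi", se_empirical = "s")
  out$unscored <- !is.finite(out$score)
  out$hgvs_pro <- format_pro_hgvs(out$position, out$wt_aa, out$alt_aa)

  out$se_prior <- NA_real_
  out$se_regularized <- NA_real_
  model <- NULL
  if (fit_prior) {
    model <- fit_error_prior(wide2, v0 = v0)
    out$se_prior <- predict(model, out$mean_pre_count, out$score)
    out$se_regularized <- regularize_error(
      out$se_empirical, out$se_prior,
      v0 = v0, n = out$n_replicates
    )
  }

  out <- out[order(out$position, match(out$alt_aa, c(AA_ALPHABET, "*"))), ]
  out <- out[, c(
    "position", "wt_aa", "alt_aa", "var_class", "hgvs_pro",
    phi_cols, "score", "se_empirical", "se_prior", "se_regularized",
    "n_replicates", "mean_pre_count", "min_pre_count",
    "low_input", "replicate_disagreement", "unscored"
  )]
  attr(out, "error_model") <- model
  tibble::as_tibble(out)
}

# long (per replicate) -> wide (per variant) with combined score and
# empirical standard error across replicates
.widen_scores <- function(long) {
  combined <- dplyr::summarise(
    dplyr::group_by(long, .data$position, .data$wt_aa, .data$alt_aa, .data$var_class),
    tile = .data$tile[1],
    n_replicates = sum(is.finite(.data$phi)),
    s = stats::sd(.data$phi),
    phi = mean(.data$phi),
    mean_pre_count = .data$mean_pre_count[1],
    min_pre_count = .data$min_pre_count[1],
    .groups = "drop"
  )
  per_rep <- tidyr::pivot_wider(
    long[, c("position", "wt_aa", "alt_aa", "replicate", "phi")],
    names_from = "replicate", values_from = "phi", names_prefix = "phi_"
  )
  dplyr::left_join(combined, per_rep, by = c("position", "wt_aa", "alt_aa"))
}

.variant_key <- function(df) paste(df$position, df$wt_aa, df$alt_aa)
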