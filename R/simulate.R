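# Synthetic tile-seq data with known ground truth.
#
# The generator emulates a growth-based abundance selection read out by
# tile-based sequencing: a latent per-variant abundance in [0, 1] drives
# exponential enrichment between the pre- and post-selection pools, counts
# are multinomial draws at a configured depth per tile/condition/replicate,
# and a wild-type-template control channel carries only the spurious
# (PCR/base-calling) error process that is shared additively by all three
# channels.

#' Parameters of the latent abundance mixture
#'
#' The latent per-variant abundance is drawn from a three-component Gaussian
#' mixture (clipped to `[0, 1]`) representing nonsense-like, intermediate,
#' and synonymous-like variants — the trimodal shape typical of abundance
#' scores from growth selections.
#'
#' @param weights,means,sds Numeric length-3 vectors; `weights` must sum
#'   to 1.
#' @return A named list with class `effect_class_params`.
#' @export
effect_class_params <- function(weights = c(0.3, 0.2, 0.5),
                                means = c(0, 0.5, 1),
                                sds = c(0.1, 0.1, 0.1)) {
  stopifnot(length(weights) == 3L, length(means) == 3L, length(sds) == 3L)
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("mixture weights must sum to 1 (got ", sum(weights), ")")
  }
  if (any(weights < 0) || any(sds <= 0)) {
    stop("weights must be non-negative and sds positive")
  }
  structure(
    list(weights = weights, means = means, sds = sds),
    class = "effect_class_params"
  )
}

#' Simulation configuration
#'
#' @param depth Reads per tile, condition, and replicate (default 1e6,
#'   giving per-variant pre-selection counts of ~100 for a full-size
#'   9744-variant library).
#' @param n_replicates Number of replicates (default 2, matching a duplicate
#'   selection design).
#' @param regions List of mutagenized regions, as in [generate_library()].
#' @param tiles_per_region Tiles per region; the default 5/5/4 split gives
#'   14 tiles over the default three regions.
#' @param selection_strength Log-enrichment span between a variant with
#'   latent abundance 0 and one with abundance 1 (natural-log units).
#' @param error_rate Mean spurious per-variant frequency in the wild-type
#'   control channel (the same spurious frequencies are added to all three
#'   channels).
#' @param dirichlet_alpha Concentration of the Dirichlet perturbation of the
#'   pre-selection library composition around uniform; `Inf` means exactly
#'   uniform.
#' @param seed Master seed; per-tile and per-replicate streams are derived
#'   deterministically from it.
#' @return A named list with class `sim_config`.
#' @export
sim_config <- function(depth = 1e6,
                       n_replicates = 2L,
                       regions = default_regions(465L),
                       tiles_per_region = c(5L, 5L, 4L),
                       selection_strength = 4,
                       error_rate = 1e-6,
                       dirichlet_alpha = 50,
                       seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (error_rate < 0) stop("error_rate must be non-negative")
  regions <- .validate_regions(regions, Inf)
  structure(
    list(
      depth = depth, n_replicates = as.integer(n_replicates),
      regions = regions, tiles_per_region = as.integer(tiles_per_region),
      selection_strength = selection_strength, error_rate = error_rate,
      dirichlet_alpha = dirichlet_alpha, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Draw latent true abundances for a variant library
#'
#' Missense variants draw their latent abundance from the three-component
#' mixture in `class_params`; nonsense variants are assigned to the low
#' component (except within the last `nonsense_tail` residues, where
#' truncations are tolerated and draw from the high component); synonymous
#' variants draw from the high component. Draws are clipped to `[0, 1]`.
#'
#' @param library Variant tibble from [generate_library()].
#' @param class_params An [effect_class_params()] object.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param nonsense_tail Number of C-terminal residues where nonsense variants
#'   keep high abundance (default 10).
#' @param protein_length Protein length; defaults to the largest library
#'   position.
#' @return The library tibble with added columns `true_abundance` and
#'   `true_class` (1 = low, 2 = intermediate, 3 = high); the generating
#'   parameters and seed are stored in attributes `class_params` and `seed`.
#' @export
sample_true_effects <- function(library, class_params = effect_class_params(),
                                seed = 1L, nonsense_tail = 10L,
                                protein_length = max(library$position)) {
  stopifnot(inherits(class_params, "effect_class_params"))
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)

  n <- nrow(library)
  comp <- integer(n)
  is_mis <- library$var_class == "missense"
  comp[is_mis] <- sample(1:3, sum(is_mis),
    replace = TRUE, prob = class_params$weights
  )
  tail_start <- protein_length - as.integer(nonsense_tail) + 1L
  is_non <- library$var_class == "nonsense"
  comp[is_non] <- ifelse(library$position[is_non] >= tail_start, 3L, 1L)
  comp[library$var_class == "synonymous"] <- 3L

  a <- stats::rnorm(n, class_params$means[comp], class_params$sds[comp])
  a <- pmin(pmax(a, 0), 1)

  out <- library
  out$true_abundance <- a
  out$true_class <- comp
  attr(out, "class_params") <- class_params
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Simulate tile-seq count tables from latent abundances
#'
#' Within each tile, variant pre-selection frequencies are drawn around
#' uniform (Dirichlet-perturbed, shared across replicates), scaled so that
#' reads from templates whose mutation lies outside the tile appear as a
#' wild-type-looking remainder row. Post-selection frequencies are
#' proportional to `pre * exp(selection_strength * a)`; the wild-type-looking
#' pool grows with the library-average enrichment. A spurious error frequency
#' per variant (mean `error_rate`, drawn once per tile) is added identically
#' to the pre, post, and wild-type-control channels, so subtracting the
#' control frequency is exactly the right correction in expectation. Counts
#' are multinomial at `depth` reads per tile/condition/replicate.
#'
#' @param effects Output of [sample_true_effects()].
#' @param config A [sim_config()].
#' @return A tibble count table with columns `position`, `wt_aa`, `alt_aa`,
#'   `var_class`, `tile`, `replicate`, `condition` (`pre`/`post`/`wtctrl`),
#'   `count`, `depth`. One `var_class = "wt"` row per tile/replicate/condition
#'   carries the wild-type-looking remainder reads, so counts in every
#'   channel sum exactly to `depth`.
#' @export
simulate_counts <- function(effects, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tm <- tile_map(config$regions, config$tiles_per_region)
  eff <- dplyr::inner_join(effects, tm, by = "position")
  if (nrow(eff) != nrow(effects)) {
    stop("library positions not covered by the configured regions/tiles")
  }

  s <- config$selection_strength
  n_lib <- nrow(eff)
  # wild-type-looking reads in a tile come from templates mutated elsewhere;
  # their pool grows with the library-average enrichment
  g_wt <- mean(exp(s * eff$true_abundance))

  out <- vector("list", 0L)
  for (tl in sort(unique(eff$tile))) {
    idx <- which(eff$tile == tl)
    nt <- length(idx)
    variant_mass <- nt / n_lib

    restore <- .local_seed(.derive_seed(config$seed, 1L, tl))
    # library composition: Dirichlet around uniform, shared by replicates
    if (is.finite(config$dirichlet_alpha)) {
      w <- stats::rgamma(nt, shape = config$dirichlet_alpha, rate = 1)
      w <- w / sum(w)
    } else {
      w <- rep(1 / nt, nt)
    }
    p_sig <- w * variant_mass
    # spurious error frequencies, one draw per tile, shared by all channels
    e <- if (config$error_rate > 0) {
      stats::rexp(nt, rate = 1 / config$error_rate)
    } else {
      rep(0, nt)
    }
    restore()

    g <- exp(s * eff$true_abundance[idx])
    z <- sum(p_sig * g) + (1 - variant_mass) * g_wt
    q_sig <- p_sig * g / z

    freqs <- list(
      pre = c(p_sig + e, 1 - sum(p_sig) - sum(e)),
      post = c(q_sig + e, 1 - sum(q_sig) - sum(e)),
      wtctrl = c(e, 1 - sum(e))
    )

    for (rep_i in seq_len(config$n_replicates)) {
      for (cond in names(freqs)) {
        restore <- .local_seed(.derive_seed(config$seed, 2L, tl, rep_i, match(cond, names(freqs))))
        counts <- as.integer(stats::rmultinom(1L, size = config$depth, prob = freqs[[cond]]))
        restore()
        out[[length(out) + 1L]] <- tibble::tibble(
          position = c(eff$position[idx], NA_integer_),
          wt_aa = c(eff$wt_aa[idx], NA_character_),
          alt_aa = c(eff$alt_aa[idx], NA_character_),
          var_class = c(eff$var_class[idx], "wt"),
          tile = tl,
          replicate = rep_i,
          condition = cond,
          count = counts,
          depth = config$depth
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
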