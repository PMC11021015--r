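# Synthetic activity scores paired with the abundance ground truth.
#
# The abundance assay alone cannot distinguish mechanism classes; a second,
# activity-like readout is needed for the quadrant analysis. This generator
# produces activity scores on the same 0/1 anchor scale in which (i) losing
# abundance also loses activity, and (ii) a configurable fraction of
# variants lose activity through an abundance-independent mechanism
# (emulating conformational-shift and binding-site variants).

#' Simulate activity scores consistent with latent abundances
#'
#' Activity is modeled as the product of the latent abundance and a latent
#' specific activity: synonymous variants keep specific activity 1; a
#' fraction `p_functional` of missense variants draw a strongly reduced
#' specific activity (mean `functional_mean`), emulating active-site,
#' allosteric, and conformational-shift mechanisms that act without changing
#' abundance; nonsense variants have activity ~ 0. Gaussian measurement
#' noise is added on the score scale.
#'
#' @param effects Output of [sample_true_effects()].
#' @param p_functional Probability that a missense variant carries an
#'   abundance-independent functional defect (default 0.15).
#' @param functional_mean,functional_sd Specific-activity distribution of
#'   functionally perturbed variants (default mean 0.1, sd 0.1, clipped to
#'   `[0, 1]`).
#' @param noise_sd Measurement noise on the activity score (default 0.05).
#' @param seed Integer seed.
#' @return The `effects` tibble with added columns `functional_defect`
#'   (logical) and `activity_score`.
#' @export
simulate_activity_scores <- function(effects, p_functional = 0.15,
                                     functional_mean = 0.1,
                                     functional_sd = 0.1,
                                     noise_sd = 0.05, seed = 1L) {
  restore <- .local_seed(.derive_seed(seed, 7L))
  on.exit(restore(), add = TRUE)
  n <- nrow(effects)
  defect <- effects$var_class == "missense" &
    stats::runif(n) < p_functional
  spec_act <- rep(1, n)
  spec_act[defect] <- pmin(pmax(
    stats::rnorm(sum(defect), functional_mean, functional_sd), 0
  ), 1)
  spec_act[effects$var_class == "nonsense"] <- 0
  act <- effects$true_abundance * spec_act + stats::rnorm(n, 0, noise_sd)
  out <- effects
  out$functional_defect <- defect
  out$activity_score <- act
  out
}
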