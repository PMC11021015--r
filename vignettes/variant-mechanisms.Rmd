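---
title: "From selection counts to variant mechanisms: the models behind mavemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From selection counts to variant mechanisms: the models behind mavemech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mavemech` analyzes multiplexed assays of variant effects (MAVEs) in which a
pooled variant library is subjected to a growth selection that couples
cellular protein abundance to yeast growth, and variant frequencies are read
out by tile-based sequencing before and after selection. This vignette is
the package's own account of the models it implements, the parameters that
matter, and the limits of what its synthetic data can show.

```{r setup}
library(mavemech)
```

## The scoring model

The input is a count table keyed by variant, sequencing tile, replicate,
and condition (`pre`, `post`, `wtctrl`). The wild-type-control channel is
sequenced from a wild-type template, so any "variant" it contains is a
PCR or base-calling artifact. Because those artifacts arise in the shared
amplification/sequencing process, they contaminate all three channels
approximately additively, and subtracting the control frequency is the
right correction in expectation:

$$\tilde f_v = \max\!\left(0,\; \frac{c_v}{D} - \frac{c^{wt}_v}{D^{wt}}\right)$$

Per-replicate enrichment is a natural-log ratio with a pseudofrequency,
$\rho_v = \log\big((\tilde f^{post}_v + \varepsilon)/(\tilde f^{pre}_v +
\varepsilon)\big)$. The pseudofrequency defaults to $1/(10D)$ per channel:
one tenth of a read, so a variant that vanishes after selection gets a
finite, depth-calibrated floor rather than $-\infty$. Scores are then
anchored affinely so that nonsense variants (which should produce no
functional protein) have median 0 and synonymous variants median 1.

Two quality filters mirror standard MAVE practice: `low_input` (fewer than
`min_pre_count = 10` pre-selection reads in any replicate — too little
template to estimate a frequency) and `replicate_disagreement`
(`|φ₁ − φ₂| > 1` score unit). Flagged variants keep their scores by default
but are excluded from the normalization anchors and downstream medians.

Anchoring is done in two passes. Per-replicate scores are anchored first;
after filtering, the combined score (the replicate mean) is re-anchored
with the same affine map applied to the replicate scores and the empirical
standard error. The second pass exists because the median of replicate
means is not exactly the mean of replicate medians: without it the
combined-score anchor medians would be off by a small, depth-dependent
amount. With it they are exact to floating precision, which is what the
package's tests pin.

### Standard-error regularization

With two replicates the empirical standard error
$s = |\varphi_1 - \varphi_2|/\sqrt{2}$ is itself extremely noisy. It is
shrunk toward a prior using the Baldi–Long inverse-gamma posterior:

$$\sigma^2 = \frac{v_0\sigma_0^2 + (n-1)s^2}{v_0 + n - 2}$$

The prior $\sigma_0$ comes from an ordinary least-squares regression of
$\log s$ on the log mean pre-selection count and the score itself, fitted
across unflagged variants: counting noise shrinks with read depth
(on idealized multinomial data the count coefficient is $-1/2$, which the
test suite recovers), and low-scoring variants have systematically noisier
enrichment. $v_0$ is the number of pseudo-observations granted to the
prior; the default of 4 weights the regression prior twice as heavily as
the two experimental replicates, appropriate when $n = 2$. Note that
$s = \sigma_0$ is not a fixed point of the formula: the posterior-mean
variance inflates agreeing prior and data by $(v_0+n-1)/(v_0+n-2)$, a
property of the inverse-gamma mean, and the limit $v_0 \to \infty$ recovers
$\sigma_0$ exactly.

## The low-abundance threshold

Abundance-score distributions from growth selections are characteristically
trimodal: a nonsense-like mode near 0, a synonymous-like mode near 1, and
an intermediate shoulder. `fit_mixture()` fits a three-component Gaussian
mixture by EM and `threshold_from_mixture()` places the low-abundance
cutoff $t^*$ where the weighted densities of the intermediate and
synonymous-like components cross — the score below which a variant is more
likely intermediate than wild-type-like.

Numerical choices (the method itself does not prescribe them):

* 20 random restarts; initialization at the 1/6, 3/6, 5/6 quantiles with
  Gaussian jitter on all but the first start.
* log-space E-step; convergence when the relative log-likelihood
  improvement drops below `1e-8`; variance floor `1e-6` against
  degenerate spikes.
* components are relabeled ascending by mean after fitting, and "second
  and third" components are defined on that ordering.
* the crossing is the root of a closed-form quadratic (equal log-densities);
  when both roots fall between the two means, the one nearer the minimum of
  the full mixture density is used, since the cutoff is meant to sit in the
  valley between the modes.

Scores flagged by the scoring module are excluded from the fit by the
pipeline. The fit uses missense, nonsense, and synonymous variants
together by default (`mixture_classes`), since anchors are legitimate
members of the outer modes; restricting to missense only is one argument
away.

## Structure-derived features

* **rASA / burial.** Absolute per-residue SASA by a rolling-probe
  (Shrake–Rupley) computation on heavy atoms: 960 near-uniform
  (Fibonacci-lattice) test points per atom, probe radius 1.4 Å, per-element
  van der Waals radii. rASA divides by a theoretical per-residue maximum
  (bundled, swappable); rASA ≤ 0.2 classifies a residue as buried. Absolute
  SASA values differ between surface algorithms by a few percent, so the
  intended contract is the burial classification, not the raw areas — the
  tests therefore pin an independent Monte-Carlo surface to ~2% and exact
  enclosure/monotonicity properties, not third-party SASA values. Ligand
  atoms do not occlude the surface.
* **WCN.** $\mathrm{WCN}_i = \sum_{j\ne i} s(r_{ij})$ with
  $s(r) = (1-(r/r_0)^6)/(1-(r/r_0)^{12})$, $r_0 = 7$ Å. The rational form
  simplifies to $1/(1+(r/r_0)^6)$, which the implementation uses: it is
  algebraically identical away from $r_0$ and supplies the removable
  singularity's continuity value $s(r_0) = 1/2$ with no special case.
  Distances are sidechain-heavy-atom minima, falling back to all-atom
  minima for pairs involving glycine (which has no sidechain heavy atom).
* **Geometry.** The inter-domain cleft angle is the planar angle at the
  Cα of the middle residue of (109, 233, 229); helix-13 motion is the
  Cα–Cα distance (159, 452). Both accept multi-model PDB input and return
  one value per frame; both are rigid-motion invariant by construction and
  by test.
* **Domains.** Residue intervals for the large/small/hinge domains are
  plain configuration (`inst/extdata/gck_domains.tsv`). The bundled file
  holds approximate intervals from the hexokinase-fold literature and is a
  user-replaceable default, not a structural ground truth; unlisted
  residues default to `hinge`.

## Mechanism classification

Thresholds: `t_abund` (fitted or fixed; 0.58 is a literature-scale value
for abundance maps anchored this way) and `t_act = 0.66`. Comparisons at
both score thresholds are strict (`<`); a variant exactly at a threshold is
not "low". Stability rules use ΔΔG in kcal/mol (Rosetta energies divided
by 2.9): a conformational-shift candidate destabilizes the closed state at
least `t_shift = 2` kcal/mol more than the super-open state *and* leaves
the super-open state below `t_superopen_cap = 2` kcal/mol (a variant that
destabilizes both states is expected to lose abundance instead); a
binding-affinity decrease is an inclusive `≥ 2` kcal/mol excess of the
glucose-bound over the glucose-free ΔΔG. The shift threshold and cap are
not standardized anywhere; 2 kcal/mol keeps them consistent with the
binding rule and with common stability-effect cutoffs, and both are
configurable. Per-position medians (the `MED` row of heatmaps) are computed
over unflagged missense variants only — nonsense variants would drag every
position's median down for reasons unrelated to local structure, and are
displayed separately.

Where an ensemble of structural models covers a flexible region,
`average_loop_models()` takes the arithmetic mean of per-model ΔΔG values,
dropping missing models and recording how many contributed.

## What the synthetic generator emulates — and what it does not

`sample_true_effects()` draws a latent abundance $a \in [0,1]$ per variant
from a three-class mixture (defaults: weights 0.3/0.2/0.5, means 0/0.5/1,
sd 0.1, clipped), mimicking the trimodal shape of real abundance maps;
nonsense variants join the low class except in the last 10 residues, where
C-terminal truncations are tolerated; synonymous variants join the high
class. `simulate_counts()` turns $a$ into counts: Dirichlet-perturbed
library composition (concentration 50, shared across replicates),
post-selection frequencies proportional to $\mathrm{pre}\cdot e^{s a}$ with
selection strength $s = 4$ (a ~55-fold enrichment span, enough to separate
the modes by several measurement standard deviations at the default
depth), an exponential spurious-frequency channel with mean `1e-6` added
identically to all channels, and multinomial sampling at `depth = 1e6`
reads per tile/channel/replicate — about 100 pre-selection reads per
variant for a full-size library, in line with benchtop sequencer
throughput. The exponential-growth mapping from abundance to enrichment is
an emulation device: the pipeline nowhere assumes it, and no claim is made
that the real assay is exponential in abundance.

Known divergences from real data, and hence limits of what green tests
show:

* **No bottleneck or growth-phase variance.** Real selections add
  biological noise far above counting noise; synthetic scores at default
  depth are much cleaner than real ones. Parameter-recovery results
  (Spearman ≈ 0.96 at depth $10^6$) are upper bounds, not forecasts.
* **Clipping atoms.** Hard-clipping the latent abundance to $[0,1]$ piles
  mass at exactly 0 and 1. With little measurement noise the ML
  three-Gaussian fit narrows its synonymous-like component onto the atom
  at 1, which pushes the fitted $t^*$ (~0.9) above the intersection of the
  generating latent components (~0.73). Real score distributions are
  smoother and do not show this artifact; the mixture-recovery tests
  therefore use unclipped draws, and the pipeline's fitted $t^*$ on
  synthetic scores should be read with this in mind.
* **Protein-level only.** No codon structure, read errors, or PCR
  jackpots; the error channel is a single additive exponential draw per
  tile, exactly the situation wild-type subtraction corrects. Real
  artifact processes are only approximately additive.
* **Sequence content is arbitrary.** Synthetic proteins use random
  sequences; nothing downstream depends on residue identity except the
  max-ASA lookup on real structures.

## Problem sizes and runtime choices

The test suite and acceptance script run full-size libraries (465 residues,
9744 variants, 14 tiles, 2 replicates) at depth $10^6$ for the end-to-end
recovery checks — about 20 s — and toy libraries (25–120 residues) or
20-residue synthetic structures everywhere a property, not scale, is under
test. Mixture-fit checks use 3000–5000 draws, where the EM parameter
recovery is comfortably inside the tested tolerances.

## Reproducibility

All randomness flows from explicit integer seeds; per-tile, per-replicate,
and per-channel streams are derived deterministically from one master seed,
so count tables are reproducible record for record. `run_pipeline()` writes
a manifest (every configuration value including defaults, fitted mixture
parameters, threshold, package version) and a log alongside its outputs;
re-running with the same configuration reproduces the outputs byte for
byte.
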