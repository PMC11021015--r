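# mavemech

Mechanistic classification of variant effects from multiplexed abundance
assays (MAVEs / deep mutational scans), with human glucokinase (GCK) as the
motivating system.

A missense variant can break an enzyme in several distinct ways: it can
destabilize the fold so the protein is degraded (loss of abundance), it can
shift the conformational equilibrium toward an inactive state, or it can
perturb ligand binding. `mavemech` turns the raw outputs of a growth-based
abundance selection — variant read counts before and after selection, in
sequencing tiles, with a wild-type-template error control — into normalized
abundance scores, and combines them with activity scores, predicted
stability changes (ΔΔG), and per-residue structural features to assign each
variant a mechanism class.

## The model

**Scoring.** For variant *v* in tile *t*, replicate *r*, frequencies are
corrected by the wild-type control channel,
f̃ = max(0, c/D − c_wt/D_wt), and scored as natural-log enrichment
ρ = log((f̃_post + ε)/(f̃_pre + ε)) with pseudofrequency ε = 1/(10·D).
Scores are anchored affinely so that the median of nonsense variants is 0
and the median of synonymous variants is 1:

    φ = (ρ − median ρ_nonsense) / (median ρ_synonymous − median ρ_nonsense)

Variants are flagged when pre-selection counts are low or replicates
disagree; flagged variants are excluded from the anchors.

**Error regularization (Baldi–Long).** The empirical replicate standard
error *s* is shrunk toward a prior σ₀ predicted by regressing log *s* on
the log pre-selection count and the score:

    σ² = (v₀σ₀² + (n−1)s²) / (v₀ + n − 2)

with prior degrees of freedom v₀ (default 4) and n replicates.

**Low-abundance threshold.** A three-component Gaussian mixture
(nonsense-like, intermediate, synonymous-like) is fitted to the score
distribution by multi-start EM; the cutoff t\* is where the weighted
densities of the second and third components intersect,
w₂N(t\*; μ₂, σ₂) = w₃N(t\*; μ₃, σ₃), solved in closed form.

**Structure features.** Per residue: solvent accessibility by a
rolling-probe (Shrake–Rupley) surface, normalized to rASA by theoretical
maxima (buried ⇔ rASA ≤ 0.2); weighted contact number
WCN_i = Σ_{j≠i} 1/(1 + (r_ij/r₀)⁶) with r₀ = 7 Å and sidechain-heavy-atom
distances (all atoms for glycine pairs); ligand contacts at < 4 Å; the
inter-domain cleft angle (Cα 109–233–229) and the helix-13 distance
(Cα 159–452).

**Mechanism classes.** With thresholds t_abund (fitted or fixed, e.g. 0.58)
and t_act (e.g. 0.66), variants are cross-tabulated into four quadrants
(strict `<`). Low-activity + low-abundance variants are labeled loss of
abundance. From ΔΔG tables (Rosetta units / 2.9 → kcal/mol):
Δ(ΔΔG) = ΔΔG_super-open − ΔΔG_closed ≤ −2 kcal/mol with
ΔΔG_super-open ≤ 2 kcal/mol flags conformational-shift candidates, and
ΔΔG_holo − ΔΔG_apo ≥ 2 kcal/mol flags predicted binding-affinity loss.

## Worked example

```r
library(mavemech)

seq_aa  <- random_protein_sequence(465, seed = 1)
lib     <- generate_library(seq_aa, default_regions(465))
effects <- sample_true_effects(lib, seed = 2)
counts  <- simulate_counts(effects, sim_config(depth = 1e6, seed = 3))
scores  <- score_counts(counts)

ok <- !scores$low_input & !scores$replicate_disagreement
median(scores$score[ok & scores$var_class == "synonymous"])  # 1
median(scores$score[ok & scores$var_class == "nonsense"])    # 0

fit <- fit_mixture(scores$score[ok], seed = 4)
fit
#> Three-component Gaussian mixture (n = 9629 )
#>     component weight   mean     sd
#>           low 0.3453 0.0282 0.2157
#>  intermediate 0.2321 0.6319 0.1986
#>          high 0.4226 0.9957 0.0397
#> log-likelihood: -357.7474  iterations: 69
#> low-abundance threshold t* = 0.8968573
```

The library holds 464 positions × 21 protein-level variants = 9744 rows.
Scores land on the anchor scale (synonymous median exactly 1, nonsense
median exactly 0); the Spearman correlation between scores and the latent
true abundances at this depth is ≈ 0.96. The fitted t\* separates
synonymous-like from intermediate variants; on these very low-noise
synthetic scores the synonymous-like component is much narrower than in
real data (see the vignette for why, and for what the generator does and
does not emulate).

A single call runs every stage and writes TSV/JSON outputs plus a manifest:

```r
res <- run_pipeline(pipeline_config(seed = 1), out_dir = "my_run")
```

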