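# One-call pipeline: simulate (optional) -> score -> threshold ->
# features (optional) -> classify (optional) -> summarize, with a manifest
# so a run is reproducible from its output directory.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default; all values
#' (including defaulted ones) are serialized into the run manifest. Unknown
#' arguments are rejected by normal argument matching.
#'
#' @param simulate Generate synthetic counts (`TRUE`) or read them from
#'   `counts` (a path or tibble).
#' @param counts Count table path or tibble when `simulate = FALSE`.
#' @param protein_length,depth,n_replicates,selection_strength,error_rate,dirichlet_alpha
#'   Synthetic-data settings, see [sim_config()].
#' @param class_params Latent-abundance mixture, see [effect_class_params()].
#' @param pseudofrequency,min_pre_count,max_replicate_delta,v0,min_anchor
#'   Scoring settings, see [score_counts()].
#' @param t_abund Low-abundance threshold: a number, or `"fit"` to derive it
#'   from the score distribution via [fit_mixture()].
#' @param mixture_starts,mixture_classes EM restarts and variant classes
#'   used for the threshold fit.
#' @param activity Optional activity score table (path or tibble) or
#'   `"simulate"` to generate one alongside synthetic data.
#' @param t_act Low-activity threshold (default 0.66).
#' @param stability Optional stability table (path or tibble) with
#'   `ddg_closed`, `ddg_closed_holo`, `ddg_superopen`.
#' @param stability_units Units of the stability input.
#' @param t_bind,t_shift,t_superopen_cap Mechanism-rule thresholds in
#'   kcal/mol.
#' @param pdb,pdb_chain,conformation,ligand_name Optional structure input
#'   for the features stage.
#' @param domain_intervals Domain interval table or path (default: bundled
#'   glucokinase intervals).
#' @param seed Master seed for every stochastic stage.
#' @return A named list with class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE,
                            counts = NULL,
                            protein_length = 465L,
                            depth = 1e6,
                            n_replicates = 2L,
                            selection_strength = 4,
                            error_rate = 1e-6,
                            dirichlet_alpha = 50,
                            class_params = effect_class_params(),
                            pseudofrequency = NULL,
                            min_pre_count = 10L,
                            max_replicate_delta = 1.0,
                            v0 = 4,
                            min_anchor = 10L,
                            t_abund = "fit",
                            mixture_starts = 20L,
                            mixture_classes = c("missense", "nonsense", "synonymous"),
                            activity = if (simulate) "simulate" else NULL,
                            t_act = 0.66,
                            stability = NULL,
                            stability_units = "kcal/mol",
                            t_bind = 2,
                            t_shift = 2,
                            t_superopen_cap = 2,
                            pdb = NULL,
                            pdb_chain = NULL,
                            conformation = "other",
                            ligand_name = NULL,
                            domain_intervals = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!simulate && is.null(counts)) {
    stop("pipeline needs either simulate = TRUE or a 'counts' input")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the configured stages and writes all outputs, a log, and a
#' manifest (configuration, derived quantities, seeds, package version)
#' into `out_dir`. Identical configuration and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results: `counts`,
#'   `effects`, `scores`, `mixture`, `t_abund`, `features`, `merged`,
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("mavemech_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...), "\n",
      sep = "", file = log_path, append = TRUE
    )
  }
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    tryCatch(expr, error = function(e) {
      logf("stage %s: ERROR %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mavemech")),
    config = .serialize_config(config)
  )

  # --- simulate / load counts ----------------------------------------------
  effects <- NULL
  counts <- stage("simulate", {
    if (isTRUE(config$simulate)) {
      seq_aa <- random_protein_sequence(config$protein_length, seed = config$seed)
      lib <- generate_library(seq_aa, default_regions(config$protein_length))
      effects <- sample_true_effects(lib,
        class_params = config$class_params, seed = config$seed
      )
      sc <- sim_config(
        depth = config$depth, n_replicates = config$n_replicates,
        regions = default_regions(config$protein_length),
        selection_strength = config$selection_strength,
        error_rate = config$error_rate,
        dirichlet_alpha = config$dirichlet_alpha, seed = config$seed
      )
      cnt <- simulate_counts(effects, sc)
      write_tsv_table(
        effects[, c("position", "wt_aa", "alt_aa", "var_class", "true_abundance")],
        file.path(out_dir, "true_effects.tsv")
      )
      write_count_table(cnt, file.path(out_dir, "counts.tsv"))
      cnt
    } else if (is.character(config$counts)) {
      read_count_table(config$counts)
    } else {
      config$counts
    }
  })

  # --- score ----------------------------------------------------------------
  scores <- stage("score", {
    sc <- score_counts(counts,
      pseudofrequency = config$pseudofrequency,
      min_pre_count = config$min_pre_count,
      max_replicate_delta = config$max_replicate_delta,
      v0 = config$v0, min_anchor = config$min_anchor
    )
    write_score_table(sc, file.path(out_dir, "abundance_scores.tsv"))
    logf(
      "scored %d variants (%d flagged low_input, %d replicate_disagreement)",
      nrow(sc), sum(sc$low_input), sum(sc$replicate_disagreement)
    )
    sc
  })

  # --- threshold ------------------------------------------------------------
  mixture <- NULL
  t_abund <- stage("threshold", {
    if (identical(config$t_abund, "fit")) {
      use <- scores$var_class %in% config$mixture_classes &
        !scores$low_input & !scores$replicate_disagreement &
        is.finite(scores$score)
      mixture <- fit_mixture(scores$score[use],
        n_starts = config$mixture_starts, seed = config$seed
      )
      manifest$mixture <- list(
        weights = mixture$weights, means = mixture$means, sds = mixture$sds,
        loglik = mixture$loglik, threshold = mixture$threshold
      )
      logf("fitted low-abundance threshold t* = %.4f", mixture$threshold)
      mixture$threshold
    } else {
      as.numeric(config$t_abund)
    }
  })
  manifest$t_abund <- t_abund

  # --- features -------------------------------------------------------------
  features <- stage("features", {
    if (is.null(config$pdb)) {
      NULL
    } else {
      st <- read_structure(config$pdb,
        conformation = config$conformation, chain = config$pdb_chain
      )
      di <- config$domain_intervals
      if (is.character(di)) di <- utils::read.delim(di, sep = "\t")
      fe <- residue_features(st,
        ligand_name = config$ligand_name, domain_intervals = di
      )
      write_tsv_table(fe, file.path(out_dir, "residue_features.tsv"))
      fe
    }
  })

  # --- classify -------------------------------------------------------------
  merged <- stage("classify", {
    act <- config$activity
    if (is.null(act)) {
      NULL
    } else {
      act_tbl <- if (identical(act, "simulate")) {
        if (is.null(effects)) {
          stop("activity = 'simulate' requires simulate = TRUE (no ground truth available)")
        }
        sim <- simulate_activity_scores(effects, seed = config$seed)
        tibble::tibble(
          position = sim$position, wt_aa = sim$wt_aa, alt_aa = sim$alt_aa,
          var_class = sim$var_class, score = sim$activity_score
        )
      } else if (is.character(act)) {
        read_score_table(act)
      } else {
        act
      }
      stab <- config$stability
      if (is.character(stab)) stab <- utils::read.delim(stab, sep = "\t")
      if (!is.null(stab)) stab <- stability_table(stab, units = config$stability_units)
      m <- merge_tables(scores, act_tbl, stability = stab, features = features)
      m <- classify_quadrants(m, t_abund = t_abund, t_act = config$t_act)
      if (!is.null(stab)) {
        m <- conformational_shift_candidates(m,
          t_shift = config$t_shift, t_superopen_cap = config$t_superopen_cap
        )
        m <- binding_affinity_flags(m, t_bind = config$t_bind)
      }
      write_tsv_table(m, file.path(out_dir, "mechanism_table.tsv"))
      m
    }
  })

  # --- summarize ------------------------------------------------------------
  summary <- stage("summarize", {
    out <- list(n_variants_scored = sum(!scores$unscored), t_abund = t_abund)
    if (!is.null(merged)) {
      qs <- quadrant_summary(merged)
      out$quadrants <- qs
    }
    out
  })

  manifest$summary <- summary["n_variants_scored"]
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  jsonlite::write_json(
    .serialize_summary(summary), file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  logf("run complete")

  invisible(list(
    counts = counts, effects = effects, scores = scores, mixture = mixture,
    t_abund = t_abund, features = features, merged = merged,
    summary = summary, manifest = manifest, out_dir = out_dir
  ))
}

.serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$class_params <- unclass(cfg$class_params)
  for (nm in names(cfg)) {
    if (is.data.frame(cfg[[nm]])) cfg[[nm]] <- paste0("<table: ", nrow(cfg[[nm]]), " rows>")
  }
  cfg
}

.serialize_summary <- function(summary) {
  if (!is.null(summary$quadrants)) {
    summary$quadrants <- list(
      counts = as.data.frame(summary$quadrants$counts),
      n_total = summary$quadrants$n_total,
      conditional = summary$quadrants$conditional
    )
  }
  summary
}
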