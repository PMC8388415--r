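#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the data source
#' (synthetic group specifications, or morphologika/TPS files plus a
#' metadata CSV), the grouping variable, the evidence gates, resampling
#' counts and seeds.  Every stochastic stage derives its seed from
#' `seed`, so a configuration determines the full report byte for
#' byte.
#'
#' @param specs Output of [paper_default_specs()] (or a compatible
#'   list with `scores` and `pits` spec lists).  Ignored when
#'   `score_file` is given.
#' @param score_file,pit_file Optional morphologika files to analyse
#'   instead of simulating.
#' @param metadata_file Optional metadata CSV for file input.
#' @param grouping Grouping variable: `"captivity"`, `"park"` or
#'   `"prey_size"`.
#' @param normality_threshold Shapiro-Wilk gate for the robust branch
#'   (default 0.003).
#' @param evidence_threshold p(H0) level treated as strong evidence
#'   (default 0.003).
#' @param prior_prob_real Prior probability of a real effect used for
#'   FPR (default 0.5).
#' @param epsilon Equivalence bound in Cohen's d units (default 0.2).
#' @param reps Resampling replicates for the circular two-sample tests.
#' @param n_perm Permutations for the allometry tests.
#' @param bayes Fit the Bayesian effect-size models? (slow; default
#'   `FALSE`).
#' @param run_tsne Compute t-SNE embeddings? (default `TRUE`).
#' @param seed Master seed.
#' @param outdir Output directory for CSV reports and the manifest
#'   (`NULL` = return results only).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(specs = paper_default_specs(seed),
                            score_file = NULL, pit_file = NULL,
                            metadata_file = NULL,
                            grouping = c("captivity", "park", "prey_size"),
                            normality_threshold = 0.003,
                            evidence_threshold = 0.003,
                            prior_prob_real = 0.5,
                            epsilon = 0.2, reps = 999, n_perm = 999,
                            bayes = FALSE, run_tsne = TRUE,
                            seed = 1L, outdir = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(normality_threshold > 0, normality_threshold < 1,
            evidence_threshold > 0, evidence_threshold < 1)
  structure(
    list(specs = specs, score_file = score_file, pit_file = pit_file,
         metadata_file = metadata_file, grouping = grouping,
         normality_threshold = normality_threshold,
         evidence_threshold = evidence_threshold,
         prior_prob_real = prior_prob_real, epsilon = epsilon,
         reps = reps, n_perm = n_perm, bayes = bayes,
         run_tsne = run_tsne, seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Run the full tooth-mark analysis pipeline
#'
#' Orchestrates every stage on tooth-score and tooth-pit data:
#' measurement extraction; circular descriptives and pairwise
#' randomization tests on opening angles; gated (robust or classical)
#' univariate descriptives; mixed-metric PCA with equivalence matrices
#' over the principal components retained to 95% variance; t-SNE;
#' Procrustes superimposition with allometric regression (log centroid
#' size, and a captivity-stress covariate where defined); shape-space
#' equivalence matrices for pits; thin-plate-spline comparison of
#' group mean shapes; and optional Bayesian effect sizes.  Every
#' p-value in every report is accompanied by its BFB, FPR and p(H0)
#' calibration, and the word "significant" appears nowhere: evidence
#' statements live on the p(H0) scale against the configured
#' threshold.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with the report tables
#'   (`circular_descriptives`, `circular_comparisons`, `descriptives`,
#'   `metric_equivalence`, `shape_equivalence`, `allometry`,
#'   `pc_scores`, `tsne`, `bayes`, `tps_bending`) and a `manifest`
#'   recording seeds, sizes, versions and per-variable branch
#'   decisions.  When `config$outdir` is set the tables are also
#'   written as CSV plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("toothmarks")),
    r_version = as.character(getRversion()),
    seed = config$seed, grouping = config$grouping,
    gates = list(normality = config$normality_threshold,
                 evidence = config$evidence_threshold),
    resampling = list(reps = config$reps, n_perm = config$n_perm),
    prior_prob_real = config$prior_prob_real,
    epsilon = config$epsilon,
    branch_decisions = list(),
    failed_stages = character(0)
  )
  result <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stages <<- c(manifest$failed_stages,
                                   paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  ## -- data ----------------------------------------------------------
  if (!is.null(config$score_file)) {
    scores <- read_morphologika(config$score_file)
    if (!is.null(config$metadata_file)) {
      scores <- landmark_dataset(scores$configs,
                                 read_metadata(config$metadata_file))
    }
    pits <- if (!is.null(config$pit_file)) {
      read_morphologika(config$pit_file)
    } else {
      NULL
    }
  } else {
    scores <- simulate_groups(config$specs$scores, "scores")
    pits <- simulate_groups(config$specs$pits, "pits")
  }
  grp <- scores$metadata[[config$grouping]]
  manifest$n <- list(scores = length(scores),
                     pits = if (is.null(pits)) 0L else length(pits))

  metrics <- score_metrics_table(scores)
  result$metrics <- metrics

  ## -- circular analyses of opening angles ---------------------------
  result$circular_descriptives <- stage("circular_descriptives", {
    do.call(rbind, lapply(split(metrics$OA, grp), function(oa) {
      desc <- circ_descriptives(oa)
      ray <- rayleigh_test(oa)
      sym <- symmetry_test(oa)
      robust <- p_h0(max(sym$p, 1e-300)) < config$evidence_threshold
      cbind(desc[, c("n", "min", "k_hat", "s_hat", "v")],
            uniformity_t = ray$statistic, uniformity_p = ray$p,
            symmetry_t = sym$statistic, symmetry_p = sym$p,
            theta_bar = desc$theta_bar, theta_tilde = desc$theta_tilde,
            central = if (robust) desc$theta_tilde else desc$theta_bar,
            robust = robust)
    }))
  })

  result$circular_comparisons <- stage("circular_comparisons", {
    levels_ <- unique(grp)
    pairs <- utils::combn(levels_, 2, simplify = FALSE)
    tab <- do.call(rbind, lapply(seq_along(pairs), function(ip) {
      pr <- pairs[[ip]]
      a <- metrics$OA[grp == pr[1]]; b <- metrics$OA[grp == pr[2]]
      do.call(rbind, lapply(
        c("watson_mean", "fisher_median", "mww_distribution"),
        function(m) {
          r <- circ_two_sample(a, b, m, reps = config$reps,
                               seed = config$seed + 31L * ip)
          data.frame(sample1 = pr[1], sample2 = pr[2], method = m,
                     statistic = r$statistic, p = r$p)
        }))
    }))
    calibrate_columns(tab, prior_prob_real = config$prior_prob_real)
  })

  ## -- univariate descriptives (gated) -------------------------------
  vars <- c("WIS", "WIM", "WIB", "D", "LDC", "RDC")
  result$descriptives <- stage("descriptives", {
    out <- do.call(rbind, lapply(vars, function(v) {
      do.call(rbind, lapply(unique(grp), function(g) {
        x <- metrics[[v]][grp == g]
        sw <- normality_test(x)
        robust <- sw$p < config$normality_threshold
        manifest$branch_decisions[[paste(v, g, sep = ".")]] <<-
          if (robust) "robust" else "parametric"
        cbind(variable = v, group = g, describe(x, robust),
              shapiro_w = sw$statistic, shapiro_p = sw$p)
      }))
    }))
    rownames(out) <- NULL
    out
  })

  ## -- mixed-metric PCA + equivalence + t-SNE -------------------------
  pca_m <- metric_pca(metrics)
  result$metric_pca_var <- pca_m$var_frac
  result$metric_equivalence <- stage("metric_equivalence", {
    equivalence_matrix(pca_m$scores, pca_m$var_frac, grp,
                       epsilon = config$epsilon,
                       prior_prob_real = config$prior_prob_real)
  })
  if (config$run_tsne) {
    result$tsne_metrics <- stage("tsne_metrics", {
      feat <- as.matrix(cbind(metrics[, vars],
                              OA = oa_to_linear(metrics$OA)))
      cbind(scores$metadata,
            as.data.frame(tsne_embed(feat, seed = config$seed + 5L)))
    })
  }

  ## -- geometric morphometrics: scores --------------------------------
  # allometric regression always works in shape space (shape on log
  # centroid size); form space is only used downstream when allometry
  # turns out to matter
  result$allometry <- list()
  gpa_shape <- gpa(scores, scale = TRUE)
  allom_scores <- stage("allometry_scores", {
    allometry_test(gpa_shape, n_perm = config$n_perm,
                   seed = config$seed + 11L)
  })
  result$allometry$scores_size <- allom_scores
  result$allometry$scores_stress <- stage("allometry_stress", {
    stress <- stress_covariate(scores$metadata$park)
    if (stats::sd(stress) > 0) {
      allometry_test(gpa_shape, covariate = stress,
                     n_perm = config$n_perm, seed = config$seed + 13L)
    } else {
      NULL
    }
  })

  # space selection: allometry "important" sends downstream analyses to
  # form space (no scaling); see the methods vignette for the 0.25
  # convention on the p(H0) scale
  important <- !is.null(allom_scores) && p_h0(max(allom_scores$p, 1e-300)) < 0.25
  manifest$branch_decisions$scores_space <-
    if (important) "form" else "shape"
  gpa_scores <- if (important) gpa(scores, scale = FALSE) else gpa_shape
  pca_s <- pca_shapes(gpa_scores)
  result$pc_scores <- cbind(scores$metadata,
                            as.data.frame(pca_s$scores[, seq_len(
                              min(10, ncol(pca_s$scores))), drop = FALSE]))
  result$shape_equivalence <- stage("shape_equivalence_scores", {
    equivalence_matrix(pca_s$scores, pca_s$var_frac, grp,
                       epsilon = config$epsilon,
                       prior_prob_real = config$prior_prob_real)
  })
  result$tps_bending <- stage("tps_scores", {
    do.call(rbind, lapply(unique(grp), function(g) {
      target <- apply(gpa_scores$aligned[, , grp == g, drop = FALSE],
                      c(1, 2), mean)
      data.frame(group = g,
                 bending_energy = tps_grid(gpa_scores$mean_shape,
                                           target)$bending_energy)
    }))
  })

  ## -- geometric morphometrics: pits ----------------------------------
  if (!is.null(pits)) {
    pgrp <- pits$metadata[[config$grouping]]
    gpa_pshape <- gpa(pits, scale = TRUE)
    allom_pits <- stage("allometry_pits", {
      allometry_test(gpa_pshape, n_perm = config$n_perm,
                     seed = config$seed + 17L)
    })
    result$allometry$pits_size <- allom_pits
    p_important <- !is.null(allom_pits) &&
      p_h0(max(allom_pits$p, 1e-300)) < 0.25
    manifest$branch_decisions$pits_space <-
      if (p_important) "form" else "shape"
    gpa_pits <- if (p_important) gpa(pits, scale = FALSE) else gpa_pshape
    pca_p <- pca_shapes(gpa_pits)
    result$pit_equivalence <- stage("shape_equivalence_pits", {
      equivalence_matrix(pca_p$scores, pca_p$var_frac, pgrp,
                         epsilon = config$epsilon,
                         prior_prob_real = config$prior_prob_real)
    })
    if (config$run_tsne) {
      result$tsne_pits <- stage("tsne_pits", {
        cbind(pits$metadata,
              as.data.frame(tsne_embed(gpa_pits$tangent,
                                       seed = config$seed + 19L)))
      })
    }
  }

  ## -- Bayesian effect sizes ------------------------------------------
  if (config$bayes && length(unique(grp)) == 2) {
    result$bayes <- stage("bayes_effects", {
      lv <- unique(grp)
      do.call(rbind, lapply(c("WIS", "D"), function(v) {
        fit <- fit_two_group(metrics[[v]][grp == lv[1]],
                             metrics[[v]][grp == lv[2]],
                             seed = config$seed + 23L)
        data.frame(variable = v, delta = fit$delta,
                   hdi_lower = fit$hdi95[1], hdi_upper = fit$hdi95[2],
                   diff = fit$diff_central, ps = fit$ps,
                   converged = fit$diagnostics$converged)
      }))
    })
  }

  result$manifest <- manifest
  class(result) <- "pipeline_result"

  if (!is.null(config$outdir)) {
    write_pipeline_reports(result, config$outdir)
  }
  result
}

# Pairwise equivalence (rTOST over retained PCs) between all group
# levels, in the lower-triangular layout of the published matrices.
equivalence_matrix <- function(scores, var_frac, groups, var_target = 0.95,
                               epsilon = 0.2, prior_prob_real = 0.5) {
  groups <- as.character(groups)
  levels_ <- unique(groups)
  pairs <- utils::combn(levels_, 2, simplify = FALSE)
  tab <- do.call(rbind, lapply(pairs, function(pr) {
    keep <- groups %in% pr
    mv <- multivariate_tost(scores[keep, , drop = FALSE], var_frac,
                            groups[keep], var_target = var_target,
                            epsilon = epsilon, method = "yuen")
    data.frame(sample1 = pr[1], sample2 = pr[2], d = mv$d, p = mv$p,
               n_pc = mv$n_pc)
  }))
  calibrate_columns(tab, prior_prob_real = prior_prob_real)
}

write_pipeline_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                       row.names = TRUE)
    }
  }
  wr(result$metrics, "metrics")
  wr(result$circular_descriptives, "circular_descriptives")
  wr(result$circular_comparisons, "circular_comparisons")
  wr(result$descriptives, "descriptives")
  wr(result$metric_equivalence, "metric_equivalence")
  wr(result$shape_equivalence, "shape_equivalence_scores")
  wr(result$pit_equivalence, "shape_equivalence_pits")
  wr(result$pc_scores, "pc_scores")
  wr(result$tsne_metrics, "tsne_metrics")
  wr(result$tsne_pits, "tsne_pits")
  wr(result$tps_bending, "tps_bending")
  wr(result$bayes, "bayes_effects")
  allom <- result$allometry
  if (length(allom)) {
    at <- do.call(rbind, lapply(names(allom), function(nm) {
      a <- allom[[nm]]
      if (is.null(a)) return(NULL)
      data.frame(test = nm, F = a$F, p = a$p,
                 resid_W = a$residual_diagnostics$W,
                 resid_p = a$residual_diagnostics$p,
                 resid_skew = a$residual_diagnostics$skew,
                 resid_kurtosis = a$residual_diagnostics$kurtosis)
    }))
    if (!is.null(at)) {
      at <- calibrate_columns(at)
      utils::write.csv(at, file.path(outdir, "allometry.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  tables:",
      paste(names(x)[vapply(x, is.data.frame, logical(1))],
            collapse = ", "), "\n")
  if (length(x$manifest$failed_stages)) {
    cat("  FAILED stages:",
        paste(x$manifest$failed_stages, collapse = "; "), "\n")
  }
  invisible(x)
}
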