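#!/usr/bin/env Rscript
# Geometric morphometrics: Procrustes superimposition of scores and
# pits, allometric regressions (log centroid size; captivity-stress
# proxy for scores), residual diagnostics, shape-space PCA with
# captive/wild equivalence across retained components, and TPS
# bending energies of the group mean shapes.

library(toothmarks)

scores <- read_morphologika("results/data/scores.morphologika.txt")
pits <- read_morphologika("results/data/pits.morphologika.txt")
dir.create("results/shape", showWarnings = FALSE, recursive = TRUE)
seed <- 20260930L

report_allometry <- function(label, a) {
  cat(sprintf("%-22s F = %6.3f  p = %.4g  p(H0) = %.3g  |skew| = %.2f\n",
              label, a$F, a$p, p_h0(min(max(a$p, 1e-300), 1 - 1e-12)),
              a$residual_diagnostics$skew))
  data.frame(test = label, F = a$F, p = a$p,
             p_h0 = p_h0(min(max(a$p, 1e-300), 1 - 1e-12)),
             resid_W = a$residual_diagnostics$W,
             resid_skew = a$residual_diagnostics$skew,
             resid_kurtosis = a$residual_diagnostics$kurtosis)
}

cat("== allometric regressions (999 permutations) ==\n")
g_scores <- gpa(scores, scale = TRUE)
g_pits <- gpa(pits, scale = TRUE)
rows <- list(
  report_allometry("scores ~ log(CS)",
                   allometry_test(g_scores, seed = seed)),
  report_allometry("scores ~ log(CS) x grp",
                   allometry_test(g_scores,
                                  groups = scores$metadata$captivity,
                                  seed = seed + 1)),
  report_allometry("scores ~ stress",
                   allometry_test(g_scores,
                                  covariate = stress_covariate(
                                    scores$metadata$park),
                                  seed = seed + 2)),
  report_allometry("pits ~ log(CS)",
                   allometry_test(g_pits, seed = seed + 3))
)
write.csv(do.call(rbind, rows), "results/shape/allometry.csv",
          row.names = FALSE)

## shape-space PCA and captive/wild equivalence over retained PCs
for (what in c("scores", "pits")) {
  g <- if (what == "scores") g_scores else g_pits
  md <- if (what == "scores") scores$metadata else pits$metadata
  p <- pca_shapes(g)
  mv <- multivariate_tost(p$scores, p$var_frac, md$captivity,
                          var_target = 0.95, epsilon = 0.2,
                          method = "yuen")
  cat(sprintf("\n%s: %d PCs to 95%% variance; captive/wild rTOST sum|d| = %.3f, p = %.3g\n",
              what, mv$n_pc, mv$d, mv$p))
  write.csv(mv$per_pc, sprintf("results/shape/equivalence_%s.csv", what),
            row.names = FALSE)
  write.csv(cbind(md, p$scores[, 1:min(10, ncol(p$scores))]),
            sprintf("results/shape/pc_scores_%s.csv", what),
            row.names = FALSE)
}

## TPS bending energy from the overall mean to each group mean (2D
## scores only)
grp <- scores$metadata$captivity
bend <- do.call(rbind, lapply(unique(grp), function(g) {
  target <- apply(g_scores$aligned[, , grp == g, drop = FALSE],
                  c(1, 2), mean)
  data.frame(group = g,
             bending_energy = tps_grid(g_scores$mean_shape,
                                       target)$bending_energy)
}))
write.csv(bend, "results/shape/tps_bending.csv", row.names = FALSE)
cat("\nTPS bending energy (mean -> group mean):\n")
print(bend, row.names = FALSE, digits = 3)
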