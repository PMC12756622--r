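#!/usr/bin/env Rscript
# Step 5: trial statistics over the assembled physicochemical table.
#
# Combines chemistry, water points, and the structure index per sample;
# tests treatment differences (Kruskal-Wallis + Dunn, Holm-adjusted,
# alpha = 0.05) and depth differences for the structure index; runs a
# correlation-matrix PCA on the standardized variables.

suppressPackageStartupMessages(library(emwsoil))

chem <- utils::read.csv("results/trial_inputs/chemistry.csv")
wp <- utils::read.csv("results/water_points.csv")
kld <- utils::read.csv("results/kld.csv")
tex <- utils::read.csv("results/trial_inputs/texture.csv")

tex$texture_class <- classify_texture(tex$sand, tex$silt, tex$clay)
utils::write.csv(tex, "results/texture_class.csv", row.names = FALSE)
cat("texture classes:", paste(unique(tex$texture_class), collapse = ", "),
    "\n")

tab <- Reduce(function(a, b) merge(a, b, by = "sample_id"),
              list(chem, wp, kld[, c("sample_id", "kld")]))
vars <- c("pH", "Ca_mg_per_kg", "SOC_mg_per_g", "P_mg_per_kg",
          "K_mg_per_kg", "Mg_mg_per_kg", "Fc_vol_pct", "PWP_vol_pct",
          "Wa_vol_pct", "porosity", "kld")

res <- group_tests(tab, vars, "treatment")
utils::write.csv(res$tests, "results/stats_tests.csv", row.names = FALSE)
utils::write.csv(res$groups, "results/stats_groups.csv", row.names = FALSE)
sig <- res$tests$variable[res$tests$kw_p <= 0.05]
cat("treatment-significant variables (alpha = 0.05):",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")

depth_res <- group_tests(tab, c("kld", "porosity"), "depth")
cat(sprintf("structure index by depth: KW p = %.4f (surface mean %.3f, deep %.3f)\n",
            depth_res$tests$kw_p[depth_res$tests$variable == "kld"],
            mean(tab$kld[tab$depth == "1-6"]),
            mean(tab$kld[tab$depth == "15-20"])))

pc <- run_pca(tab, vars)
ev <- pc$sdev^2 / sum(pc$sdev^2)
utils::write.csv(data.frame(sample_id = tab$sample_id,
                            treatment = tab$treatment, depth = tab$depth,
                            pc$x[, 1:3]),
                 "results/pca_scores.csv", row.names = FALSE)
utils::write.csv(data.frame(variable = rownames(pc$rotation),
                            pc$rotation[, 1:3]),
                 "results/pca_loadings.csv", row.names = FALSE)
cat(sprintf("PCA: first two components explain %.1f%% of the variance\n",
            100 * sum(ev[1:2])))
cat("wrote results/stats_*.csv, results/pca_*.csv\n")
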