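#!/usr/bin/env Rscript
# Step 7: the inference layer. (i) collinearity screen of the site
# covariates; (ii) random-forest permutation importance ranking of SOC
# drivers at the site scale; (iii) weighted forward-AIC interaction
# models of normalised SOC on the PES index, biomass, and site
# conditions, with and without past land-use (PLU).

library(soctraits)

d <- read_fixture("results/data")
tab <- assemble_analysis_table(d)
cat("analysis table:", nrow(tab), "stands\n\n")

## collinearity screen of candidate site covariates
cov <- d$sites[, c("mat_c", "map_mm", "n_dep", "f_climate",
                   "sand_mg_g", "clay_mg_g", "silt_mg_g", "ph")]
names(cov) <- sub("_mg_g", "", names(cov))
names(cov)[names(cov) == "f_climate"] <- "f_climate"
sc <- collinearity_screen(cov, preferred = c("sand", "f_climate"))
cat("covariate blocks:\n")
for (b in sc$blocks) cat(" ", paste(b, collapse = " + "), "\n")
cat("retained:", paste(sc$retained, collapse = ", "), "\n\n")

## driver ranking
pred <- tab[, c("pes_rr", "biomass_rr")]
pred$pes_sq <- tab$pes_rr^2
rk <- rank_drivers(tab$soc_rr, pred, weights = tab$w_data, seed = 1)
print(rk, digits = 3)
write.csv(rk, "results/driver_importance.csv", row.names = FALSE)

## interaction models
for (plu in c(TRUE, FALSE)) {
  cat("\n--- interaction model", if (plu) "with" else "without", "PLU ---\n")
  mod <- fit_interaction_model(tab, "soc_rr", "pes_rr", "biomass_rr",
                               weights = "w_data", include_plu = plu)
  cat("selected:", paste(mod$selected, collapse = ", "), "\n")
  cat("adjusted r2:", round(mod$adj_r_squared, 3), " n =", mod$n, "\n")
  print(round(mod$coefficients, 4))
  write.csv(as.data.frame(mod$coefficients),
            sprintf("results/model_%s_plu.csv", if (plu) "with" else "no"))
}
cat("\nwritten to results/driver_importance.csv, results/model_*_plu.csv\n")
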