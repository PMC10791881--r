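#!/usr/bin/env Rscript
# Validation analyses: leave-one-out cross-validation of the fitted
# model (stability of R2), Bland-Altman agreement between the two
# weekly filters of each campaign (an instrument-repeatability check the
# synthetic campaign supports), and a reduced parameter-recovery study.
# The full 100-replicate study runs in scripts/acceptance.R; here a
# 25-replicate version illustrates the result.

library(urbanlur)

res <- suppressMessages(run_pipeline(list(seed = 101, n_sites = 40)))
v <- res$validation
cat(sprintf("LOOCV: model R2 %.3f vs CV R2 %.3f -> gap %d pp (CV RMSE %.3f)\n",
            v$model_r2, v$cv_r2, v$r2_gap, sqrt(v$cv_mse)))

# agreement between week-1 and week-2 filters of the dry campaign
m <- res$measurements
dry <- m[m$campaign == "dry", ]
w1 <- dry$value[dry$week == 1][order(dry$site_id[dry$week == 1])]
w2 <- dry$value[dry$week == 2][order(dry$site_id[dry$week == 2])]
ba <- bland_altman(w1, w2)
print(ba)

rec <- recovery_experiment(n_reps = 25, seed = 77)
cat("\nparameter recovery over 25 synthetic cities (fraction of\n",
    "replicates with the generating coefficient inside its 95% CI):\n")
print(round(rec$recovery, 2))
cat("noise predictors per selected model:", rec$noise_terms_per_rep, "\n")

dir.create("results", showWarnings = FALSE)
jsonlite::write_json(
  list(loocv = v[c("model_r2", "cv_r2", "r2_gap", "cv_mse", "cv_sse", "n")],
       bland_altman = list(mean_difference = ba$mean_difference,
                           sd = ba$sd_difference,
                           limits = c(ba$lower_limit, ba$upper_limit)),
       recovery = as.list(rec$recovery),
       noise_terms_per_rep = rec$noise_terms_per_rep),
  "results/validation.json", auto_unbox = TRUE, digits = NA)
cat("written: results/validation.json\n")
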