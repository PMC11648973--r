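#!/usr/bin/env Rscript

# Nested beta regressions linking mean assignment probabilities to effective
# size and generations of drift. Two responses from script 03:
#   - distinct_response.csv: each wild analog's mean assignment to its own
#     eventual cluster (how quickly populations look distinct);
#   - hatchery_response.csv: each wild analog's mean assignment to the
#     hatchery analog's cluster (how quickly shared ancestry fades).
# Five candidate mean models (logit link, constant precision) are ranked by
# AICc; prediction surfaces of the best models are exported.

library(popdrift)

out_dir <- "results"
for (resp in c("distinct", "hatchery")) {
  path <- file.path(out_dir, paste0(resp, "_response.csv"))
  if (!file.exists(path))
    stop("run analysis/03_ancestry_over_time.R first (missing ", path, ")")
  ds <- read.csv(path)
  mt <- model_table(ds)
  write.csv(mt$table, file.path(out_dir, paste0(resp, "_model_table.csv")),
            row.names = FALSE)
  cat("\n==", resp, "response ==\n")
  print(mt$table[, c("model", "b0", "b1", "b2", "b3", "df", "loglik",
                     "aicc", "delta_aicc", "akaike_weight", "pseudo_r2")],
        digits = 4)
  best <- mt$fits[[mt$table$model[1]]]
  surf <- predict_surface(best, ne_grid = seq(25, 550, by = 25),
                          gen_grid = 0:50)
  write.csv(surf, file.path(out_dir, paste0(resp, "_predictions.csv")),
            row.names = FALSE)
  cat(sprintf("best model: %s (w = %.2f, pseudo-R2 = %.3f)\n",
              mt$table$model[1], mt$table$akaike_weight[1],
              mt$table$pseudo_r2[1]))
}
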