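#!/usr/bin/env Rscript
# Stage 2 — sweep the number of clusters and select K, per sex.
#
# Encodes each sex stratum as a binary co-occurrence matrix, fits PLSA for
# K = 2..10 (best of five seeded EM restarts each), and selects the working
# number of clusters by the default policy: minimum emission-count BIC
# among candidates whose smallest cluster covers at least 8% of the
# stratum. Writes the per-K score tables and the selected models.

suppressPackageStartupMessages(library(segmint))

roster <- read_roster("results/roster.csv")
strata <- stratify_by_sex(roster)
seed <- 1L

for (sex in c("male", "female")) {
  m <- encode_roster(strata[[sex]])
  cfg <- fit_config(n_restarts = 5L, seed = seed * 100L + 7L)
  tab <- suppressWarnings(sweep_k(m, 2L, 10L, cfg))
  k_sel <- select_k(tab, selection_policy())
  model <- attr(tab, "models")[[match(as.integer(k_sel), tab$k)]]
  write.csv(as.data.frame(tab), sprintf("results/sweep_%s.csv", sex),
            row.names = FALSE)
  write_model_json(model, sprintf("results/model_%s.json", sex))

  cat(sprintf("\n== %s stratum (n = %d) ==\n", sex, nrow(m)))
  print(as.data.frame(tab)[, c("k", "loglik", "bic_emission",
                               "min_cluster_mass", "min_cluster_n")],
        digits = 6, row.names = FALSE)
  cat(sprintf("selected K = %d (winning restart seed %d, %d EM iterations)\n",
              as.integer(k_sel), model$seed, model$n_iter))
}
cat("\nwrote results/sweep_{male,female}.csv and results/model_{male,female}.json\n")
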