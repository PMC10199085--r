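#!/usr/bin/env Rscript
# Cohort-scale parameter recovery: with an odds ratio of 4 planted on one of
# the five candidate genes (5236 samples, 1.54% prevalence, per-gene variant
# counts matching the observed totals), how often does the burden scan rank
# that gene's p-value smallest? Also demonstrates co-carrier group recovery.

library(cholvar)
out <- "results"
dir.create(out, showWarnings = FALSE)
seed <- 1L
reps <- 100L

scan_rep <- function(r) {
  cfg <- sim_config(seed = seed * 30000L + r, or = c(ABCB11 = 4))
  sim <- simulate_cohort(cfg)
  p <- vapply(cfg$genes, function(g) {
    b <- cmc_exact(sim$genotypes, g, sim$truth$case)
    if (is_empty_collapse(b)) 1 else b$p_value
  }, numeric(1))
  list(top = names(which.min(p)), p = p)
}

runs <- lapply(seq_len(reps), scan_rep)
hits <- vapply(runs, function(x) x$top == "ABCB11", logical(1))
cat(sprintf("Planted ABCB11 enrichment ranked first in %d/%d replicates\n",
            sum(hits), reps))
pmat <- t(vapply(runs, `[[`, numeric(5), "p"))
write_tsv(cbind(replicate = seq_len(reps), as.data.frame(pmat),
                top_gene = vapply(runs, `[[`, character(1), "top")),
          file.path(out, "parameter_recovery.tsv"))

# exact-carrier-set grouping on one replicate with a planted trio
cfg <- sim_config(n_samples = 1000, seed = seed, genes = "ATP8B1",
                  n_variants = 20, prevalence = 0.0154)
sim <- simulate_cohort(cfg)
gm <- plant_co_carriers(sim$genotypes, sim$genotypes$variant_keys[1:3],
                        sim$genotypes$sample_ids[1:3])
groups <- co_carrier_groups(gm)
cat("Recovered", length(groups), "co-carrier group(s); first:",
    paste(groups[[1]], collapse = ", "), "\n")
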