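#!/usr/bin/env Rscript
# Genotype-to-phenotype side of the analysis on the packaged variant tables:
# consequence classification, LoF tallies, inclusion filtering, ACMG-AMP
# verdicts and their concordance with the printed calls, and the per-gene
# phenotype counts. Writes tables under results/printed_tables/.

library(cholvar)
out <- "results/printed_tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

t3 <- chol_fixture("phenotype_variants")
t4 <- chol_fixture("lof_variants")
both <- classify_variants(rbind(t3, t4))

tl <- tally_lof(both)
cat("Loss-of-function variants:", tl["total"], "(",
    tl["frameshift"], "frameshift,", tl["stop_gained"], "stop-gained,",
    tl["splice_acceptor"], "splice-acceptor )\n")

filt <- filter_table(both)
cat("Inclusion rule keeps", nrow(filt$records), "of", nrow(both),
    "variants; excluded:\n")
print(filt$decisions$variant_id[!filt$decisions$included])
write_tsv(filt$decisions, file.path(out, "inclusion_decisions.tsv"))

for (mode in c("strict", "paper_tolerant")) {
  conc <- validate_against_printed(classify_variants(both), mode = mode)
  cat(sprintf("ACMG %s mode: %d/%d rows concordant with printed verdicts\n",
              mode, conc$n_match, conc$n_match + conc$n_mismatch))
  write_tsv(conc$mismatches,
            file.path(out, paste0("acmg_discordant_", mode, ".tsv")))
}

counts <- genotype_phenotype_counts(t3)
cat("Per-gene phenotype counts (missense table):\n")
print(counts[, c("ICP", "gallstone", "cholangiocarcinoma", "cirrhosis")])
write_tsv(cbind(gene = rownames(counts), as.data.frame(counts)),
          file.path(out, "phenotype_counts.tsv"))

summ <- render_summary(list(decisions = filt$decisions,
                            verdicts = acmg_verdicts(filt$records)))
write_tsv(cbind(gene = rownames(summ), as.data.frame(summ)),
          file.path(out, "gene_summary.tsv"))
cat("Per-gene summary written to", file.path(out, "gene_summary.tsv"), "\n")
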