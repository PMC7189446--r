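#!/usr/bin/env Rscript
# Stage 6 -- gene-pair ledger: annotate conserved-loop anchors with genes,
# compute the feature-association ledger (odds ratios, Cramer's V),
# expression-quartile concordance, and partner-count distribution.
source("analysis/00_common.R")

lay <- study_layout()
ma <- read_matrix(file.path(DATA, "matrix_shoot.tsv"), lay)
mb <- read_matrix(file.path(DATA, "matrix_root.tsv"), lay)
cons <- conserved_loops(call_loops_intra(ma), call_loops_intra(mb))
genes <- read_genes(file.path(DATA, "genes.bed"))

pairs <- annotate_anchors(cons, genes)
fwrite(pairs, file.path(OUT, "gene_pair_table.tsv"), sep = "\t")
cat(sprintf("gene pairs on conserved loops: %d\n", nrow(pairs)))

feats <- c("expressed", "H3K9ac", "H3K36me3", "H3K27me3", "RNAPII")
led <- association_matrix(pairs, feats)
fwrite(led$raw, file.path(OUT, "association_ledger_raw.tsv"), sep = "\t")
fwrite(led$symmetrized, file.path(OUT, "association_ledger.tsv"),
       sep = "\t")
ee <- led$symmetrized[feature1 == "expressed" & feature2 == "expressed"]
cat(sprintf(
  "transcriptional-status concordance: log2(OR) = %.3f, Cramer's V = %.3f\n",
  ee$log2_or, ee$cramers_v))

conc <- tryCatch(expression_concordance(pairs, n_quantiles = 4),
                 error = function(e) NULL)
if (!is.null(conc)) {
  fwrite(as.data.table(conc$counts),
         file.path(OUT, "expression_concordance.tsv"), sep = "\t")
  cat(sprintf(
    "expression quartile concordance: diagonal fraction %.2f (n = %d)\n",
    conc$diagonal_fraction, conc$n))
}

pc <- partner_counts(pairs)
fwrite(pc$counts, file.path(OUT, "partner_counts.tsv"), sep = "\t")
cat(sprintf(
  "partners per looped gene: %.0f%% with >= 4, %.0f%% with >= 10 (n = %d)\n",
  100 * pc$frac_ge4, 100 * pc$frac_ge10, pc$n_genes))
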