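#!/usr/bin/env Rscript
# Stage 1 -- simulate the synthetic polyploid study system: two Hi-C
# conditions drawn around one planted truth (territories, Rabl signal,
# condensed domains, gene-to-gene loops), genes with marks and coupled
# two-condition expression, and an RNAPII Hi-ChIP-like matrix.
source("analysis/00_common.R")

lay <- study_layout()
pa <- study_params(SEED)
sim_a <- simulate_contacts(lay, pa)
pb <- study_params(SEED + 1L)
sim_b <- simulate_contacts(lay, pb, truth = sim_a$truth)
gx <- simulate_genes_and_expression(lay, sim_a$truth, pa)
hichip <- simulate_hichip(sim_a$matrix, gx$genes, occupancy_boost = 5,
                          thinning = 0.5, seed = SEED + 2L)

write_matrix(sim_a$matrix, file.path(DATA, "matrix_shoot.tsv"))
write_matrix(sim_b$matrix, file.path(DATA, "matrix_root.tsv"))
write_matrix(hichip, file.path(DATA, "matrix_hichip.tsv"))
write_genes(gx$genes, file.path(DATA, "genes.bed"))
truth <- gx$truth
fwrite(truth$planted_domains, file.path(DATA, "truth_domains.tsv"),
       sep = "\t")
fwrite(truth$boundaries, file.path(DATA, "truth_boundaries.tsv"),
       sep = "\t")
fwrite(truth$planted_loops, file.path(DATA, "truth_loops.tsv"), sep = "\t")
fwrite(truth$gene_pair_couplings, file.path(DATA, "truth_couplings.tsv"),
       sep = "\t")

cat(sprintf(
  "simulated %d bins over %d chromosomes; %d genes (%d expressed);\n",
  nrow(sim_a$matrix$bins), nrow(lay$chroms), nrow(gx$genes),
  sum(gx$genes$expressed)),
  sprintf("planted: %d domains, %d boundary bins, %d loops\n",
          nrow(truth$planted_domains), nrow(truth$boundaries),
          nrow(truth$planted_loops)))
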