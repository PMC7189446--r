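#!/usr/bin/env Rscript
# Stage 3 -- genome-territory statistics: super-bin class medians,
# subgenome-pair medians, and the homeolog vs non-homeolog comparison
# (Mann-Whitney U, Cliff's Delta).
source("analysis/00_common.R")

lay <- study_layout()
bal <- ice_normalize(read_matrix(file.path(DATA, "matrix_shoot.tsv"), lay))
tab <- classify_and_aggregate(bal, super_bin = 1e6)
med <- median_by_class(tab)
ht <- homeolog_test(tab)

fwrite(med$by_class, file.path(OUT, "territory_class_medians.tsv"),
       sep = "\t")
fwrite(med$by_subgenome_pair,
       file.path(OUT, "territory_subgenome_pairs.tsv"), sep = "\t")
fwrite(data.table(U = ht$U, p = ht$p, cliffs_delta = ht$cliffs_delta,
                  n_homeolog = ht$n1, n_non_homeolog = ht$n2),
       file.path(OUT, "territory_homeolog_test.tsv"), sep = "\t")

cat("class medians (CPM):\n")
print(med$by_class)
cat(sprintf(
  "hierarchy intra >= same-subgenome >= cross-subgenome: %s\n",
  med$hierarchy_ok))
cat(sprintf(
  "homeolog vs non-homeolog: U = %.0f, p = %.3g, Cliff's delta = %.3f\n",
  ht$U, ht$p, ht$cliffs_delta))
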