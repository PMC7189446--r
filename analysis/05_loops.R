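#!/usr/bin/env Rscript
# Stage 5 -- significance-based loop calling (p < 0.05, z > 1.5,
# FDR < 0.1) in both conditions, conservation matching, interchromosomal
# interactions, RNAPII Hi-ChIP loops, and recovery against the planted
# truth.
source("analysis/00_common.R")

lay <- study_layout()
ma <- read_matrix(file.path(DATA, "matrix_shoot.tsv"), lay)
mb <- read_matrix(file.path(DATA, "matrix_root.tsv"), lay)
mh <- read_matrix(file.path(DATA, "matrix_hichip.tsv"), lay)

la <- call_loops_intra(ma)
lb <- call_loops_intra(mb)
cons <- conserved_loops(la, lb)
inter <- call_interactions_inter(ma)
ral <- call_loops_intra(mh)

write_bedpe(la, file.path(OUT, "loops_shoot.bedpe"))
write_bedpe(lb, file.path(OUT, "loops_root.bedpe"))
write_bedpe(cons, file.path(OUT, "loops_conserved.bedpe"))
write_bedpe(inter, file.path(OUT, "interchromosomal.bedpe"))
write_bedpe(ral, file.path(OUT, "loops_hichip.bedpe"))

truthl <- fread(file.path(DATA, "truth_loops.tsv"))
key <- paste(truthl$i, truthl$j)
rec <- function(ls) mean(key %in% paste(ls$loops$i, ls$loops$j))
cat(sprintf("loops: shoot %d, root %d, conserved %d (of %d tested pairs)\n",
            nrow(la$loops), nrow(lb$loops), nrow(cons$loops), la$n_tested),
    sprintf("planted-loop recovery: shoot %.0f%%, root %.0f%%, conserved %.0f%%\n",
            100 * rec(la), 100 * rec(lb), 100 * rec(cons)),
    sprintf("interchromosomal calls: %d (none planted); Hi-ChIP loops: %d\n",
            nrow(inter$loops), nrow(ral$loops)))
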