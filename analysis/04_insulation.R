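#!/usr/bin/env Rscript
# Stage 4 -- insulation index at 25 kb with a 100-kb window, condensed
# domain (ICONS) calling at threshold 0.4, insulation deciles, boundary
# recovery against the planted truth, and insulation meta-profiles over
# gene classes.
source("analysis/00_common.R")

lay <- study_layout()
bal <- ice_normalize(read_matrix(file.path(DATA, "matrix_shoot.tsv"), lay))
track <- insulation_index(bal, window = 100e3)
doms <- call_domains(track, threshold = 0.4, min_bins = 2)
track <- partition_deciles(track)
write_bedgraph(track, file.path(OUT, "insulation.bedgraph"))
write_domains_bed(doms, file.path(OUT, "icons_domains.bed"))
fwrite(track[!is.na(decile), .(chrom, start, end, decile)],
       file.path(OUT, "insulation_deciles.bed"), sep = "\t",
       col.names = FALSE)

s <- attr(doms, "summary")
cat(sprintf(
  "ICONS: %d domains, %.1f%% genome coverage, mean size %.0f kb\n",
  s$count, 100 * s$coverage_fraction, s$mean_size / 1e3))

# boundary recovery against the planted truth
truthb <- fread(file.path(DATA, "truth_boundaries.tsv"))
bd <- call_boundaries(track)
bd[, pos := start / lay$bin_size]
hit <- vapply(seq_len(nrow(truthb)), function(k)
  any(abs(bd[chrom == truthb$chrom[k]]$pos - truthb$bin[k]) <= 1),
  logical(1))
cat(sprintf("planted boundaries recovered within +/-1 bin: %.0f%%\n",
            100 * mean(hit)))

# insulation over genes split by RNAPII occupancy and expression status
genes <- read_genes(file.path(DATA, "genes.bed"))
for (attr_col in c("RNAPII", "expressed")) {
  prof <- insulation_over_genes(track, genes, split_by = attr_col,
                                flank = 50e3, body_bins = 20,
                                flank_bins = 10)
  for (lev in names(prof))
    fwrite(prof[[lev]],
           file.path(OUT, sprintf("insulation_over_genes_%s_%s.tsv",
                                  attr_col, lev)), sep = "\t")
  b_true <- median(prof$`TRUE`[position == "body"]$value, na.rm = TRUE)
  b_false <- median(prof$`FALSE`[position == "body"]$value, na.rm = TRUE)
  cat(sprintf(
    "median body insulation, %s TRUE vs FALSE: %.3f vs %.3f\n",
    attr_col, b_true, b_false))
}

# gene decile assignment (>= 50%% of the gene inside the bin)
assigned <- assign_genes(genes, track[!is.na(decile)], label_col = "decile")
fwrite(assigned, file.path(OUT, "gene_deciles.tsv"), sep = "\t")
cat(sprintf("genes assigned to insulation deciles: %d of %d\n",
            sum(!is.na(assigned$label)), nrow(assigned)))
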