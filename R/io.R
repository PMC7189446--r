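#' Writers for the package's text formats
#'
#' All coordinates are written 0-based half-open (BED convention).
#'
#' @name writers
NULL

#' @describeIn writers insulation (or any per-bin) track as bedGraph;
#'   undefined bins omitted.
#' @param track data.table(chrom, start, end, score).
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  dt <- as.data.table(track)[!is.na(score), .(chrom, start, end, score)]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @describeIn writers domain set as BED4 (name = mean insulation score).
#' @param domains data.table(chrom, start, end, mean_score).
#' @export
write_domains_bed <- function(domains, path) {
  dt <- as.data.table(domains)[, .(chrom, start, end,
                                   name = sprintf("%.4f", mean_score))]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @describeIn writers loop set as BEDPE with name, score = z and extra
#'   columns obs, exp, p, q.
#' @param loop_set a `loop_set`.
#' @export
write_bedpe <- function(loop_set, path) {
  lp <- loop_set$loops
  out <- lp[, .(chrom1, start1, end1, chrom2, start2, end2,
                name = sprintf("loop_%d", .I), score = z, strand1 = ".",
                strand2 = ".", obs, expected, p, q)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @describeIn writers genes as BED6 plus a sidecar TSV
#'   (`<path>.attrs.tsv`) with gene_id, marks as a semicolon list, TPM per
#'   condition/replicate, log2fc and de_pvalue.
#' @param genes gene table from [simulate_genes_and_expression()].
#' @export
write_genes <- function(genes, path) {
  g <- as.data.table(genes)
  bed <- g[, .(chrom, start, end, name = gene_id, score = 0, strand)]
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  mark_cols <- intersect(c("H3K9ac", "H3K36me3", "H3K27me3", "RNAPII",
                           "ATAC"), names(g))
  marks <- apply(as.matrix(g[, ..mark_cols]), 1L, function(r)
    paste(mark_cols[as.logical(r)], collapse = ";"))
  tpm_cols <- grep("^tpm_[ab]_r", names(g), value = TRUE)
  side <- cbind(g[, .(gene_id)], marks = marks, g[, ..tpm_cols],
                g[, .(expressed, log2fc, de_pvalue)])
  fwrite(side, paste0(path, ".attrs.tsv"), sep = "\t")
  invisible(path)
}

#' Read genes written by [write_genes()]
#' @param path BED6 path (sidecar `<path>.attrs.tsv` must exist).
#' @return gene data.table.
#' @export
read_genes <- function(path) {
  bed <- fread(path, sep = "\t",
               col.names = c("chrom", "start", "end", "gene_id", "score",
                             "strand"))
  side <- fread(paste0(path, ".attrs.tsv"), sep = "\t")
  g <- merge(bed[, .(gene_id, chrom, start, end, strand)], side,
             by = "gene_id", sort = FALSE)
  all_marks <- c("H3K9ac", "H3K36me3", "H3K27me3", "RNAPII", "ATAC")
  for (mk in all_marks)
    set(g, j = mk, value = vapply(strsplit(ifelse(is.na(g$marks), "",
                                                  g$marks), ";"),
                                  function(v) mk %in% v, logical(1)))
  g[, marks := NULL]
  tpm_a_cols <- grep("^tpm_a_r", names(g), value = TRUE)
  tpm_b_cols <- grep("^tpm_b_r", names(g), value = TRUE)
  if (length(tpm_a_cols))
    g[, tpm_a := apply(as.matrix(.SD), 1L, median), .SDcols = tpm_a_cols]
  if (length(tpm_b_cols))
    g[, tpm_b := apply(as.matrix(.SD), 1L, median), .SDcols = tpm_b_cols]
  g[]
}

#' Read gene intervals from a GFF3 file
#'
#' Extracts `gene`-type records; GFF3 1-based closed coordinates are
#' converted to the package's 0-based half-open convention.  The gene_id
#' is taken from the `ID` attribute.
#'
#' @param path GFF3 file.
#' @return data.table(gene_id, chrom, start, end, strand).
#' @export
read_genes_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- tstrsplit(ln, "\t", fixed = TRUE)
  if (length(f) < 9L) stop("format error: not a 9-column GFF3")
  dt <- data.table(chrom = f[[1L]], type = f[[3L]],
                   start = as.numeric(f[[4L]]) - 1, end = as.numeric(f[[5L]]),
                   strand = f[[7L]], attrs = f[[9L]])
  dt <- dt[type == "gene"]
  id <- sub(".*ID=([^;]+).*", "\\1", dt$attrs)
  dt[, .(gene_id = id, chrom, start, end, strand)]
}

#' Read peak intervals from a BED file
#' @param path BED3+ file.
#' @return data.table(chrom, start, end).
#' @export
read_peaks_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  dt[, .(chrom, start = as.numeric(start), end = as.numeric(end))]
}

#' Assign chromatin marks to genes from peak files
#'
#' A gene carries a mark when a peak overlaps it by >= 1 bp; for ATAC the
#' rule is a peak within `atac_upstream` bp upstream of the TSS
#' (strand-aware).
#'
#' @param genes data.table(gene_id, chrom, start, end, strand).
#' @param peaks named list of peak tables (names become mark columns).
#' @param atac_upstream bp upstream of the TSS for the ATAC rule
#'   (default 500).
#' @return genes with one logical column per mark.
#' @export
assign_marks <- function(genes, peaks, atac_upstream = 500) {
  g <- copy(as.data.table(genes))
  for (mk in names(peaks)) {
    pk <- as.data.table(peaks[[mk]])
    if (identical(mk, "ATAC")) {
      tss <- ifelse(g$strand == "-", g$end, g$start)
      qs <- ifelse(g$strand == "-", tss, tss - atac_upstream)
      qe <- ifelse(g$strand == "-", tss + atac_upstream, tss)
      gr_q <- GenomicRanges::GRanges(g$chrom,
        IRanges::IRanges(pmax(qs, 0) + 1, pmax(qe, 1)))
    } else {
      gr_q <- GenomicRanges::GRanges(g$chrom,
        IRanges::IRanges(g$start + 1, g$end))
    }
    gr_p <- GenomicRanges::GRanges(pk$chrom,
      IRanges::IRanges(pk$start + 1, pk$end))
    set(g, j = mk,
        value = GenomicRanges::countOverlaps(gr_q, gr_p) > 0)
  }
  g[]
}
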