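#' Insulation index of a balanced contact matrix
#'
#' For every bin `i`, the raw insulation is the mean balanced contact over
#' the `w x w` square straddling the bin: rows `[i-w, i-1]`, columns
#' `[i+1, i+w]` on the same chromosome, where `w = window / bin_size`.
#' The score is `log2(raw_i / chromosome mean of defined raw values)`, so
#' each chromosome's defined scores are centred on 0 and negative scores
#' mark insulated (contact-depleted) bins.  The score is missing where the
#' full square does not fit inside the chromosome, or where more than half
#' of the window entries involve masked bins.
#'
#' @param m ICE-balanced contact_matrix.
#' @param window window size in bp (default 100 kb); must be a multiple of
#'   the bin size and at least one bin.
#' @return data.table (chrom, start, end, idx, score) with attribute
#'   `window`; class `insulation_track`.
#' @export
insulation_index <- function(m, window = 100e3) {
  bs <- m$layout$bin_size
  if (window < bs || window %% bs != 0)
    stop("invalid parameter: window must be a positive multiple of bin size")
  w <- as.integer(window / bs)
  bins <- m$bins
  masked <- if (!is.null(m$bias)) is.na(m$bias) else rep(FALSE, nrow(bins))
  dense <- as_dense(m)           # balanced values, masked rows/cols NA
  raw <- rep(NA_real_, nrow(bins))
  for (ck in unique(bins$chrom)) {
    ix <- bins[chrom == ck]$idx
    k <- length(ix)
    sub <- dense[ix, ix, drop = FALSE]
    for (t in seq_len(k)) {
      if (t - w < 1L || t + w > k) next
      sq <- sub[(t - w):(t - 1L), (t + 1L):(t + w), drop = FALSE]
      if (mean(is.na(sq)) > 0.5) next
      raw[ix[t]] <- mean(sq, na.rm = TRUE)
    }
  }
  track <- data.table(bins[, .(chrom, start, end, idx)], raw = raw)
  track[, score := {
    mu <- mean(raw[!is.na(raw)])
    ifelse(is.na(raw) | mu <= 0 | raw <= 0, NA_real_, log2(raw / mu))
  }, by = chrom]
  track[, raw := NULL]
  setattr(track, "window", window)
  setattr(track, "class", c("insulation_track", class(track)))
  track[]
}

#' Call condensed folding domains (ICONS) from an insulation track
#'
#' Domains are maximal runs of at least `min_bins` consecutive defined bins
#' with insulation score `>= threshold` -- the condensed, contact-enriched,
#' gene-poor interiors; the flanking low-score bins are their boundaries.
#'
#' @param track an insulation_track.
#' @param threshold calling threshold on the score (default 0.4).
#' @param min_bins minimum run length (default 2).
#' @return data.table (chrom, start, end, n_bins, mean_score) with a
#'   `summary` attribute: list(count, coverage_bp, coverage_fraction,
#'   mean_size).  Empty set allowed.
#' @export
call_domains <- function(track, threshold = 0.4, min_bins = 2L) {
  dt <- as.data.table(track)
  doms <- dt[, {
    ok <- !is.na(score) & score >= threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_bins
    if (any(keep)) {
      data.table(start = start[starts[keep]], end = end[ends[keep]],
                 n_bins = r$lengths[keep],
                 mean_score = vapply(which(keep), function(k)
                   mean(score[starts[k]:ends[k]]), numeric(1)))
    } else data.table(start = numeric(), end = numeric(),
                      n_bins = integer(), mean_score = numeric())
  }, by = chrom]
  genome_bp <- dt[, sum(end - start)]
  cov <- if (nrow(doms)) sum(doms$end - doms$start) else 0
  setattr(doms, "summary", list(
    count = nrow(doms), coverage_bp = cov,
    coverage_fraction = cov / genome_bp,
    mean_size = if (nrow(doms)) mean(doms$end - doms$start) else NA_real_))
  doms[]
}

#' Call insulated boundaries as local minima of the insulation score
#'
#' A boundary bin is a (possibly tied) local minimum of the insulation
#' score along its chromosome with score below `max_score`: its score is
#' no greater than both neighbours' (undefined neighbours count as +Inf).
#' These are the contact-depleted bins flanking condensed domains, where
#' boundary genes reside.
#'
#' @param track an insulation_track.
#' @param max_score only minima below this score qualify (default 0).
#' @return data.table (chrom, start, end, idx, score) of boundary bins.
#' @export
call_boundaries <- function(track, max_score = 0) {
  dt <- as.data.table(track)
  dt[, {
    sc <- ifelse(is.na(score), Inf, score)
    lo <- c(Inf, head(sc, -1L)); hi <- c(tail(sc, -1L), Inf)
    ok <- is.finite(sc) & sc <= lo & sc <= hi & sc < max_score
    .(start = start[ok], end = end[ok], idx = idx[ok], score = score[ok])
  }, by = chrom]
}

#' Partition defined insulation bins into deciles
#'
#' Defined bins are ranked by score (ties broken by genomic order, i.e. by
#' bin index) and split into 10 groups; when the count is not divisible by
#' 10 the remainder is spread over the lowest deciles.  Decile 1 holds the
#' most negative scores.
#'
#' @param track an insulation_track.
#' @return the track with an integer `decile` column (NA for undefined
#'   bins).
#' @export
partition_deciles <- function(track) {
  dt <- copy(as.data.table(track))
  def <- which(!is.na(dt$score))
  if (length(def) < 10L) stop("invalid input: fewer than 10 defined bins")
  ord <- def[order(dt$score[def], def)]
  n <- length(ord)
  base <- n %/% 10L; rem <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  lab <- rep.int(seq_len(10L), sizes)
  dt[, decile := NA_integer_]
  dt[ord, decile := lab]
  dt[]
}

#' Assign genes to labelled bins by majority overlap
#'
#' A gene is assigned the label of the bin covering at least
#' `min_overlap_fraction` of its length; a gene split exactly 50/50 between
#' two bins goes to the left (lower-coordinate) bin; genes without a
#' qualifying bin are unassigned (NA).
#'
#' @param genes data.table with `gene_id`, `chrom`, `start`, `end`.
#' @param bins data.table with `chrom`, `start`, `end` and a `label`
#'   column (name given by `label_col`).
#' @param label_col name of the label column in `bins` (default "decile").
#' @param min_overlap_fraction default 0.5.
#' @return data.table (gene_id, label).
#' @export
assign_genes <- function(genes, bins, label_col = "decile",
                         min_overlap_fraction = 0.5) {
  g <- as.data.table(genes)
  b <- as.data.table(bins)
  if (any(g$end <= g$start) || any(b$end <= b$start))
    stop("format error: intervals must satisfy end > start")
  gr_g <- GenomicRanges::GRanges(g$chrom,
    IRanges::IRanges(g$start + 1L, g$end))
  gr_b <- GenomicRanges::GRanges(b$chrom,
    IRanges::IRanges(b$start + 1L, b$end))
  hits <- GenomicRanges::findOverlaps(gr_g, gr_b)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_g)[qh], IRanges::ranges(gr_b)[sh]))
  frac <- ov / (g$end[qh] - g$start[qh])
  cand <- data.table(gi = qh, bi = sh, frac = frac,
                     bstart = b$start[sh])[frac >= min_overlap_fraction]
  setorder(cand, gi, -frac, bstart)   # ties at the boundary -> left bin
  best <- cand[!duplicated(gi)]
  lab <- b[[label_col]][rep(NA_integer_, nrow(g))]  # NA of the label type
  lab[best$gi] <- b[[label_col]][best$bi]
  data.table(gene_id = g$gene_id, label = lab)
}
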