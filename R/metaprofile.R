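#' Meta-profiles of a signal track over scaled regions
#'
#' Rescales every region body to `body_bins` meta-bins, adds `flank` bp of
#' fixed-width flank on each side (`flank_bins` bins per flank), reverses
#' minus-strand regions, and summarises the signal per meta-bin across
#' regions with `statistic` (median by default).  The signal is an interval
#' track (bedGraph semantics: `chrom`, `start`, `end`, `value`, 0-based
#' half-open); uncovered base pairs count as 0.  Regions shorter than 1 bp
#' are skipped and counted in the `n_skipped` attribute.
#'
#' @param signal data.table(chrom, start, end, value).
#' @param regions data.table(chrom, start, end) with optional `strand`.
#' @param body_bins number of meta-bins over the region body (default 100).
#' @param flank flank size in bp on each side (default 2000).
#' @param flank_bins number of meta-bins per flank (default 20).
#' @param statistic "median" or "mean".
#' @return data.table (meta_bin, position, value) where position is
#'   "upstream", "body" or "downstream"; attributes `n_regions`,
#'   `n_skipped`.  Class `signal_profile`.
#' @export
metaprofile <- function(signal, regions, body_bins = 100L, flank = 2000,
                        flank_bins = 20L, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  sig <- as.data.table(signal)
  reg <- as.data.table(regions)
  if (nrow(reg) == 0L) stop("invalid input: no regions")
  if (!"strand" %in% names(reg)) reg[, strand := "+"]
  skipped <- reg[end - start < 1]
  reg <- reg[end - start >= 1]
  nm <- body_bins + 2L * flank_bins

  # cumulative integral of the signal per chromosome: F(x) = int_0^x v
  cumint <- lapply(split(sig, sig$chrom), function(s) {
    s <- s[order(start)]
    list(starts = s$start, ends = s$end, v = s$value)
  })
  int_at <- function(ci, x) {
    # integral of the track from 0 to x (x may be a vector)
    if (is.null(ci)) return(numeric(length(x)))
    s <- ci$starts; e <- ci$ends; v <- ci$v
    cum <- cumsum(v * (e - s))
    idx <- findInterval(x, s)
    out <- numeric(length(x))
    pos <- idx > 0
    prev <- ifelse(idx > 1, cum[pmax(idx - 1, 1)], 0)
    within <- pmax(0, pmin(x[pos], e[idx[pos]]) - s[idx[pos]]) * v[idx[pos]]
    out[pos] <- prev[pos] + within
    out
  }
  mean_over <- function(ci, a, b) {
    w <- b - a
    ifelse(w > 0, (int_at(ci, b) - int_at(ci, a)) / w, NA_real_)
  }

  prof <- matrix(NA_real_, nrow(reg), nm)
  fw <- if (flank_bins > 0L) flank / flank_bins else 0
  for (r in seq_len(nrow(reg))) {
    ci <- cumint[[reg$chrom[r]]]
    s <- reg$start[r]; e <- reg$end[r]
    up_edges <- if (flank_bins > 0L) s - flank + fw * (0:flank_bins) else s
    body_edges <- s + (e - s) * (0:body_bins) / body_bins
    dn_edges <- if (flank_bins > 0L) e + fw * (0:flank_bins) else NULL
    edges <- c(up_edges, body_edges[-1L],
               if (flank_bins > 0L) dn_edges[-1L])
    vals <- mean_over(ci, head(edges, -1L), tail(edges, -1L))
    if (reg$strand[r] == "-") vals <- rev(vals)
    prof[r, ] <- vals
  }
  stat_fun <- if (statistic == "median") {
    function(v) median(v, na.rm = TRUE)
  } else function(v) mean(v, na.rm = TRUE)
  out <- data.table(
    meta_bin = seq_len(nm),
    position = rep(c("upstream", "body", "downstream"),
                   c(flank_bins, body_bins, flank_bins)),
    value = apply(prof, 2L, stat_fun))
  setattr(out, "n_regions", nrow(reg))
  setattr(out, "n_skipped", nrow(skipped))
  setattr(out, "class", c("signal_profile", class(out)))
  out[]
}

#' Insulation meta-profiles over gene classes
#'
#' Builds one meta-profile of the insulation score over scaled gene bodies
#' (plus flanks) per level of a splitting attribute, e.g. presence/absence
#' of a chromatin mark or an expression class.  Classes with zero genes are
#' omitted with a warning.  Undefined insulation bins are dropped from the
#' signal (they contribute as 0 coverage).
#'
#' @param track an insulation_track (from [insulation_index()]).
#' @param genes gene table with `chrom`, `start`, `end`, optional `strand`,
#'   and the splitting column.
#' @param split_by name of the splitting column in `genes`.
#' @param flank flank bp (default 2000).
#' @param body_bins meta-bins over the gene body (default 20).
#' @param flank_bins meta-bins per flank (default 10).
#' @param statistic passed to [metaprofile()].
#' @return named list of signal_profile, one per class level.
#' @export
insulation_over_genes <- function(track, genes, split_by, flank = 2000,
                                  body_bins = 20L, flank_bins = 10L,
                                  statistic = "median") {
  sig <- as.data.table(track)[!is.na(score),
                              .(chrom, start, end, value = score)]
  g <- as.data.table(genes)
  if (!split_by %in% names(g))
    stop("invalid parameter: genes lack column '", split_by, "'")
  out <- list()
  for (lev in sort(unique(as.character(g[[split_by]])))) {
    sel <- g[as.character(g[[split_by]]) == lev]
    if (nrow(sel) == 0L) {
      warning("class ", lev, " has zero genes; omitted")
      next
    }
    out[[lev]] <- metaprofile(sig, sel, body_bins = body_bins,
                              flank = flank, flank_bins = flank_bins,
                              statistic = statistic)
  }
  if (length(out) == 0L) warning("no non-empty classes")
  out
}
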