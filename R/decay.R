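#' Distance-decay profile of intra-chromosomal contacts
#'
#' Mean, standard deviation and pair count of the (balanced, if available)
#' contact value at every intra-chromosomal bin separation `d = 1..D`,
#' pooled over chromosomes.  Implicit zero pairs are counted: `n(d)` is the
#' number of possible non-masked intra-chromosomal pairs at separation `d`,
#' not the number of stored pixels.  Distances with `n(d) == 0` are omitted.
#'
#' @param m contact_matrix (balanced or raw; balanced values are used when
#'   present).
#' @return data.table with columns `d`, `mean`, `sd`, `n`; class
#'   `decay_profile`.
#' @export
decay_profile <- function(m) {
  bins <- m$bins
  masked <- if (!is.null(m$bias)) is.na(m$bias) else rep(FALSE, nrow(bins))
  # possible pair count per distance: for a chromosome with k usable bins at
  # positions p, count pairs |p_u - p_v| = d among non-masked bins
  per_chrom <- split(bins$pos[!masked], bins$chrom[!masked])
  max_d <- max(vapply(per_chrom, function(p)
    if (length(p) >= 2) diff(range(p)) else 0L, numeric(1)))
  if (max_d < 1) stop("degenerate input: no intra-chromosomal pairs")
  n_d <- numeric(max_d)
  for (p in per_chrom) {
    if (length(p) < 2) next
    dd <- tabulate(as.vector(dist(p)), nbins = max_d)
    n_d <- n_d + dd
  }
  px <- cm_values(m)
  px <- px[bins$chrom[i] == bins$chrom[j] & i != j]
  px[, d := bins$pos[j] - bins$pos[i]]
  sums <- px[, .(s = sum(value), ss = sum(value^2)), by = d]
  prof <- data.table(d = seq_len(max_d), n = n_d)
  prof <- sums[prof, on = "d"]
  prof[is.na(s), `:=`(s = 0, ss = 0)]
  prof <- prof[n >= 1]
  prof[, mean := s / n]
  prof[, sd := ifelse(n > 1, sqrt(pmax(0, (ss - n * mean^2) / (n - 1))), 0)]
  prof <- prof[, .(d, mean, sd, n)]
  setattr(prof, "class", c("decay_profile", class(prof)))
  prof[]
}

#' Fit a power-law exponent to a decay profile
#'
#' Ordinary least squares of `log(mean)` on `log(1 + d)`; returns the slope
#' (the decay exponent is its negation).
#' @param prof decay_profile.
#' @param d_max optional maximum distance used in the fit.
#' @return list(slope, intercept).
#' @export
fit_decay_exponent <- function(prof, d_max = Inf) {
  dt <- as.data.table(prof)[d <= d_max & mean > 0]
  fit <- lm(log(mean) ~ log(1 + d), data = dt)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}
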