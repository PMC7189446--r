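#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values: `q_(k) = min over m >= k of
#' p_(m) * n / m`, monotone non-decreasing in sorted order and `q >= p`
#' elementwise.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * n / (n - seq_len(n) + 1)))
  q[ro]
}

# shared engine: score candidate pairs against an expected value and filter
loop_filter <- function(cand, p_max, z_min, q_max) {
  cand[, z := (obs - expected) / sqrt(expected)]
  cand[, p := ppois(obs - 1, expected, lower.tail = FALSE)]
  cand[, q := bh_fdr(p)]
  n_tested <- nrow(cand)
  loops <- cand[p < p_max & z > z_min & q < q_max]
  list(loops = loops, n_tested = n_tested)
}

#' Call significant intra-chromosomal loops
#'
#' Tests every intra-chromosomal bin pair at separation
#' `>= min_distance_bins` (and `<= max_distance`, if finite) against a
#' coverage-corrected distance-decay expectation:
#' `expected(i, j) = decay_mean(d_ij) * cov_i * cov_j / mean_cov^2`,
#' where `decay_mean` is the genome-wide mean contact at that separation
#' and `cov` the per-bin marginal coverage.  The score is
#' `z = (obs - exp) / sqrt(exp)`, the p-value the upper Poisson tail
#' `P(X >= obs)`, and q the BH adjustment over all tested intra pairs at
#' this resolution.  Loops are the pairs with `p < p_max`, `z > z_min`
#' and `q < q_max`.  Pairs with zero expected (masked or uncovered bins)
#' are skipped.
#'
#' @param m raw contact_matrix at the calling resolution (use [coarsen()]
#'   first if needed).
#' @param p_max,z_min,q_max thresholds (defaults 0.05, 1.5, 0.1).
#' @param min_distance_bins minimum anchor separation in bins (default 2,
#'   excluding the diagonal and adjacent bins).
#' @param max_distance maximum anchor separation in bp (default Inf).
#' @return object of class `loop_set`: list with `loops` (data.table:
#'   chrom1, start1, end1, chrom2, start2, end2, i, j, obs, expected, z, p,
#'   q, kind), `kind`, `resolution`, `thresholds`, `n_tested`.
#' @export
call_loops_intra <- function(m, p_max = 0.05, z_min = 1.5, q_max = 0.1,
                             min_distance_bins = 2L, max_distance = Inf) {
  bins <- m$bins
  cov <- cm_marginals(m, balanced = FALSE)
  usable <- cov > 0 & !(if (!is.null(m$bias)) is.na(m$bias) else FALSE)
  prof <- decay_profile(m)
  dmean <- numeric(max(prof$d)); dmean[prof$d] <- prof$mean
  max_d_bins <- if (is.finite(max_distance))
    as.integer(max_distance / m$layout$bin_size) else Inf

  cand <- bins[, {
    u <- idx[usable[idx]]
    if (length(u) >= 2) {
      cj <- CJ(a = seq_along(u), b = seq_along(u))[a < b]
      cj[, `:=`(i = u[a], j = u[b])]
      cj[, d := bins$pos[j] - bins$pos[i]]
      cj[d >= min_distance_bins & d <= max_d_bins, .(i, j, d)]
    } else data.table(i = integer(), j = integer(), d = integer())
  }, by = .(chrom)]
  if (nrow(cand) == 0L)
    return(empty_loop_set("intra", m, p_max, z_min, q_max))
  mean_cov <- mean(cov[usable])
  cand[, expected := ifelse(d <= length(dmean), dmean[pmin(d, length(dmean))],
                            0) * cov[i] * cov[j] / mean_cov^2]
  cand <- cand[expected > 0]
  obs_tab <- m$pixels
  cand <- obs_tab[cand, on = c("i", "j")]
  cand[is.na(count), count := 0]
  setnames(cand, "count", "obs")
  res <- loop_filter(cand, p_max, z_min, q_max)
  finish_loop_set(res, "intra", m, p_max, z_min, q_max)
}

#' Call significant interchromosomal interactions
#'
#' Tests every inter-chromosomal bin pair against the coverage-product
#' expectation `expected(i, j) = 2 * cov_i * cov_j / T` (T = total matrix
#' counts; the factor 2 reflects unordered-pair counting), with the same
#' z / Poisson-p / BH-q filters as [call_loops_intra()], pooled over all
#' tested inter pairs.
#'
#' @inheritParams call_loops_intra
#' @return a `loop_set` with kind "inter"; empty with a warning on a
#'   single-chromosome layout.
#' @export
call_interactions_inter <- function(m, p_max = 0.05, z_min = 1.5,
                                    q_max = 0.1) {
  bins <- m$bins
  if (length(unique(bins$chrom)) < 2L) {
    warning("single-chromosome layout: no interchromosomal pairs")
    return(empty_loop_set("inter", m, p_max, z_min, q_max))
  }
  cov <- cm_marginals(m, balanced = FALSE)
  usable <- cov > 0 & !(if (!is.null(m$bias)) is.na(m$bias) else FALSE)
  total <- sum(m$pixels$count)
  u <- which(usable)
  cand <- CJ(i = u, j = u)[i < j][bins$chrom[i] != bins$chrom[j]]
  cand[, expected := 2 * cov[i] * cov[j] / total]
  cand <- cand[expected > 0]
  cand <- m$pixels[cand, on = c("i", "j")]
  cand[is.na(count), count := 0]
  setnames(cand, "count", "obs")
  res <- loop_filter(cand, p_max, z_min, q_max)
  finish_loop_set(res, "inter", m, p_max, z_min, q_max)
}

empty_loop_set <- function(kind, m, p_max, z_min, q_max) {
  structure(list(
    loops = data.table(chrom1 = character(), start1 = numeric(),
                       end1 = numeric(), chrom2 = character(),
                       start2 = numeric(), end2 = numeric(),
                       i = integer(), j = integer(), obs = numeric(),
                       expected = numeric(), z = numeric(), p = numeric(),
                       q = numeric(), kind = character()),
    kind = kind, resolution = m$layout$bin_size,
    thresholds = list(p = p_max, z = z_min, q = q_max), n_tested = 0L),
    class = "loop_set")
}

finish_loop_set <- function(res, kind, m, p_max, z_min, q_max) {
  bins <- m$bins
  lp <- res$loops
  lp[, `:=`(chrom1 = bins$chrom[i], start1 = bins$start[i],
            end1 = bins$end[i], chrom2 = bins$chrom[j],
            start2 = bins$start[j], end2 = bins$end[j], kind = kind)]
  out <- lp[, .(chrom1, start1, end1, chrom2, start2, end2, i, j, obs,
                expected, z, p, q, kind)]
  setorder(out, chrom1, start1, chrom2, start2)
  structure(list(loops = out, kind = kind,
                 resolution = m$layout$bin_size,
                 thresholds = list(p = p_max, z = z_min, q = q_max),
                 n_tested = res$n_tested),
            class = "loop_set")
}

#' @export
print.loop_set <- function(x, ...) {
  cat(sprintf(
    "loop_set (%s): %d loops of %d tested pairs at %s bp (p<%g, z>%g, q<%g)\n",
    x$kind, nrow(x$loops), x$n_tested,
    format(x$resolution, big.mark = ","), x$thresholds$p, x$thresholds$z,
    x$thresholds$q))
  invisible(x)
}

#' Loops conserved between two conditions
#'
#' Keeps the loops of `set_a` whose two anchors both overlap (by at least
#' 1 bp) the corresponding anchors of some loop in `set_b`; anchor pairs
#' are matched in canonical order (anchor1 is the genomically lower
#' anchor in both sets).  Works across resolutions: overlap is evaluated
#' on the interval level, so an anchor at 20 kb matches a containing 40-kb
#' anchor.  The matched loop's z in condition B is attached as `z_b` (the
#' maximum over multiple matches).
#'
#' @param set_a,set_b loop_set objects.
#' @return a `loop_set` like `set_a` with a `z_b` column.
#' @export
conserved_loops <- function(set_a, set_b) {
  a <- copy(set_a$loops); b <- set_b$loops
  if (nrow(a) == 0L || nrow(b) == 0L) {
    out <- set_a
    out$loops <- a[0][, z_b := numeric(0)]
    return(out)
  }
  ov <- function(c1, s1, e1, c2, s2, e2) {
    # returns data.table(ai, bi) of overlapping anchor pairs
    ga <- GenomicRanges::GRanges(c1, IRanges::IRanges(s1 + 1, e1))
    gb <- GenomicRanges::GRanges(c2, IRanges::IRanges(s2 + 1, e2))
    h <- suppressWarnings(GenomicRanges::findOverlaps(ga, gb))
    data.table(ai = S4Vectors::queryHits(h), bi = S4Vectors::subjectHits(h))
  }
  h1 <- ov(a$chrom1, a$start1, a$end1, b$chrom1, b$start1, b$end1)
  h2 <- ov(a$chrom2, a$start2, a$end2, b$chrom2, b$start2, b$end2)
  both <- merge(h1, h2, by = c("ai", "bi"))
  if (nrow(both) == 0L) {
    out <- set_a
    out$loops <- a[0][, z_b := numeric(0)]
    return(out)
  }
  both[, z_b := b$z[bi]]
  zb <- both[, .(z_b = max(z_b)), by = ai]
  a[, z_b := NA_real_]
  a[zb$ai, z_b := zb$z_b]
  out <- set_a
  out$loops <- a[!is.na(z_b)]
  out
}
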