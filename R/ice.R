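#' ICE iterative balancing
#'
#' Iterative correction of a raw contact matrix so that every usable bin has
#' the same visibility (uniform marginals).  Each iteration divides every
#' pair value by the product of its two bins' current marginal sums rescaled
#' to mean 1, until the coefficient of variation (CV) of the non-masked
#' marginals drops below `tol` or `max_iter` is reached.  Low-coverage bins
#' (the lowest `mask_fraction` of bins by raw coverage, plus all
#' zero-coverage bins) are masked: their bias is NA and their pair values
#' are treated as missing downstream.
#'
#' The accumulated bias vector satisfies
#' `balanced(i, j) == raw(i, j) / (bias_i * bias_j)` exactly; biases are
#' rescaled at the end so the non-masked balanced marginals have mean equal
#' to the mean raw non-masked marginal (matrix mass preserved up to the
#' masked bins).
#'
#' @param m raw contact_matrix.
#' @param max_iter maximum number of iterations (default 200).
#' @param tol convergence threshold on the marginal CV (default 1e-5).
#' @param mask_fraction fraction of lowest-coverage bins to mask
#'   (default 0.02).
#' @return balanced contact_matrix; attributes `ice_iterations` and
#'   `ice_cv_trace` (CV before each iteration and at exit) record the run.
#' @export
ice_normalize <- function(m, max_iter = 200L, tol = 1e-5,
                          mask_fraction = 0.02) {
  if (m$balanced) stop("matrix is already balanced")
  n <- nrow(m$bins)
  cov <- cm_marginals(m, balanced = FALSE)
  masked <- cov == 0
  n_low <- floor(mask_fraction * n)
  if (n_low > 0) {
    ord <- order(cov)
    masked[ord[seq_len(n_low)]] <- TRUE
  }
  keep <- which(!masked)
  if (length(keep) == 0L) stop("degenerate input: all bins masked")

  px <- m$pixels[!(i %in% which(masked)) & !(j %in% which(masked))]
  work <- px$count
  bias <- rep(1, n)
  cv_trace <- numeric(0)
  iters <- 0L
  marg_of <- function(v) {
    mm <- numeric(n)
    s1 <- rowsum(v, px$i)
    mm[as.integer(rownames(s1))] <- s1[, 1L]
    off <- px$i != px$j
    if (any(off)) {
      s2 <- rowsum(v[off], px$j[off])
      mm[as.integer(rownames(s2))] <- mm[as.integer(rownames(s2))] + s2[, 1L]
    }
    mm
  }
  repeat {
    marg <- marg_of(work)[keep]
    cv <- sd(marg) / mean(marg)
    cv_trace <- c(cv_trace, cv)
    if (is.na(cv) || cv < tol || iters >= max_iter) break
    iters <- iters + 1L
    s <- numeric(n)
    s[keep] <- marg / mean(marg)
    bias <- bias * ifelse(s > 0, s, 1)
    work <- work / (s[px$i] * s[px$j])
  }
  # rescale so the mean balanced marginal equals the mean raw marginal
  raw_mean <- mean(cm_marginals(m, balanced = FALSE)[keep])
  bal_marg <- marg_of(m$pixels[
    !(i %in% which(masked)) & !(j %in% which(masked)),
    count / (bias[i] * bias[j])])[keep]
  scale <- sqrt(mean(bal_marg) / raw_mean)
  bias[keep] <- bias[keep] * scale
  bias[masked] <- NA_real_
  out <- m
  out$balanced <- TRUE
  out$bias <- bias
  attr(out, "ice_iterations") <- iters
  attr(out, "ice_cv_trace") <- cv_trace
  out
}
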