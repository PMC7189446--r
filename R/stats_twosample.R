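#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with `U = sum over (x_i, y_j) of [x > y] +
#' 0.5 * [x == y]`.  For `n1 + n2 <= 12` (or `method = "exact"`) the
#' p-value is computed by exact enumeration of all `choose(n1+n2, n1)`
#' labelings of the pooled sample (ties handled naturally by the half-count
#' convention): `p = min(1, 2 * min(P(U <= u), P(U >= u)))`.  Larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param method "auto" (default), "exact" or "normal".
#' @return list(U, p, n1, n2, method).
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("invalid input: empty sample")
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy) {
    cmp <- outer(xx, yy, ">") + 0.5 * outer(xx, yy, "==")
    sum(cmp)
  }
  u <- u_stat(x, y)
  use_exact <- method == "exact" || (method == "auto" && n1 + n2 <= 12L)
  if (use_exact) {
    pool <- c(x, y)
    labs <- combn(n1 + n2, n1)
    us <- apply(labs, 2L, function(ix) u_stat(pool[ix], pool[-ix]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
    meth <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    mu <- n1 * n2 / 2
    zc <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(zc)))
    meth <- "normal"
  }
  list(U = u, p = p, n1 = n1, n2 = n2, method = meth)
}

#' Cliff's Delta effect size
#'
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (n1 * n2)`, computed exactly;
#' ties contribute zero.  `delta` lies in `[-1, 1]`; on tie-free data it
#' satisfies `delta = 2 U / (n1 n2) - 1` with U from [mann_whitney_u()].
#'
#' @param x,y numeric samples (non-empty).
#' @return delta.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("invalid input: empty sample")
  gt <- sum(outer(x, y, ">"))
  lt <- sum(outer(x, y, "<"))
  (gt - lt) / (length(x) * length(y))
}

#' Homeolog vs non-homeolog two-sample report
#'
#' Compares the normalized interaction frequency of homeolog and
#' non-homeolog inter-subgenome super-bin pairs.
#'
#' @param tab output of [classify_and_aggregate()].
#' @return list(U, p, cliffs_delta, n1, n2) with sample 1 = homeolog pairs.
#' @export
homeolog_test <- function(tab) {
  hx <- tab[homeolog %in% TRUE]$cpm
  hy <- tab[homeolog %in% FALSE]$cpm
  mw <- mann_whitney_u(hx, hy)
  list(U = mw$U, p = mw$p, cliffs_delta = cliffs_delta(hx, hy),
       n1 = mw$n1, n2 = mw$n2)
}
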