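#' Select differentially expressed gene pairs on conserved loops
#'
#' Keeps the pairs whose loop is conserved across the two conditions (has a
#' `z_b` value) and whose two genes are both differentially expressed
#' (`de_pvalue < p_max`).  Fold changes and DE p-values are taken from
#' `de_table` (gene_id, log2fc, de_pvalue) when supplied, otherwise from
#' the `log2fc_*` / `de_pvalue_*` columns carried by the pair table.
#' Pairs with a missing fold change are dropped; their number is reported
#' in the `n_dropped_missing_lfc` attribute (with a warning).
#'
#' @param pairs gene-pair table from [annotate_anchors()].
#' @param de_table optional data.table(gene_id, log2fc, de_pvalue).
#' @param p_max DE p-value threshold (default 0.01).
#' @param require_conserved drop pairs without `z_b` (default TRUE).
#' @return filtered pair table with `log2fc_1` / `log2fc_2` set.
#' @export
select_de_pairs <- function(pairs, de_table = NULL, p_max = 0.01,
                            require_conserved = TRUE) {
  pr <- copy(as.data.table(pairs))
  if (!is.null(de_table)) {
    de <- as.data.table(de_table)
    idx1 <- match(pr$gene1, de$gene_id)
    idx2 <- match(pr$gene2, de$gene_id)
    pr[, `:=`(log2fc_1 = de$log2fc[idx1], log2fc_2 = de$log2fc[idx2],
              de_pvalue_1 = de$de_pvalue[idx1],
              de_pvalue_2 = de$de_pvalue[idx2])]
  }
  need <- c("log2fc_1", "log2fc_2", "de_pvalue_1", "de_pvalue_2")
  if (!all(need %in% names(pr)))
    stop("invalid input: pairs lack DE columns and no de_table given")
  if (require_conserved) {
    if (!"z_b" %in% names(pr)) pr[, z_b := NA_real_]
    pr <- pr[!is.na(z_b)]
  }
  pr <- pr[!is.na(de_pvalue_1) & !is.na(de_pvalue_2) &
             de_pvalue_1 < p_max & de_pvalue_2 < p_max]
  miss <- is.na(pr$log2fc_1) | is.na(pr$log2fc_2)
  if (any(miss))
    warning(sum(miss), " DE pair(s) dropped for missing log2FC")
  pr <- pr[!miss]
  setattr(pr, "n_dropped_missing_lfc", sum(miss))
  pr[]
}

#' Regression of partner log2 fold changes
#'
#' Ordinary least squares of the second gene's log2 fold change on the
#' first gene's (`log2fc_2 ~ log2fc_1`): slope, intercept, R-squared and
#' the F-test p-value on (1, n - 2) degrees of freedom.
#'
#' @param pairs pair table with `log2fc_1`, `log2fc_2` (n >= 3).
#' @param stratum optional stratum label to attach.
#' @return one-row data.table(stratum, n_pairs, slope, intercept,
#'   r_squared, f_pvalue).
#' @export
regress_pair_logfc <- function(pairs, stratum = "all") {
  pr <- as.data.table(pairs)
  if (nrow(pr) < 3L) stop("invalid input: need >= 3 pairs")
  x <- pr$log2fc_1; y <- pr$log2fc_2
  if (var(x) == 0) stop("degenerate input: zero variance in predictor")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  data.table(stratum = stratum, n_pairs = nrow(pr),
             slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             r_squared = sm$r.squared,
             f_pvalue = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                                  lower.tail = FALSE)))
}

#' Stratified partner-fold-change regressions
#'
#' `strat = "strength"`: loop-strength quantiles of `z` (condition A) and
#' `z_b` (condition B) are computed independently and one regression is
#' fitted per quantile combination (cells with n < 3 reported with NA
#' fit).  `strat = "distance"`: one regression per distance quantile.
#'
#' @param pairs pair table (output of [select_de_pairs()]).
#' @param strat "strength" or "distance".
#' @param n_quantiles default 4 (quartiles).
#' @return data.table of fits; for strength, columns `q_a`, `q_b`.
#' @export
stratified_regression <- function(pairs, strat = c("strength", "distance"),
                                  n_quantiles = 4L) {
  strat <- match.arg(strat)
  pr <- copy(as.data.table(pairs))
  empty_fit <- data.table(n_pairs = NA_integer_, slope = NA_real_,
                          intercept = NA_real_, r_squared = NA_real_,
                          f_pvalue = NA_real_)
  fit_or_na <- function(p, label) {
    if (nrow(p) >= 3L && var(p$log2fc_1) > 0)
      regress_pair_logfc(p, label)
    else cbind(data.table(stratum = label), empty_fit)[
      , .(stratum, n_pairs = nrow(p), slope, intercept, r_squared,
          f_pvalue)]
  }
  if (strat == "strength") {
    if (!all(c("z", "z_b") %in% names(pr)))
      stop("invalid input: strength stratification needs z and z_b")
    pr[, qa := quantile_rank(z, n_quantiles)]
    pr[, qb := quantile_rank(z_b, n_quantiles)]
    grid <- CJ(q_a = seq_len(n_quantiles), q_b = seq_len(n_quantiles))
    out <- grid[, fit_or_na(pr[qa == q_a & qb == q_b],
                            sprintf("z%d/z%d", q_a, q_b)),
                by = .(q_a, q_b)]
  } else {
    if (!"distance" %in% names(pr))
      stop("invalid input: distance stratification needs a distance column")
    pr <- pr[!is.na(distance)]
    pr[, qa := quantile_rank(distance, n_quantiles)]
    out <- data.table(q_a = seq_len(n_quantiles))[
      , fit_or_na(pr[qa == q_a], sprintf("d%d", q_a)), by = q_a]
  }
  out[]
}
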