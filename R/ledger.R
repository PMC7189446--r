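#' Join loop anchors to genes: the gene-pair table
#'
#' Annotates the two anchors of every loop with overlapping genes (any
#' overlap, >= 1 bp), drops loops with a gene-less anchor, and emits every
#' (gene-in-anchor1, gene-in-anchor2) combination as a pair; pairs mapping
#' both anchors to the same gene are dropped.  Intra-chromosomal pairs are
#' oriented genomically (gene1 upstream); inter-chromosomal pairs by
#' chromosome name order, then start.  Gene attribute columns listed in
#' `carry` are copied per gene with suffixes `_1` / `_2` at join time.
#'
#' @param loop_set a `loop_set` (or its `loops` data.table).
#' @param genes gene table with `gene_id`, `chrom`, `start`, `end` and any
#'   attribute columns.
#' @param carry character vector of gene columns to copy (default: all
#'   logical columns plus `tpm_a`, `tpm_b`, `expressed`, `log2fc`,
#'   `de_pvalue` when present).
#' @return data.table, one row per gene pair: `loop_id`, `kind`, `z`
#'   (and `z_b` if present), `chrom1`, `chrom2`, `gene1`, `gene2`,
#'   `distance` (bp between gene midpoints, NA for inter pairs), carried
#'   attributes.
#' @export
annotate_anchors <- function(loop_set, genes, carry = NULL) {
  loops <- if (inherits(loop_set, "loop_set")) loop_set$loops else
    as.data.table(loop_set)
  g <- as.data.table(genes)
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(g)))
    stop("format error: genes need gene_id, chrom, start, end")
  if (nrow(loops) == 0L) return(data.table())
  if (is.null(carry)) {
    logi <- names(g)[vapply(g, is.logical, logical(1))]
    carry <- intersect(c(logi, "tpm_a", "tpm_b", "expressed", "log2fc",
                         "de_pvalue"), names(g))
    carry <- unique(carry)
  }
  loops <- copy(loops)[, loop_id := .I]
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start + 1,
                                                           g$end))
  hit_anchor <- function(ch, s, e) {
    ga <- GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1, e))
    h <- GenomicRanges::findOverlaps(ga, gr_g)
    data.table(loop_id = S4Vectors::queryHits(h),
               gi = S4Vectors::subjectHits(h))
  }
  h1 <- hit_anchor(loops$chrom1, loops$start1, loops$end1)
  h2 <- hit_anchor(loops$chrom2, loops$start2, loops$end2)
  pairs <- merge(h1, h2, by = "loop_id", allow.cartesian = TRUE,
                 suffixes = c("1", "2"))
  pairs <- pairs[gi1 != gi2]
  if (nrow(pairs) == 0L) return(data.table())
  keep <- c("loop_id", "kind", "z", if ("z_b" %in% names(loops)) "z_b")
  out <- loops[, ..keep][pairs, on = "loop_id"]
  # orient: intra genomically, inter lexicographically
  c1 <- g$chrom[out$gi1]; c2 <- g$chrom[out$gi2]
  s1 <- g$start[out$gi1]; s2 <- g$start[out$gi2]
  swap <- (c1 == c2 & s1 > s2) | (c1 != c2 & c1 > c2)
  tmp <- out$gi1[swap]; out$gi1[swap] <- out$gi2[swap]; out$gi2[swap] <- tmp
  out[, `:=`(gene1 = g$gene_id[gi1], gene2 = g$gene_id[gi2],
             chrom1 = g$chrom[gi1], chrom2 = g$chrom[gi2])]
  mid <- (g$start + g$end) / 2
  out[, distance := ifelse(chrom1 == chrom2,
                           abs(mid[gi2] - mid[gi1]), NA_real_)]
  for (cn in carry) {
    set(out, j = paste0(cn, "_1"), value = g[[cn]][out$gi1])
    set(out, j = paste0(cn, "_2"), value = g[[cn]][out$gi2])
  }
  out[, c("gi1", "gi2") := NULL]
  unique(out, by = c("loop_id", "gene1", "gene2"))[]
}

#' 2x2 feature association between loop partner genes
#'
#' Counts pairs by (feature1 on gene1) x (feature2 on gene2) into the table
#' `[[a, b], [c, d]]` (a = both present, d = both absent), then computes
#' the odds ratio `ad / bc` (Haldane-Anscombe +0.5 on every cell iff any
#' cell is zero), its log2, the chi-square statistic without continuity
#' correction, its p-value, and Cramer's V `sqrt(chi2 / n)`.
#'
#' @param pairs gene-pair table from [annotate_anchors()] (or any table
#'   with `<feature>_1` / `<feature>_2` logical columns).
#' @param feature1,feature2 feature base names (e.g. "expressed",
#'   "H3K27me3").
#' @return list(a, b, c, d, odds_ratio, log2_or, chi2, p, cramers_v, n,
#'   haldane_applied).
#' @export
feature_association <- function(pairs, feature1, feature2 = feature1) {
  pr <- as.data.table(pairs)
  if (nrow(pr) == 0L) stop("invalid input: empty pair table")
  f1 <- pr[[paste0(feature1, "_1")]]
  f2 <- pr[[paste0(feature2, "_2")]]
  if (is.null(f1) || is.null(f2))
    stop("invalid parameter: unknown feature name")
  contingency_2x2(sum(f1 & f2), sum(f1 & !f2), sum(!f1 & f2), sum(!f1 & !f2))
}

#' @rdname feature_association
#' @param a,b,c,d cell counts (a = row1/col1).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n < 1) stop("invalid input: empty contingency table")
  haldane <- any(c(a, b, c, d) == 0)
  aa <- a; bb <- b; cc <- c; dd <- d
  if (haldane) { aa <- a + 0.5; bb <- b + 0.5; cc <- c + 0.5; dd <- d + 0.5 }
  or <- (aa * dd) / (bb * cc)
  tab <- matrix(c(a, c, b, d), 2L)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  chi2 <- unname(chi$statistic)
  v <- sqrt(chi2 / n)
  list(a = a, b = b, c = c, d = d, odds_ratio = or, log2_or = log2(or),
       chi2 = chi2, p = unname(chi$p.value), cramers_v = v, n = n,
       haldane_applied = haldane)
}

#' Feature-association ledger over all feature combinations
#'
#' Applies [feature_association()] to every ordered (feature on gene1,
#' feature on gene2) combination.  Two ledgers are returned: `raw`, using
#' the pairs as oriented, and `symmetrized`, where every unordered pair
#' contributes both orientations (the pair table is pooled with its
#' gene-swapped copy), making the ledger symmetric in its two features.
#'
#' @param pairs gene-pair table.
#' @param features character vector of feature base names.
#' @return list(raw, symmetrized): data.tables with one row per feature
#'   combination (feature1, feature2, a, b, c, d, odds_ratio, log2_or,
#'   chi2, p, cramers_v, haldane_applied).
#' @export
association_matrix <- function(pairs, features) {
  if (length(features) < 1L) stop("invalid parameter: need >= 1 feature")
  pr <- as.data.table(pairs)
  for (f in features)
    if (is.null(pr[[paste0(f, "_1")]]) || is.null(pr[[paste0(f, "_2")]]))
      stop("invalid parameter: unknown feature name '", f, "'")
  swap_pairs <- function(p) {
    sw <- copy(p)
    for (f in features) {
      c1 <- paste0(f, "_1"); c2 <- paste0(f, "_2")
      tmp <- sw[[c1]]
      set(sw, j = c1, value = sw[[c2]])
      set(sw, j = c2, value = tmp)
    }
    sw
  }
  ledger_of <- function(p) {
    rbindlist(lapply(features, function(fa) rbindlist(lapply(features,
      function(fb) {
        r <- feature_association(p, fa, fb)
        data.table(feature1 = fa, feature2 = fb, a = r$a, b = r$b, c = r$c,
                   d = r$d, odds_ratio = r$odds_ratio, log2_or = r$log2_or,
                   chi2 = r$chi2, p = r$p, cramers_v = r$cramers_v,
                   haldane_applied = r$haldane_applied)
      }))))
  }
  list(raw = ledger_of(pr),
       symmetrized = ledger_of(rbind(pr, swap_pairs(pr))))
}

# left-closed quantile rank: ties share the lower quantile
quantile_rank <- function(x, k) {
  r <- rank(x, ties.method = "min")
  pmin(k, as.integer(floor((r - 1) * k / length(x))) + 1L)
}

#' Expression-quantile concordance of loop partners
#'
#' Restricts the pair table to pairs expressed on both sides (TPM > 0),
#' splits gene1 and gene2 TPM independently into `n_quantiles` quantiles
#' (left-closed; ties to the lower quantile), and counts pairs per quantile
#' combination.  The diagonal mass fraction summarises concordance.
#'
#' @param pairs gene-pair table with `tpm_a_1` / `tpm_a_2` columns (or
#'   columns named by `tpm_cols`).
#' @param n_quantiles 4 for loop quartiles, 10 for interchromosomal deciles.
#' @param tpm_cols length-2 character vector of the two TPM columns.
#' @return list(counts = n_quantiles x n_quantiles matrix (rows = gene1
#'   quantile), diagonal_fraction, n).
#' @export
expression_concordance <- function(pairs, n_quantiles = 4L,
                                   tpm_cols = c("tpm_a_1", "tpm_a_2")) {
  pr <- as.data.table(pairs)
  t1 <- pr[[tpm_cols[1L]]]; t2 <- pr[[tpm_cols[2L]]]
  if (is.null(t1) || is.null(t2))
    stop("invalid parameter: TPM columns not found")
  keep <- t1 > 0 & t2 > 0
  t1 <- t1[keep]; t2 <- t2[keep]
  if (length(t1) < n_quantiles)
    stop("invalid input: fewer expressed pairs than quantiles")
  if (length(unique(t1)) == 1L || length(unique(t2)) == 1L)
    stop("degenerate quantiles: all TPM identical")
  q1 <- quantile_rank(t1, n_quantiles)
  q2 <- quantile_rank(t2, n_quantiles)
  counts <- matrix(0L, n_quantiles, n_quantiles)
  tb <- data.table(q1, q2)[, .N, by = .(q1, q2)]
  counts[cbind(tb$q1, tb$q2)] <- tb$N
  list(counts = counts,
       diagonal_fraction = sum(diag(counts)) / sum(counts),
       n = length(t1))
}

#' Partner counts of loop-joined genes
#'
#' Number of distinct partner genes per gene over a pair table (duplicate
#' pairs count once), plus the fractions of genes with >= 4 and >= 10
#' partners.
#'
#' @param pairs gene-pair table with `gene1`, `gene2`.
#' @return list(counts = data.table(gene_id, n_partners),
#'   frac_ge4, frac_ge10, n_genes).
#' @export
partner_counts <- function(pairs) {
  pr <- as.data.table(pairs)
  if (nrow(pr) == 0L) stop("invalid input: empty pair table")
  e <- unique(rbind(pr[, .(a = gene1, b = gene2)],
                    pr[, .(a = gene2, b = gene1)]))
  cnt <- e[, .(n_partners = uniqueN(b)), by = .(gene_id = a)]
  setorder(cnt, -n_partners, gene_id)
  list(counts = cnt,
       frac_ge4 = mean(cnt$n_partners >= 4),
       frac_ge10 = mean(cnt$n_partners >= 10),
       n_genes = nrow(cnt))
}

#' Read a deposited gene-pair table
#'
#' Ingests an externally produced loop/gene-pair TSV (for example a
#' supplementary pair table) into the package's pair schema.  `mapping`
#' renames source columns to package names; by default columns are taken
#' as already named like [annotate_anchors()] output.  Mark/status columns
#' coded 0/1 are converted to logical.
#'
#' @param path TSV file.
#' @param mapping named character vector `c(package_name = source_name)`.
#' @return gene-pair data.table.
#' @export
read_pair_table <- function(path, mapping = NULL) {
  dt <- fread(path, sep = "\t")
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(dt))
    if (length(missing_src))
      stop("format error: source columns not found: ",
           paste(missing_src, collapse = ", "))
    setnames(dt, unname(mapping), names(mapping))
  }
  if (!all(c("gene1", "gene2") %in% names(dt)))
    stop("format error: pair table needs gene1 and gene2 columns")
  for (cn in names(dt))
    if (grepl("_[12]$", cn) && is.numeric(dt[[cn]]) &&
        all(dt[[cn]] %in% c(0, 1)))
      set(dt, j = cn, value = as.logical(dt[[cn]]))
  dt[]
}
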