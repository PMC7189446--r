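#' Simulate genes, chromatin marks and two-condition expression
#'
#' Places genes on the simulated genome so that every planted-domain
#' boundary bin and every planted-loop anchor bin hosts a gene (bins inside
#' condensed domains are gene-poor, the rest intermediate), assigns
#' chromatin marks (H3K9ac, H3K36me3, H3K27me3, RNAPII, ATAC) conditional on
#' an active/repressed state, draws log-normal TPM for expressed genes over
#' two conditions x three replicates, and couples the log2 fold changes of
#' loop-partner genes: `lfc2 = beta * lfc1 + eps`,
#' `eps ~ N(0, pair_logfc_noise_sd)`, with `beta` per planted loop.
#' Coupled genes receive the configured differential-expression p-value
#' (default 1e-4); uncoupled genes get p = 1.  Partner genes copy each
#' other's mark set with probability `mark_concordance`, and their log-TPMs
#' are correlated with `tpm_pair_rho`.
#'
#' @param layout a [genome_layout()].
#' @param truth sim_truth from [simulate_contacts()] (updated in place with
#'   `gene_pair_couplings` and returned).
#' @param params the same [sim_params()].
#' @return list(genes = data.table (one row per gene), truth = updated
#'   sim_truth).  Expression columns: `tpm_a_r1..r3`, `tpm_b_r1..r3`,
#'   `tpm_a`, `tpm_b` (medians), `expressed` (median TPM of condition a
#'   > 0), `log2fc` (a vs b), `de_pvalue`.
#' @export
simulate_genes_and_expression <- function(layout, truth, params) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  set.seed(params$seed + 500009L)  # separate stream from the matrix draws
  bins <- bin_table(layout)
  n <- nrow(bins)
  doms <- truth$planted_domains
  in_dom <- rep(FALSE, n)
  if (nrow(doms)) {
    dl <- doms[, .(pos = seq(start_bin, end_bin)),
               by = .(chrom, start_bin)][, .(chrom, pos)]
    in_dom[bins[dl, on = c("chrom", "pos")]$idx] <- TRUE
  }
  boundary <- rep(FALSE, n)
  if (nrow(truth$boundaries)) {
    hit <- bins[truth$boundaries[, .(chrom, pos = bin)],
                on = c("chrom", "pos")]
    boundary[hit$idx] <- TRUE
  }
  anchor <- rep(FALSE, n)
  lp <- truth$planted_loops
  if (nrow(lp)) anchor[c(lp$i, lp$j)] <- TRUE

  pgene <- ifelse(anchor, 1,
           ifelse(boundary, params$boundary_gene_prob,
           ifelse(in_dom, params$domain_gene_prob, params$other_gene_prob)))
  has_gene <- runif(n) < pgene
  gbin <- which(has_gene)
  ng <- length(gbin)
  if (ng == 0L) stop("generation error: no genes placed")
  bs <- layout$bin_size
  genes <- data.table(
    gene_id = sprintf("G%05d", seq_len(ng)),
    chrom = bins$chrom[gbin],
    start = bins$start[gbin] + round(0.2 * bs),
    end = bins$start[gbin] + round(0.8 * bs),
    strand = sample(c("+", "-"), ng, replace = TRUE),
    bin = gbin)
  genes[, end := pmin(end, bins$end[gbin])]

  gene_at <- integer(n); gene_at[gbin] <- seq_len(ng)

  active <- runif(ng) < params$p_active
  draw_marks <- function(act) {
    k <- length(act)
    data.table(
      H3K9ac = runif(k) < ifelse(act, 0.85, 0.05),
      H3K36me3 = runif(k) < ifelse(act, 0.85, 0.05),
      H3K27me3 = runif(k) < ifelse(act, 0.05, 0.85),
      RNAPII = runif(k) < ifelse(act, 0.90, 0.05),
      ATAC = runif(k) < ifelse(act, 0.70, 0.10))
  }
  marks <- draw_marks(active)

  # base expression and fold change
  log_tpm <- rnorm(ng, params$tpm_meanlog, params$tpm_sdlog)
  lfc <- rnorm(ng, 0, params$logfc_sd)
  de_p <- rep(1, ng)

  couplings <- NULL
  if (nrow(lp)) {
    g1 <- gene_at[lp$i]; g2 <- gene_at[lp$j]
    stopifnot(all(g1 > 0), all(g2 > 0))
    # partner copies the mate's state/marks with prob mark_concordance
    copy <- runif(nrow(lp)) < params$mark_concordance
    active[g2[copy]] <- active[g1[copy]]
    for (cn in names(marks))
      set(marks, i = g2[copy], j = cn, value = marks[[cn]][g1[copy]])
    # correlated log-TPM between partners
    rho <- params$tpm_pair_rho
    z <- rnorm(nrow(lp))
    log_tpm[g2] <- params$tpm_meanlog +
      rho * (log_tpm[g1] - params$tpm_meanlog) +
      sqrt(1 - rho^2) * params$tpm_sdlog * z
    # coupled fold changes
    lfc[g2] <- lp$beta * lfc[g1] +
      rnorm(nrow(lp), 0, params$pair_logfc_noise_sd)
    de_p[g1] <- params$de_pvalue_coupled
    de_p[g2] <- params$de_pvalue_coupled
    couplings <- data.table(loop_id = seq_len(nrow(lp)),
                            gene1 = genes$gene_id[g1],
                            gene2 = genes$gene_id[g2],
                            beta = lp$beta, fold = lp$fold)
  }

  tpm_a <- ifelse(active, exp(log_tpm), 0)
  tpm_b <- ifelse(active, tpm_a / 2^lfc, 0)
  for (r in 1:3) {
    genes[, paste0("tpm_a_r", r) := tpm_a * exp(rnorm(ng, 0, 0.1)) *
            as.numeric(active)]
    genes[, paste0("tpm_b_r", r) := tpm_b * exp(rnorm(ng, 0, 0.1)) *
            as.numeric(active)]
  }
  genes <- cbind(genes, marks)
  genes[, active := active]
  genes[, tpm_a := apply(as.matrix(.SD), 1L, median),
        .SDcols = paste0("tpm_a_r", 1:3)]
  genes[, tpm_b := apply(as.matrix(.SD), 1L, median),
        .SDcols = paste0("tpm_b_r", 1:3)]
  genes[, expressed := tpm_a > 0]
  genes[, log2fc := lfc]
  genes[, de_pvalue := de_p]

  truth$gene_pair_couplings <- couplings
  list(genes = genes[], truth = truth)
}

#' Simulate a protein-centric (Hi-ChIP-like) matrix from a Hi-C matrix
#'
#' Emulates chromatin-immunoprecipitation enrichment of contacts: bin pairs
#' whose two bins both contain an RNAPII-marked gene have their counts
#' multiplied by `occupancy_boost` and re-drawn from a Poisson; all other
#' pairs are binomially thinned by `thinning`.  Symmetry and non-negativity
#' are preserved.  With `occupancy_boost = 1` and `thinning = 1` the output
#' equals the input in expectation; with no RNAPII genes the output is a
#' uniformly thinned copy.
#'
#' @param m raw contact_matrix (integer counts).
#' @param genes gene table from [simulate_genes_and_expression()].
#' @param occupancy_boost multiplier >= 1 on RNAPII-RNAPII pairs.
#' @param thinning retention probability in (0, 1] for other pairs.
#' @param seed integer seed.
#' @return raw contact_matrix.
#' @export
simulate_hichip <- function(m, genes, occupancy_boost = 5, thinning = 0.5,
                            seed = 1L) {
  if (occupancy_boost < 1) stop("invalid parameter: occupancy_boost >= 1")
  if (thinning <= 0 || thinning > 1)
    stop("invalid parameter: thinning in (0, 1]")
  set.seed(as.integer(seed))
  pol_bins <- unique(genes[RNAPII == TRUE]$bin)
  px <- copy(m$pixels)
  hot <- px$i %in% pol_bins & px$j %in% pol_bins
  cnt <- px$count
  if (any(hot)) cnt[hot] <- rpois(sum(hot), px$count[hot] * occupancy_boost)
  if (thinning < 1 && any(!hot))
    cnt[!hot] <- rbinom(sum(!hot), size = as.integer(px$count[!hot]),
                        prob = thinning)
  px[, count := cnt]
  contact_matrix(m$layout, px[count > 0])
}

#' Generate coupled partner log2 fold changes
#'
#' Stand-alone generator for the coregulation model:
#' `lfc1 ~ N(0, logfc_sd)`, `lfc2 = beta * lfc1 + N(0, noise_sd)`.  When
#' `r_squared` is given instead of `noise_sd`, the noise is set to
#' `beta * logfc_sd * sqrt(1/r_squared - 1)` so the population R-squared of
#' the lfc2-on-lfc1 regression equals `r_squared`.
#'
#' @param n number of pairs.
#' @param beta coupling slope (scalar or length n).
#' @param noise_sd noise standard deviation (ignored if `r_squared` given).
#' @param r_squared target population R-squared.
#' @param logfc_sd sd of the predictor fold changes.
#' @param seed integer seed (NULL = use current RNG state).
#' @return data.table(lfc1, lfc2, beta).
#' @export
simulate_coupled_logfc <- function(n, beta, noise_sd = NULL,
                                   r_squared = NULL, logfc_sd = 1,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  beta <- rep_len(beta, n)
  if (!is.null(r_squared)) {
    if (r_squared <= 0 || r_squared >= 1)
      stop("invalid parameter: r_squared in (0, 1)")
    noise_sd <- abs(beta) * logfc_sd * sqrt(1 / r_squared - 1)
  } else noise_sd <- rep_len(noise_sd, n)
  lfc1 <- rnorm(n, 0, logfc_sd)
  lfc2 <- beta * lfc1 + rnorm(n, 0, noise_sd)
  data.table(lfc1 = lfc1, lfc2 = lfc2, beta = beta)
}
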