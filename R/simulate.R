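#' Simulation parameters for the synthetic polyploid generator
#'
#' Bundles every knob of the generative model with validated defaults.
#' Counts are Poisson draws around a deterministic expectation:
#'
#' * intra-chromosomal pair at bin separation d:
#'   `mu(d) = base_rate * f_intra * (1 + d)^(-decay_exponent)`,
#'   multiplied by `1/domain_depletion` when both bins lie in the same
#'   planted condensed domain, by `domain_depletion` when the pair straddles
#'   a planted domain edge, and by the loop fold on planted loop pairs;
#' * inter-chromosomal pair: `base_rate * f_class`
#'   (`f_subgenome` within a subgenome, `f_inter` across subgenomes),
#'   times `homeolog_factor` on homeologous chromosome pairs and
#'   `rabl_strength` on mirrored-position pairs (bin `i` against bin
#'   `N - 1 - i`, the anti-diagonal signature of the Rabl configuration).
#'
#' Planted domains are contact-enriched interiors (condensed spacers) whose
#' flanking boundary bins are contact-depleted, so the insulation caller can
#' recover them; `domain_depletion < 1` controls both sides with one knob.
#'
#' @param decay_exponent power-law decay exponent alpha (> 0).
#' @param base_rate expected counts per bin pair at distance 1 bin.
#' @param f_intra,f_subgenome,f_inter class enrichment factors,
#'   `f_intra >= f_subgenome >= f_inter > 0`.
#' @param homeolog_factor multiplier >= 1 on homeolog chromosome pairs.
#' @param rabl_strength multiplier >= 1 on mirrored-position inter pairs.
#' @param n_domains planted condensed domains per chromosome.
#' @param domain_depletion factor in (0, 1]; see above.
#' @param loop_rate number of planted intra-chromosomal loops (genome-wide).
#' @param loop_fold multiplier > 1 on planted loop pairs; scalar or one
#'   value per loop.
#' @param min_loop_distance minimum anchor separation of planted loops, in
#'   bins.
#' @param max_loop_distance maximum anchor separation of planted loops, in
#'   bins (Inf = unbounded); bounding it keeps the decay baseline at the
#'   loops within a chosen range.
#' @param boundary_gene_prob probability a domain-boundary bin hosts a gene.
#' @param domain_gene_prob gene probability for bins inside domains.
#' @param other_gene_prob gene probability for remaining bins.
#' @param mark_concordance probability a looped partner gene copies its
#'   mate's activity state.
#' @param p_active probability a (non-partner) gene is active/expressed.
#' @param tpm_meanlog,tpm_sdlog log-normal TPM parameters for expressed
#'   genes.
#' @param tpm_pair_rho correlation of log-TPM between looped partners.
#' @param logfc_sd standard deviation of gene log2 fold changes.
#' @param pair_logfc_slope coupling slope beta between partner log2 fold
#'   changes; scalar or one value per loop (strata).
#' @param pair_logfc_noise_sd sd of the coupling noise epsilon.
#' @param de_pvalue_coupled differential-expression p-value assigned to
#'   coupled genes (uncoupled genes get p = 1).
#' @param seed integer seed driving all randomness of a simulation.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(decay_exponent = 1,
                       base_rate = 50,
                       f_intra = 1,
                       f_subgenome = 0.2,
                       f_inter = 0.05,
                       homeolog_factor = 2,
                       rabl_strength = 1.5,
                       n_domains = 10,
                       domain_depletion = 0.3,
                       loop_rate = 30,
                       loop_fold = 5,
                       min_loop_distance = 5,
                       max_loop_distance = Inf,
                       boundary_gene_prob = 1,
                       domain_gene_prob = 0.05,
                       other_gene_prob = 0.4,
                       mark_concordance = 0.8,
                       p_active = 0.6,
                       tpm_meanlog = 3,
                       tpm_sdlog = 1.2,
                       tpm_pair_rho = 0.8,
                       logfc_sd = 1,
                       pair_logfc_slope = 0.483,
                       pair_logfc_noise_sd = 0.884,
                       de_pvalue_coupled = 1e-4,
                       seed = 1L) {
  p <- as.list(environment())
  if (p$decay_exponent <= 0 || p$base_rate <= 0)
    stop("invalid parameter: decay_exponent and base_rate must be > 0")
  if (!(p$f_intra >= p$f_subgenome && p$f_subgenome >= p$f_inter &&
        p$f_inter > 0))
    stop("invalid parameter: need f_intra >= f_subgenome >= f_inter > 0")
  if (p$homeolog_factor < 1 || p$rabl_strength < 1)
    stop("invalid parameter: homeolog_factor and rabl_strength must be >= 1")
  if (p$domain_depletion <= 0 || p$domain_depletion > 1)
    stop("invalid parameter: domain_depletion must be in (0, 1]")
  if (any(p$loop_fold <= 0))
    stop("invalid parameter: loop_fold must be > 0")
  for (nm in c("boundary_gene_prob", "domain_gene_prob", "other_gene_prob",
               "mark_concordance", "p_active", "tpm_pair_rho"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("invalid parameter: ", nm, " must be in [0, 1]")
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

# place n_domains non-overlapping domains on a chromosome of nbins bins,
# keeping `margin` free bins at each chromosome end and >= 2 free bins
# between domains so every domain has its own boundary bins.  Domains are
# at least `min_len` bins long so that interior bins have insulation
# windows dominated by within-domain pairs (min_len should be >=
# 2 * window_bins + 1 for the window the caller will use).
place_domains <- function(nbins, n_domains, margin, min_len = 9L) {
  if (n_domains == 0L) return(data.table(start_bin = integer(),
                                         end_bin = integer()))
  usable <- nbins - 2L * margin
  block <- usable %/% n_domains
  if (block < min_len + 2L)
    stop("generation error: chromosome too short for ", n_domains,
         " domains (need >= ", n_domains * (min_len + 2L) + 2L * margin,
         " bins)")
  out <- vector("list", n_domains)
  for (k in seq_len(n_domains)) {
    b0 <- margin + (k - 1L) * block          # 0-based block start
    # leave >= 1 free bin on each side of the domain inside its block
    max_len <- min(min_len + 5L, block - 2L)
    len <- sample(min_len:max_len, 1L)
    slack <- block - len - 2L
    off <- if (slack > 0) sample.int(slack + 1L, 1L) - 1L else 0L
    out[[k]] <- data.table(start_bin = b0 + 1L + off,
                           end_bin = b0 + off + len)
  }
  rbindlist(out)
}

#' Simulate a polyploid Hi-C contact matrix with planted structure
#'
#' Draws Poisson counts for every unordered bin pair around the expectation
#' described in [sim_params()], planting condensed domains, chromatin loops,
#' subgenome territories, a homeolog bonus and Rabl anti-diagonal signal.
#' The returned truth records everything planted, for recovery tests.
#'
#' @param layout a [genome_layout()].
#' @param params a [sim_params()].
#' @param truth optional truth from a previous call: reuse the same planted
#'   domains/loops and redraw counts only (a second condition / replicate).
#' @return list(matrix = contact_matrix, truth = sim_truth).  The truth is
#'   a list with `planted_domains` (chrom, start_bin, end_bin, start, end),
#'   `boundaries` (chrom, bin pos), `planted_loops` (i, j global indices,
#'   chrom, fold, beta), `homeolog_pairs`, and `params`.
#' @export
simulate_contacts <- function(layout, params, truth = NULL) {
  stopifnot(inherits(layout, "genome_layout"), inherits(params, "sim_params"))
  set.seed(params$seed)
  bins <- bin_table(layout)
  n <- nrow(bins)

  if (is.null(truth)) {
    w_margin <- 4L  # keep domains clear of chromosome ends
    doms <- bins[, {
      dd <- place_domains(nbins[1L], as.integer(params$n_domains), w_margin)
      dd
    }, by = chrom]
    bs <- layout$bin_size
    doms[, `:=`(start = start_bin * bs, end = (end_bin + 1L) * bs)]
    bounds <- rbind(doms[, .(chrom, bin = start_bin - 1L)],
                    doms[, .(chrom, bin = end_bin + 1L)])
    setorder(bounds, chrom, bin)

    # planted loops: intra-chromosomal bin pairs outside domains, separated
    # by >= min_loop_distance bins
    n_loops <- as.integer(params$loop_rate)
    loops <- NULL
    if (n_loops > 0L) {
      dom_bins <- if (nrow(doms))
        doms[, .(pos = seq(start_bin, end_bin)),
             by = .(chrom, start_bin)][, .(chrom, pos)]
      else data.table(chrom = character(), pos = integer())
      free <- bins[!dom_bins, on = c("chrom", "pos")]
      free <- free[!bounds[, .(chrom, pos = bin)], on = c("chrom", "pos")]
      cand <- free[, {
        if (.N >= 2) {
          a <- CJ(x = seq_len(.N), y = seq_len(.N))[x < y]
          a[, `:=`(i = idx[x], j = idx[y], d = pos[y] - pos[x])]
          a[d >= params$min_loop_distance & d <= params$max_loop_distance,
            .(i, j, d)]
        } else data.table(i = integer(), j = integer(), d = integer())
      }, by = chrom]
      if (nrow(cand) < n_loops)
        stop("generation error: not enough eligible bin pairs for ",
             n_loops, " loops")
      # greedy selection with distinct anchor bins, so every planted loop
      # couples its own gene pair
      ord <- sample.int(nrow(cand))
      used <- integer(0)
      keep <- integer(0)
      for (r in ord) {
        if (cand$i[r] %in% used || cand$j[r] %in% used) next
        keep <- c(keep, r)
        used <- c(used, cand$i[r], cand$j[r])
        if (length(keep) == n_loops) break
      }
      if (length(keep) < n_loops)
        stop("generation error: cannot place ", n_loops,
             " loops with distinct anchors")
      pick <- cand[keep]
      fold <- rep_len(params$loop_fold, n_loops)
      beta <- rep_len(params$pair_logfc_slope, n_loops)
      loops <- pick[, .(chrom, i, j, fold = fold, beta = beta)]
      setorder(loops, i, j)
    } else {
      loops <- data.table(chrom = character(), i = integer(), j = integer(),
                          fold = numeric(), beta = numeric())
    }
    hp <- CJ(a = seq_len(nrow(layout$chroms)), b = seq_len(nrow(layout$chroms)))[a < b]
    ch <- layout$chroms
    homeolog_pairs <- hp[ch$homeolog_group[a] == ch$homeolog_group[b] &
                           ch$subgenome[a] != ch$subgenome[b],
                         .(chrom1 = ch$name[a], chrom2 = ch$name[b])]
    truth <- structure(list(planted_domains = doms, boundaries = bounds,
                            planted_loops = loops,
                            homeolog_pairs = homeolog_pairs,
                            gene_pair_couplings = NULL,
                            params = params),
                       class = "sim_truth")
  } else {
    if (nrow(truth$planted_loops) &&
        max(truth$planted_loops$j) > n)
      stop("generation error: planted loop coordinates outside the genome")
  }

  # expectation over all unordered pairs
  pr <- CJ(i = seq_len(n), j = seq_len(n))[i <= j]
  pr[, `:=`(c1 = bins$chrom[i], c2 = bins$chrom[j],
            p1 = bins$pos[i], p2 = bins$pos[j],
            s1 = bins$subgenome[i], s2 = bins$subgenome[j],
            g1 = bins$homeolog_group[i], g2 = bins$homeolog_group[j],
            n2 = bins$nbins[j])]
  intra <- pr$c1 == pr$c2
  mu <- numeric(nrow(pr))
  mu[intra] <- params$base_rate * params$f_intra *
    (1 + (pr$p2[intra] - pr$p1[intra]))^(-params$decay_exponent)
  same_sub <- !intra & pr$s1 == pr$s2
  cross_sub <- !intra & pr$s1 != pr$s2
  mu[same_sub] <- params$base_rate * params$f_subgenome
  mu[cross_sub] <- params$base_rate * params$f_inter
  homeo <- cross_sub & pr$g1 == pr$g2
  mu[homeo] <- mu[homeo] * params$homeolog_factor
  mirror <- !intra & (pr$p2 == pr$n2 - 1L - pr$p1)
  mu[mirror] <- mu[mirror] * params$rabl_strength

  # domain modulation: bin -> domain id (0 = none)
  dom_id <- integer(n)
  doms <- truth$planted_domains
  if (nrow(doms)) {
    dl <- doms[, .(pos = seq(start_bin, end_bin), id = .GRP),
               by = .(chrom, start_bin)][, .(chrom, pos, id)]
    hit <- bins[dl, on = c("chrom", "pos")]
    dom_id[hit$idx] <- hit$id
  }
  d1 <- dom_id[pr$i]; d2 <- dom_id[pr$j]
  within_dom <- intra & d1 > 0L & d1 == d2
  # an intra pair "crosses" a domain edge when its interval overlaps any
  # planted domain but the two ends are not inside the same one: the
  # condensed blob insulates its flanks from each other
  cross_dom <- logical(nrow(pr))
  if (nrow(doms)) {
    for (ck in unique(doms$chrom)) {
      rows <- which(intra & pr$c1 == ck)
      if (!length(rows)) next
      dck <- doms[chrom == ck]
      ov <- logical(length(rows))
      for (r in seq_len(nrow(dck)))
        ov <- ov | (pr$p1[rows] <= dck$end_bin[r] &
                      pr$p2[rows] >= dck$start_bin[r])
      cross_dom[rows] <- ov & !within_dom[rows]
    }
  }
  mu[within_dom] <- mu[within_dom] / params$domain_depletion
  mu[cross_dom] <- mu[cross_dom] * params$domain_depletion

  lp <- truth$planted_loops
  if (nrow(lp)) {
    key <- paste(pr$i, pr$j)
    hit <- match(paste(lp$i, lp$j), key)
    if (anyNA(hit))
      stop("generation error: planted loop coordinates outside the genome")
    # loop expectation is the plain decay baseline times the fold, exempt
    # from domain modulation, so the planted fold is the true enrichment
    dlp <- bins$pos[lp$j] - bins$pos[lp$i]
    mu[hit] <- params$base_rate * params$f_intra *
      (1 + dlp)^(-params$decay_exponent) * lp$fold
  }

  cnt <- rpois(nrow(pr), mu)
  px <- data.table(i = pr$i, j = pr$j, count = cnt)[count > 0]
  list(matrix = contact_matrix(layout, px), truth = truth)
}
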