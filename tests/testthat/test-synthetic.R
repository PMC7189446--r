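test_that("null simulation matches the decay expectation per distance", {
  lay <- tiny_layout(80, bin = 1e4)
  p <- sim_params(seed = 2, decay_exponent = 1, base_rate = 200,
                  n_domains = 0, loop_rate = 0, rabl_strength = 1,
                  homeolog_factor = 1)
  sim <- simulate_contacts(lay, p)
  prof <- decay_profile(sim$matrix)
  for (dd in c(1, 3, 10)) {
    mu <- 200 * (1 + dd)^-1
    n <- prof[d == dd]$n
    obs <- prof[d == dd]$mean
    # Poisson mean over n pairs: 4-sigma Monte-Carlo band
    expect_lt(abs(obs - mu), 4 * sqrt(mu / n))
  }
})

test_that("simulated matrices are symmetric, non-negative, seed-stable", {
  lay <- make_layout(2, 2, 20 * 25e3, 25e3)
  p <- sim_params(seed = 10, n_domains = 0, loop_rate = 4,
                  min_loop_distance = 3)
  s1 <- simulate_contacts(lay, p)
  s2 <- simulate_contacts(lay, p)
  expect_identical(s1$matrix$pixels, s2$matrix$pixels)
  expect_true(all(s1$matrix$pixels$count >= 0))
  d <- as_dense(s1$matrix)
  expect_identical(d, t(d))
  p3 <- sim_params(seed = 11, n_domains = 0, loop_rate = 4,
                   min_loop_distance = 3)
  s3 <- simulate_contacts(lay, p3)
  expect_false(identical(s1$matrix$pixels, s3$matrix$pixels))
})

test_that("class-wise means recover the configured 8:4:1 hierarchy", {
  sim <- territory_sim(1)
  bins <- bin_table(sim$layout)
  px <- as_dense(sim$matrix)
  same_chrom <- outer(bins$chrom, bins$chrom, "==")
  same_sub <- outer(bins$subgenome, bins$subgenome, "==")
  up <- upper.tri(px)
  m_intra <- mean(px[same_chrom & up])
  m_sub <- mean(px[!same_chrom & same_sub & up])
  m_inter <- mean(px[!same_sub & up])
  expect_gt(m_intra, m_sub)
  expect_gt(m_sub, m_inter)
  # inter-class sample means match configured rates (homeolog/Rabl aside)
  expect_lt(abs(m_sub - 50 * 0.4) / (50 * 0.4), 0.05)
})

test_that("homeolog and Rabl multipliers act where configured", {
  lay <- make_layout(2, 1, 40 * 25e3, 25e3)
  p <- sim_params(seed = 4, n_domains = 0, loop_rate = 0,
                  f_intra = 1, f_subgenome = 0.5, f_inter = 0.5,
                  base_rate = 100, homeolog_factor = 3, rabl_strength = 2)
  sim <- simulate_contacts(lay, p)
  bins <- bin_table(lay)
  px <- as_dense(sim$matrix)
  inter <- which(outer(bins$chrom, bins$chrom, "!=") & upper.tri(px),
                 arr.ind = TRUE)
  pos <- bins$pos
  mirrored <- pos[inter[, 2]] == 40 - 1 - pos[inter[, 1]]
  m_mir <- mean(px[inter[mirrored, , drop = FALSE]])
  m_other <- mean(px[inter[!mirrored, , drop = FALSE]])
  # all pairs are homeolog (1 chrom/subgenome): mu = 100*0.5*3 = 150,
  # mirrored doubled
  expect_lt(abs(m_other - 150) / 150, 0.05)
  expect_lt(abs(m_mir - 300) / 300, 0.10)
})

test_that("planted loop pairs carry the configured fold", {
  sim <- loop_sim(6, lambda = 5)
  tl <- sim$truth$planted_loops
  bins <- bin_table(sim$layout)
  d <- bins$pos[tl$j] - bins$pos[tl$i]
  mu0 <- 40 * (1 + d)^-0.2
  obs <- merge(tl, sim$matrix$pixels, by = c("i", "j"))$count
  expect_equal(length(obs), nrow(tl))
  expect_lt(abs(mean(obs / mu0) - 5), 0.5)
  expect_true(all(d >= 5 & d <= 30))
})

test_that("gene placement favours boundaries and loop anchors", {
  sim <- domain_sim(3)
  p <- sim$truth$params
  gx <- simulate_genes_and_expression(sim$layout, sim$truth, p)
  g <- gx$genes
  bins <- bin_table(sim$layout)
  pb <- sim$truth$boundaries
  bbins <- bins[pb[, .(chrom, pos = bin)], on = c("chrom", "pos")]$idx
  expect_true(all(bbins %in% g$bin))          # boundary_gene_prob = 1
  dl <- sim$truth$planted_domains[
    , .(pos = seq(start_bin, end_bin)), by = .(chrom, start_bin)]
  dbins <- bins[dl[, .(chrom, pos)], on = c("chrom", "pos")]$idx
  frac_dom <- mean(dbins %in% g$bin)
  expect_lt(frac_dom, 0.25)                   # gene-poor interiors
  expect_true(all(g$expressed == (g$tpm_a > 0)))
})

test_that("mark concordance 1 copies the partner's mark set exactly", {
  sim <- loop_sim(8, lambda = 3, n_loops = 25)
  p <- sim$truth$params
  p$mark_concordance <- 1
  gx <- simulate_genes_and_expression(sim$layout, sim$truth, p)
  g <- gx$genes
  cp <- gx$truth$gene_pair_couplings
  mk <- c("H3K9ac", "H3K36me3", "H3K27me3", "RNAPII", "ATAC")
  g1 <- g[match(cp$gene1, gene_id), ..mk]
  g2 <- g[match(cp$gene2, gene_id), ..mk]
  expect_identical(g1, g2)
})

test_that("degenerate coupling gives exact slope, noisy coupling recovers", {
  # beta = 1, sd = 0 -> slope exactly 1
  d0 <- simulate_coupled_logfc(50, beta = 1, noise_sd = 0, seed = 1)
  fit0 <- lm(lfc2 ~ lfc1, data = d0)
  expect_equal(unname(coef(fit0)[2]), 1, tolerance = 1e-12)
  # beta = 0.5, sd = 0.5, 2000 pairs -> slope within +/- 0.05
  d1 <- simulate_coupled_logfc(2000, beta = 0.5, noise_sd = 0.5, seed = 2)
  fit1 <- lm(lfc2 ~ lfc1, data = d1)
  expect_lt(abs(unname(coef(fit1)[2]) - 0.5), 0.05)
})

test_that("hichip boosts RNAPII pairs and thins the rest", {
  sim <- loop_sim(12, lambda = 6, n_loops = 20)
  p <- sim$truth$params
  gx <- simulate_genes_and_expression(sim$layout, sim$truth, p)
  # boost = 1, thinning = 1 -> unchanged
  h0 <- simulate_hichip(sim$matrix, gx$genes, occupancy_boost = 1,
                        thinning = 1, seed = 3)
  # re-Poisson only touches RNAPII pairs; totals agree in expectation
  expect_lt(abs(sum(h0$pixels$count) - sum(sim$matrix$pixels$count)) /
              sum(sim$matrix$pixels$count), 0.05)
  # no RNAPII genes -> uniformly thinned copy
  g2 <- copy(gx$genes)[, RNAPII := FALSE]
  h1 <- simulate_hichip(sim$matrix, g2, occupancy_boost = 5,
                        thinning = 0.5, seed = 3)
  expect_lt(abs(sum(h1$pixels$count) / sum(sim$matrix$pixels$count) - 0.5),
            0.02)
  # boosted planted RNAPII loop scores higher z than in the plain matrix
  pol <- gx$genes[RNAPII == TRUE]$bin
  tl <- sim$truth$planted_loops[i %in% pol & j %in% pol]
  expect_gt(nrow(tl), 0)  # deterministic under the fixed seed
  h2 <- simulate_hichip(sim$matrix, gx$genes, occupancy_boost = 5,
                        thinning = 1, seed = 3)
  z_of <- function(m) {
    ls <- call_loops_intra(m, q_max = 1, p_max = 1, z_min = -Inf)
    merge(ls$loops, tl, by = c("i", "j"))$z
  }
  expect_gt(mean(z_of(h2)), mean(z_of(sim$matrix)))
  d <- as_dense(h2)
  expect_identical(d, t(d))
})
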