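test_that("BH step-up matches hand cases and stats::p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(1)
  p <- runif(200)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "invalid input")
})

test_that("z and Poisson p follow the closed forms", {
  # scoring engine on a pair with obs = 40, expected = 20 exactly
  cand <- data.table(i = 1L, j = 10L, obs = 40, expected = 20)
  r <- territoria:::loop_filter(copy(cand), 0.05, 1.5, 0.1)
  expect_equal(nrow(r$loops), 1L)
  expect_equal(r$loops$z, (40 - 20) / sqrt(20), tolerance = 1e-12)
  expect_equal(r$loops$z, 4.47, tolerance = 0.01)
  expect_equal(r$loops$p, ppois(39, 20, lower.tail = FALSE),
               tolerance = 1e-15)
  expect_lt(r$loops$p, 1e-4)

  # full caller: boosted pair scores near the closed form (its own counts
  # perturb the empirical decay mean and coverages slightly)
  lay <- tiny_layout(100, bin = 20e3)
  dense <- matrix(20, 100, 100); diag(dense) <- 20
  dense[5, 15] <- 40; dense[15, 5] <- 40
  m <- cm_from_dense(dense, lay)
  ls <- call_loops_intra(m, p_max = 1, z_min = -Inf, q_max = 1,
                         min_distance_bins = 2)
  hit <- ls$loops[i == 5 & j == 15]
  expect_equal(hit$z, (hit$obs - hit$expected) / sqrt(hit$expected),
               tolerance = 1e-12)
  expect_equal(hit$p, ppois(hit$obs - 1, hit$expected, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(hit$z - (40 - 20) / sqrt(20)), 0.5)
  expect_lt(hit$p, 2e-4)
})

test_that("null-equal matrix yields z = 0 and no loops", {
  lay <- tiny_layout(20, bin = 20e3)
  dense <- matrix(10, 20, 20)
  m <- cm_from_dense(dense, lay)
  ls <- call_loops_intra(m)
  expect_equal(nrow(ls$loops), 0L)
  all_t <- call_loops_intra(m, p_max = 1.1, z_min = -Inf, q_max = 1.1)
  expect_true(all(abs(all_t$loops$z) < 1e-9))
})

test_that("every returned loop satisfies the stored thresholds", {
  sim <- loop_sim(17, lambda = 5)
  ls <- call_loops_intra(sim$matrix)
  expect_true(all(ls$loops$p < ls$thresholds$p))
  expect_true(all(ls$loops$z > ls$thresholds$z))
  expect_true(all(ls$loops$q < ls$thresholds$q))
  expect_true(all(ls$loops$q >= ls$loops$p))
  expect_false(any(duplicated(ls$loops[, .(i, j)])))
  # z agrees with brute-force recomputation from matrix + decay profile
  prof <- decay_profile(sim$matrix)
  cov <- cm_marginals(sim$matrix, balanced = FALSE)
  mc <- mean(cov[cov > 0])
  dense <- as_dense(sim$matrix)
  bins <- bin_table(sim$layout)
  for (r in 1:min(5, nrow(ls$loops))) {
    lp <- ls$loops[r]
    dd <- bins$pos[lp$j] - bins$pos[lp$i]
    e <- prof$mean[match(dd, prof$d)] * cov[lp$i] * cov[lp$j] / mc^2
    z_bf <- (dense[lp$i, lp$j] - e) / sqrt(e)
    expect_equal(lp$z, z_bf, tolerance = 1e-9)
  }
})

test_that("planted loops are recovered with bounded false discoveries", {
  stats <- t(vapply(1:20, function(s) {
    sim <- loop_sim(200 + s, lambda = 5)
    ls <- call_loops_intra(sim$matrix)
    tl <- sim$truth$planted_loops
    called <- paste(ls$loops$i, ls$loops$j)
    truthk <- paste(tl$i, tl$j)
    sens <- mean(truthk %in% called)
    fdp <- if (length(called)) mean(!(called %in% truthk)) else 0
    c(sens = sens, fdp = fdp)
  }, numeric(2)))
  expect_gte(mean(stats[, "sens"]), 0.9)
  expect_lte(mean(stats[, "fdp"]), 0.15)
})

test_that("null simulations stay within the BH false-call bound", {
  ok <- vapply(1:20, function(s) {
    sim <- loop_sim(300 + s, lambda = 1, n_loops = 0)
    ls <- call_loops_intra(sim$matrix)
    bound <- 0.1 * ls$n_tested + 3 * sqrt(0.1 * ls$n_tested)
    nrow(ls$loops) <= bound
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("detection power is monotone in the planted fold", {
  sens_at <- function(lambda) {
    mean(vapply(1:5, function(s) {
      sim <- loop_sim(400 + s, lambda = lambda)
      ls <- call_loops_intra(sim$matrix)
      tl <- sim$truth$planted_loops
      mean(paste(tl$i, tl$j) %in% paste(ls$loops$i, ls$loops$j))
    }, numeric(1)))
  }
  s2 <- sens_at(2); s4 <- sens_at(4); s8 <- sens_at(8)
  expect_lte(s2, s4 + 1e-9)
  expect_lte(s4, s8 + 1e-9)
})

test_that("interchromosomal calling finds planted pairs, not noise", {
  lay <- make_layout(1, 2, 50 * 50e3, 50e3)
  set.seed(31)
  n <- 100
  dense <- matrix(0, n, n)
  # uniform inter block + decayed intra
  for (a in 1:n) for (b in a:n) {
    same <- (a <= 50) == (b <= 50)
    mu <- if (same) 30 / (1 + abs(a - b)) else 5
    dense[a, b] <- rpois(1, mu); dense[b, a] <- dense[a, b]
  }
  m <- cm_from_dense(dense, lay)
  ls0 <- call_interactions_inter(m)
  expect_lte(nrow(ls0$loops), 0.1 * ls0$n_tested +
               3 * sqrt(0.1 * ls0$n_tested))
  # planted inter pair at 5x expected
  dense2 <- dense
  dense2[10, 60] <- 5 * 5 * 2; dense2[60, 10] <- dense2[10, 60]
  m2 <- cm_from_dense(dense2, lay)
  ls2 <- call_interactions_inter(m2)
  expect_true(nrow(ls2$loops[i == 10 & j == 60]) == 1)
  # single chromosome -> empty with warning
  m1 <- random_positive_cm(10, seed = 2)
  expect_warning(e <- call_interactions_inter(m1), "single-chromosome")
  expect_equal(nrow(e$loops), 0L)
})

test_that("conserved loops match by anchor overlap across resolutions", {
  sim <- loop_sim(55, lambda = 8)
  la <- call_loops_intra(sim$matrix)
  # identical sets -> all conserved
  cc <- conserved_loops(la, la)
  expect_equal(nrow(cc$loops), nrow(la$loops))
  expect_true(all(!is.na(cc$loops$z_b)))
  # disjoint -> empty
  lb <- la
  lb$loops <- copy(la$loops)[, `:=`(chrom1 = "9Z", chrom2 = "9Z")]
  expect_equal(nrow(conserved_loops(la, lb)$loops), 0L)
  # coarser condition B still matches (loop inside wider anchors)
  lc <- la
  lc$loops <- copy(la$loops)[, `:=`(start1 = pmax(0, start1 - 20e3),
                                    end1 = end1 + 20e3,
                                    start2 = pmax(0, start2 - 20e3),
                                    end2 = end2 + 20e3)]
  expect_equal(nrow(conserved_loops(la, lc)$loops), nrow(la$loops))
})
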