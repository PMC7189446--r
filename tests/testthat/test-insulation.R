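test_that("insulation equals a brute-force window average exactly", {
  m <- random_positive_cm(20, seed = 5)
  bal <- ice_normalize(m, mask_fraction = 0)
  w <- 3L
  tr <- insulation_index(bal, window = 3 * 1000)
  dense <- as_dense(bal)
  raw <- rep(NA_real_, 20)
  for (i in seq_len(20)) {
    if (i - w < 1 || i + w > 20) next
    raw[i] <- mean(dense[(i - w):(i - 1), (i + 1):(i + w)])
  }
  expected <- log2(raw / mean(raw, na.rm = TRUE))
  expect_equal(tr$score, expected, tolerance = 1e-12)
  # edge rule: first and last w bins undefined
  expect_true(all(is.na(tr$score[c(1:w, (20 - w + 1):20)])))
})

test_that("constant matrix scores 0 at every defined bin", {
  m <- cm_from_dense(matrix(5, 15, 15), tiny_layout(15))
  tr <- insulation_index(m, window = 4000)
  expect_true(all(abs(tr$score[!is.na(tr$score)]) < 1e-12))
  expect_error(insulation_index(m, window = 500), "multiple")
})

test_that("a planted contact-depleted boundary is a local minimum", {
  n <- 24
  dense <- matrix(10, n, n)
  b <- 12  # boundary bin (1-based); pairs straddling it depleted
  for (u in 1:n) for (v in 1:n)
    if (u < b && v > b) { dense[u, v] <- 1; dense[v, u] <- 1 }
  m <- cm_from_dense(dense, tiny_layout(n))
  tr <- insulation_index(m, window = 4000)
  sc <- tr$score
  expect_equal(which.min(sc), b)
  bd <- call_boundaries(tr)
  expect_true(b %in% bd$idx)
})

test_that("domain calling is a run-length rule over the threshold", {
  tr <- data.table(chrom = "1A", start = (0:3) * 25e3, end = (1:4) * 25e3,
                   idx = 1:4, score = c(-1, 0.5, 0.6, -1))
  setattr(tr, "class", c("insulation_track", class(tr)))
  setattr(tr, "window", 100e3)
  d <- call_domains(tr, threshold = 0.4, min_bins = 2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 25e3)
  expect_equal(d$end, 75e3)
  expect_equal(d$n_bins, 2L)
  # all below threshold -> empty set
  tr2 <- copy(tr)[, score := -1]
  expect_equal(nrow(call_domains(tr2)), 0L)
  # summary recomputable from intervals
  s <- attr(d, "summary")
  expect_equal(s$count, 1L)
  expect_equal(s$coverage_fraction, 50e3 / 100e3)
})

test_that("planted domains are recovered with interior > boundary scores", {
  sim <- domain_sim(21)
  bal <- ice_normalize(sim$matrix)
  tr <- insulation_index(bal, window = 100e3)
  rec <- boundary_recovery(tr, sim$truth, tol = 1L)
  expect_gte(rec, 0.9)
  doms <- call_domains(tr, threshold = 0.4, min_bins = 2)
  expect_gte(nrow(doms), 0.9 * nrow(sim$truth$planted_domains))
  # no two called domains overlap, each >= 2 bins
  expect_true(all(doms$n_bins >= 2))
  setorder(doms, chrom, start)
  byc <- doms[, all(head(end, -1) <= tail(start, -1)), by = chrom]
  expect_true(all(byc$V1))
  # per-bin comparison: mean score inside planted domains > at boundaries
  bins <- bin_table(sim$layout)
  dl <- sim$truth$planted_domains[
    , .(pos = seq(start_bin, end_bin)), by = .(chrom, start_bin)]
  trk <- copy(tr)[, pos := start / 25e3]
  int_sc <- trk[dl[, .(chrom, pos)], on = c("chrom", "pos")]$score
  bnd_sc <- trk[sim$truth$boundaries[, .(chrom, pos = bin)],
                on = c("chrom", "pos")]$score
  expect_gt(mean(int_sc, na.rm = TRUE), mean(bnd_sc, na.rm = TRUE))
})

test_that("decile partition follows the remainder and tie rules", {
  mk_track <- function(sc) {
    dt <- data.table(chrom = "1A", start = (seq_along(sc) - 1) * 1000,
                     end = seq_along(sc) * 1000, idx = seq_along(sc),
                     score = sc)
    setattr(dt, "class", c("insulation_track", class(dt)))
    dt
  }
  t20 <- partition_deciles(mk_track(rnorm(20)))
  expect_equal(as.integer(table(t20$decile)), rep(2L, 10))
  t25 <- partition_deciles(mk_track(rnorm(25)))
  expect_equal(as.integer(table(t25$decile)), c(3L, 3L, 3L, 3L, 3L,
                                                2L, 2L, 2L, 2L, 2L))
  # decile 1 = most negative
  sc <- seq(-2, 2, length.out = 20)
  t <- partition_deciles(mk_track(sc))
  expect_equal(t$decile[1:2], c(1L, 1L))
  expect_equal(t$decile[19:20], c(10L, 10L))
  # ties broken by genomic order
  tt <- partition_deciles(mk_track(rep(c(0, 1), each = 10)))
  expect_equal(tt$decile[1:10], rep(1:5, each = 2L))
  expect_equal(tt$decile[11:20], rep(6:10, each = 2L))
  expect_error(partition_deciles(mk_track(rnorm(9))), "fewer than 10")
  # permutation invariance of gene assignment through scores
  sc2 <- rnorm(30)
  t1 <- partition_deciles(mk_track(sc2))
  perm <- sample(30)
  t2 <- partition_deciles(mk_track(sc2[perm]))
  expect_equal(t2$decile[order(perm)], t1$decile)
})

test_that("gene-to-bin assignment follows the majority-overlap rule", {
  bins <- data.table(chrom = "1A", start = c(0, 1000, 2000),
                     end = c(1000, 2000, 3000), decile = c(1L, 2L, 3L))
  genes <- data.table(
    gene_id = c("inside", "split5050", "middle60", "tiny_left"),
    chrom = "1A",
    start = c(100, 500, 700, 0),
    end = c(900, 1500, 2200, 400))
  a <- assign_genes(genes, bins)
  expect_equal(a[gene_id == "inside"]$label, 1L)
  # 50/50 split -> left bin
  expect_equal(a[gene_id == "split5050"]$label, 1L)
  # 60% in middle bin of three
  expect_equal(a[gene_id == "middle60"]$label, 2L)
  expect_equal(a[gene_id == "tiny_left"]$label, 1L)
  # no qualifying bin -> unassigned
  g2 <- data.table(gene_id = "span3", chrom = "1A", start = 800,
                   end = 2900)
  expect_true(is.na(assign_genes(g2, bins)$label))
  expect_error(assign_genes(data.table(gene_id = "bad", chrom = "1A",
                                       start = 5, end = 5), bins),
               "format error")
})
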