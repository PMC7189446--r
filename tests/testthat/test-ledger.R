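mk_loopset <- function(loops_dt, resolution = 20e3) {
  structure(list(loops = loops_dt, kind = "intra", resolution = resolution,
                 thresholds = list(p = 0.05, z = 1.5, q = 0.1),
                 n_tested = nrow(loops_dt)),
            class = "loop_set")
}

test_that("anchor annotation emits the gene cross product", {
  loops <- data.table(chrom1 = "1A", start1 = 0, end1 = 20e3,
                      chrom2 = "1A", start2 = 100e3, end2 = 120e3,
                      z = 3, kind = "intra")
  genes <- data.table(
    gene_id = c("a1", "a2", "b1", "b2", "b3", "far"),
    chrom = "1A",
    start = c(1e3, 10e3, 101e3, 105e3, 110e3, 500e3),
    end = c(5e3, 15e3, 104e3, 108e3, 115e3, 510e3),
    expressed = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  pr <- annotate_anchors(mk_loopset(loops), genes)
  expect_equal(nrow(pr), 2 * 3)
  # orientation: gene1 upstream
  expect_true(all(pr$gene1 %in% c("a1", "a2")))
  # gene-less anchor -> loop dropped
  loops2 <- rbind(loops, data.table(chrom1 = "1A", start1 = 200e3,
                                    end1 = 220e3, chrom2 = "1A",
                                    start2 = 300e3, end2 = 320e3, z = 2,
                                    kind = "intra"))
  pr2 <- annotate_anchors(mk_loopset(loops2), genes)
  expect_equal(nrow(pr2), 6)
  # distance is between gene midpoints
  expect_equal(pr[gene1 == "a1" & gene2 == "b1"]$distance,
               (101e3 + 104e3) / 2 - (1e3 + 5e3) / 2)
})

test_that("a gene overlapping both anchors yields no self-pair", {
  loops <- data.table(chrom1 = "1A", start1 = 0, end1 = 50e3,
                      chrom2 = "1A", start2 = 40e3, end2 = 90e3,
                      z = 2, kind = "intra")
  genes <- data.table(gene_id = c("span", "right"), chrom = "1A",
                      start = c(30e3, 60e3), end = c(60e3, 70e3),
                      expressed = c(TRUE, TRUE))
  pr <- annotate_anchors(mk_loopset(loops), genes)
  expect_false(any(pr$gene1 == pr$gene2))
  expect_true(nrow(pr) >= 1)
})

test_that("2x2 association matches the closed forms", {
  r0 <- contingency_2x2(25, 25, 25, 25)
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$log2_or, 0)
  expect_equal(r0$cramers_v, 0)
  r1 <- contingency_2x2(10, 5, 5, 10)
  expect_equal(r1$odds_ratio, 4)
  expect_equal(r1$log2_or, 2)
  expect_equal(r1$chi2, 10 / 3, tolerance = 1e-12)
  expect_equal(r1$cramers_v, 1 / 3, tolerance = 1e-12)
  expect_false(r1$haldane_applied)
  r2 <- contingency_2x2(10, 0, 0, 10)
  expect_true(r2$haldane_applied)
  expect_equal(r2$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_error(contingency_2x2(0, 0, 0, 0), "empty")
  # phi identity against the chi-square route on random tables
  set.seed(12)
  for (k in 1:10) {
    cells <- rpois(4, 20) + 1
    r <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    phi <- abs(a * d - b * c) /
      sqrt((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(r$cramers_v, phi, tolerance = 1e-12)
  }
})

test_that("feature association counts pairs by gene-side flags", {
  pr <- data.table(expressed_1 = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                   expressed_2 = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  r <- feature_association(pr, "expressed")
  expect_equal(c(r$a, r$b, r$c, r$d), c(2, 1, 1, 1))
  expect_equal(r$n, 5)
  expect_error(feature_association(pr, "nope"), "unknown feature")
  expect_error(feature_association(pr[0], "expressed"), "empty")
})

test_that("association ledger is symmetric after pooling orientations", {
  set.seed(13)
  n <- 5000
  pr <- data.table(expressed_1 = runif(n) < 0.5,
                   H3K27me3_1 = runif(n) < 0.3)
  pr[, expressed_2 := runif(n) < 0.5]
  pr[, H3K27me3_2 := runif(n) < 0.3]
  led <- association_matrix(pr, c("expressed", "H3K27me3"))
  sym <- led$symmetrized
  ab <- sym[feature1 == "expressed" & feature2 == "H3K27me3"]
  ba <- sym[feature1 == "H3K27me3" & feature2 == "expressed"]
  expect_equal(ab$odds_ratio, ba$odds_ratio, tolerance = 1e-12)
  # mirrored input gives the identical symmetrized ledger
  swapped <- copy(pr)
  setnames(swapped,
           c("expressed_1", "H3K27me3_1", "expressed_2", "H3K27me3_2"),
           c("expressed_2", "H3K27me3_2", "expressed_1", "H3K27me3_1"))
  led2 <- association_matrix(swapped, c("expressed", "H3K27me3"))
  expect_equal(led$symmetrized$odds_ratio, led2$symmetrized$odds_ratio,
               tolerance = 1e-12)
  # independent features -> small |log2OR|
  expect_true(all(abs(sym$log2_or) <= 0.3))
})

test_that("planted concordance produces a strongly positive diagonal", {
  set.seed(14)
  n <- 2000
  s1 <- runif(n) < 0.5
  s2 <- ifelse(runif(n) < 0.9, s1, !s1)
  pr <- data.table(expressed_1 = s1, expressed_2 = s2)
  r <- feature_association(pr, "expressed")
  expect_gt(r$log2_or, 2)
  expect_gt(r$cramers_v, 0.5)
})

test_that("expression concordance concentrates on the diagonal", {
  # perfectly matched TPM -> all mass on the diagonal
  set.seed(15)
  t1 <- rlnorm(400, 3, 1)
  pr <- data.table(tpm_a_1 = t1, tpm_a_2 = t1)
  r <- expression_concordance(pr, 4)
  expect_equal(r$diagonal_fraction, 1)
  expect_equal(sum(r$counts), 400)
  # balanced marginals
  expect_true(all(abs(rowSums(r$counts) - 100) <= 1))
  expect_true(all(abs(colSums(r$counts) - 100) <= 1))
  # independent TPMs -> near-uniform cells
  pr2 <- data.table(tpm_a_1 = rlnorm(10000, 3, 1),
                    tpm_a_2 = rlnorm(10000, 3, 1))
  r2 <- expression_concordance(pr2, 4)
  gof <- chisq.test(as.vector(r2$counts))
  expect_gt(gof$p.value, 0.01)
  # rank correlation 0.8 -> diagonal dominates
  z1 <- rnorm(5000)
  z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(5000)
  pr3 <- data.table(tpm_a_1 = exp(z1), tpm_a_2 = exp(z2))
  r3 <- expression_concordance(pr3, 4)
  off <- (sum(r3$counts) - sum(diag(r3$counts))) / 12
  expect_gt(sum(diag(r3$counts)) / 4, off)
  expect_error(expression_concordance(
    data.table(tpm_a_1 = rep(2, 50), tpm_a_2 = rep(2, 50)), 4),
    "degenerate")
})

test_that("partner counts are distinct and fractions follow", {
  pr <- data.table(gene1 = c("A", "A", "A", "A"),
                   gene2 = c("B", "C", "D", "B"))
  pc <- partner_counts(pr)
  expect_equal(pc$counts[gene_id == "A"]$n_partners, 3L)
  expect_equal(pc$counts[gene_id == "B"]$n_partners, 1L)
  expect_equal(pc$frac_ge4, 0)
  # star graph A-{B..K}: 1 of 11 genes has >= 10 partners
  star <- data.table(gene1 = "A", gene2 = paste0("P", 1:10))
  pcs <- partner_counts(star)
  expect_equal(pcs$frac_ge10, 1 / 11)
  expect_equal(pcs$frac_ge4, 1 / 11)
})

test_that("pair-table ingestion maps columns and converts 0/1 flags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  dt <- data.table(first_gene = c("g1", "g2"), second_gene = c("g3", "g4"),
                   expr_1 = c(1, 0), expr_2 = c(1, 1),
                   tpm_a_1 = c(5, 0), tpm_a_2 = c(2, 1), z = c(2.5, 3))
  fwrite(dt, path, sep = "\t")
  pr <- read_pair_table(path, mapping = c(gene1 = "first_gene",
                                          gene2 = "second_gene",
                                          expressed_1 = "expr_1",
                                          expressed_2 = "expr_2"))
  expect_identical(pr$expressed_1, c(TRUE, FALSE))
  expect_identical(pr$gene1, c("g1", "g2"))
  r <- feature_association(pr, "expressed")
  expect_equal(r$n, 2)
  expect_error(read_pair_table(path, mapping = c(gene1 = "missing_col")),
               "not found")
})
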