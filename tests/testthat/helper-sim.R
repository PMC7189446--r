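# Shared fixtures, built in code.

library(data.table)

# tiny layout: one subgenome, one chromosome
tiny_layout <- function(nbins = 10L, bin = 1000) {
  make_layout(1, 1, nbins * bin, bin)
}

# small dense symmetric count matrix as a contact_matrix
cm_from_dense <- function(mat, layout) {
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  contact_matrix(layout,
                 data.table(i = idx[, 1], j = idx[, 2],
                            count = mat[idx]))
}

# random strictly positive symmetric matrix
random_positive_cm <- function(nbins, seed, bin = 1000) {
  set.seed(seed)
  m <- matrix(runif(nbins^2, 1, 10), nbins)
  m <- (m + t(m)) / 2
  cm_from_dense(m, tiny_layout(nbins, bin))
}

# study-condition simulation for domain recovery: 10 condensed domains per
# chromosome at strong depletion, 25-kb bins, 100-kb scoring window
domain_sim <- function(seed, n_chrom = 2L, nbins = 130L) {
  lay <- make_layout(1, n_chrom, nbins * 25e3, 25e3)
  p <- sim_params(seed = seed, n_domains = 10, domain_depletion = 0.2,
                  loop_rate = 0, decay_exponent = 0.8, base_rate = 60,
                  rabl_strength = 1, homeolog_factor = 1)
  c(simulate_contacts(lay, p), list(layout = lay))
}

# study-condition simulation for loop calling: flat-ish decay so the
# baseline expectation at the planted loops is ~20-28 counts
loop_sim <- function(seed, lambda, n_loops = 40L, nbins = 150L) {
  lay <- make_layout(1, 2, nbins * 20e3, 20e3)
  p <- sim_params(seed = seed, n_domains = 0, loop_rate = n_loops,
                  loop_fold = lambda, min_loop_distance = 5,
                  max_loop_distance = 30, decay_exponent = 0.2,
                  base_rate = 40, rabl_strength = 1, homeolog_factor = 1)
  c(simulate_contacts(lay, p), list(layout = lay))
}

# study-condition simulation for territory statistics: 8:4:1 class
# hierarchy, homeolog bonus 2, shallow decay at the megabase scale
territory_sim <- function(seed) {
  lay <- make_layout(3, 2, 30 * 100e3, 100e3)
  p <- sim_params(seed = seed, n_domains = 0, loop_rate = 0,
                  decay_exponent = 0.1, base_rate = 50,
                  f_intra = 0.8, f_subgenome = 0.4, f_inter = 0.1,
                  homeolog_factor = 2, rabl_strength = 1)
  c(simulate_contacts(lay, p), list(layout = lay))
}

# fraction of planted boundary bins within +/- tol bins of a called
# insulation minimum
boundary_recovery <- function(track, truth, tol = 1L) {
  bs <- attr(track, "window") / (track$end[1] - track$start[1]) # unused
  bw <- track$end[1] - track$start[1]
  bd <- call_boundaries(track)
  bd[, pos := start / bw]
  pb <- truth$boundaries
  hits <- vapply(seq_len(nrow(pb)), function(k) {
    any(abs(bd[chrom == pb$chrom[k]]$pos - pb$bin[k]) <= tol)
  }, logical(1))
  mean(hits)
}
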