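#' Contact matrices
#'
#' A `contact_matrix` stores a symmetric, genome-wide binned contact map as
#' an upper-triangle sparse triplet table: one row per unordered bin pair
#' with a non-zero value (`i <= j`, global bin indices from [bin_table()]).
#' Zero pairs are implicit.  After [ice_normalize()] the object carries a
#' per-bin `bias` vector (NA for masked bins) and `balanced = TRUE`; the
#' balanced value of a pair is `raw / (bias_i * bias_j)` exactly.
#'
#' @param layout a [genome_layout()].
#' @param pixels data.table with columns `i`, `j`, `count` (`i <= j` after
#'   canonicalisation; duplicates are an error).
#' @param balanced logical.
#' @param bias numeric per-bin vector (required iff `balanced`).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(layout, pixels, balanced = FALSE, bias = NULL) {
  bins <- bin_table(layout)
  px <- as.data.table(pixels)[, .(i = as.integer(i), j = as.integer(j),
                                  count = as.numeric(count))]
  swap <- px$i > px$j
  if (any(swap)) px[swap, c("i", "j") := .(j, i)]
  if (nrow(px) && (min(px$i) < 1L || max(px$j) > nrow(bins)))
    stop("pixel bin index outside the genome")
  if (any(px$count < 0)) stop("negative contact count")
  if (anyDuplicated(px, by = c("i", "j")))
    stop("duplicate unordered bin pair in pixels")
  px <- px[count != 0]
  setkey(px, i, j)
  structure(list(layout = layout, bins = bins, pixels = px,
                 balanced = isTRUE(balanced), bias = bias),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "contact_matrix: %d bins (%s bp), %d non-zero pairs, sum %.6g, %s\n",
    nrow(x$bins), format(x$layout$bin_size, big.mark = ","),
    nrow(x$pixels), sum(x$pixels$count),
    if (x$balanced) "ICE-balanced" else "raw"))
  invisible(x)
}

#' Pair values of a contact matrix
#'
#' Returns the pixel table with the working value per pair: raw counts, or
#' bias-divided values if the matrix is balanced (pairs touching masked bins
#' dropped).
#' @param m contact_matrix.
#' @return data.table (i, j, value).
#' @keywords internal
cm_values <- function(m) {
  px <- m$pixels[, .(i, j, value = count)]
  if (m$balanced) {
    b <- m$bias
    px[, value := value / (b[i] * b[j])]
    px <- px[is.finite(value)]
  }
  px
}

#' Per-bin marginal sums
#'
#' Dense-equivalent row sums: each off-diagonal pair contributes to both of
#' its bins, a diagonal pair once.
#' @param m contact_matrix.
#' @param balanced use balanced values (default: whatever the matrix is).
#' @return numeric vector, one entry per bin.
#' @export
cm_marginals <- function(m, balanced = m$balanced) {
  px <- if (balanced) cm_values(m) else m$pixels[, .(i, j, value = count)]
  n <- nrow(m$bins)
  marg <- numeric(n)
  s1 <- px[, sum(value), by = i]
  s2 <- px[i != j, sum(value), by = j]
  marg[s1$i] <- marg[s1$i] + s1$V1
  if (nrow(s2)) marg[s2$j] <- marg[s2$j] + s2$V1
  marg
}

#' Dense symmetric matrix view (small matrices only)
#' @param m contact_matrix.
#' @param balanced use balanced values.
#' @return base matrix, masked bins as NA rows/columns when balanced.
#' @export
as_dense <- function(m, balanced = m$balanced) {
  n <- nrow(m$bins)
  out <- matrix(0, n, n)
  px <- if (balanced) cm_values(m) else m$pixels[, .(i, j, value = count)]
  out[cbind(px$i, px$j)] <- px$value
  out[cbind(px$j, px$i)] <- px$value
  if (balanced && !is.null(m$bias)) {
    bad <- which(is.na(m$bias))
    out[bad, ] <- NA_real_
    out[, bad] <- NA_real_
  }
  out
}

#' Sum counts into coarser bins
#'
#' Merges `factor` consecutive bins per chromosome (never across chromosome
#' boundaries); counts are summed.  The total matrix mass is conserved.
#'
#' @param m contact_matrix (raw).
#' @param factor integer >= 1; new bin size = `factor *` old.
#' @return contact_matrix at the coarser resolution.
#' @export
coarsen <- function(m, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("invalid parameter: factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  new_layout <- genome_layout(m$layout$chroms,
                              m$layout$bin_size * factor)
  old <- m$bins
  # map old global idx -> new global idx through per-chromosome ordinals
  new_bins <- bin_table(new_layout)
  map <- old[, .(chrom, idx, newpos = pos %/% factor)]
  map <- new_bins[, .(chrom, newpos = pos, newidx = idx)][map,
    on = c("chrom", "newpos")]
  lut <- integer(nrow(old)); lut[map$idx] <- map$newidx
  px <- m$pixels[, .(i = lut[i], j = lut[j], count)]
  px <- px[, .(count = sum(count)), by = .(i = pmin(i, j), j = pmax(i, j))]
  contact_matrix(new_layout, px)
}
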