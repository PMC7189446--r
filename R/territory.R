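#' Classify and aggregate contacts into super-bin pairs
#'
#' Sums (balanced, if available) contact values into `super_bin`-sized
#' super-bins (never merging across chromosomes; the last super-bin of a
#' chromosome may be short and is retained), scales to counts per million
#' of the aggregated total, and labels every unordered super-bin pair:
#' `intra_chromosome`, `inter_same_subgenome`, or `inter_subgenome(X,Y)`
#' with the two subgenome labels sorted.  For inter-subgenome pairs a
#' `homeolog` flag marks pairs of chromosomes sharing a homeolog group.
#' Super-bin self-pairs are kept in the `intra_chromosome` class.
#'
#' @param m contact_matrix (typically ICE-balanced).
#' @param super_bin super-bin width in bp (default 10 Mb); must be a
#'   multiple of the matrix bin size.
#' @return data.table, one row per super-bin pair, with columns `chrom1`,
#'   `super1`, `chrom2`, `super2`, `class_label`, `homeolog`, `freq` (summed
#'   value) and `cpm`.
#' @export
classify_and_aggregate <- function(m, super_bin = 10e6) {
  bs <- m$layout$bin_size
  if (super_bin %% bs != 0)
    stop("invalid parameter: super_bin must be a multiple of the bin size")
  fac <- as.integer(super_bin / bs)
  bins <- m$bins
  sb <- bins$pos %/% fac            # super-bin ordinal within chromosome
  # global super-bin index so zero pairs are enumerated too
  sup <- unique(data.table(chrom = bins$chrom, super = sb))
  sup[, sidx := .I]
  skey <- sup$sidx[match(paste(bins$chrom, sb), paste(sup$chrom, sup$super))]
  px <- cm_values(m)
  got <- px[, .(freq = sum(value)),
            by = .(s1 = pmin(skey[i], skey[j]), s2 = pmax(skey[i], skey[j]))]
  allp <- CJ(s1 = sup$sidx, s2 = sup$sidx)[s1 <= s2]
  agg <- got[allp, on = c("s1", "s2")]
  agg[is.na(freq), freq := 0]
  agg <- agg[, .(chrom1 = sup$chrom[s1], super1 = sup$super[s1],
                 chrom2 = sup$chrom[s2], super2 = sup$super[s2], freq)]
  ch <- m$layout$chroms
  sub_of <- setNames(ch$subgenome, ch$name)
  grp_of <- setNames(ch$homeolog_group, ch$name)
  agg[, `:=`(sub1 = sub_of[chrom1], sub2 = sub_of[chrom2],
             group1 = grp_of[chrom1], group2 = grp_of[chrom2])]
  agg[, class_label := ifelse(chrom1 == chrom2, "intra_chromosome",
                       ifelse(sub1 == sub2, "inter_same_subgenome",
                              paste0("inter_subgenome(",
                                     pmin(sub1, sub2), ",",
                                     pmax(sub1, sub2), ")")))]
  agg[, homeolog := chrom1 != chrom2 & sub1 != sub2 & group1 == group2]
  agg[chrom1 == chrom2 | sub1 == sub2, homeolog := NA]
  agg[, cpm := freq / sum(freq) * 1e6]
  agg[, c("sub1", "sub2", "group1", "group2") := NULL]
  agg[]
}

#' Per-class medians of super-bin interaction frequencies
#'
#' @param tab output of [classify_and_aggregate()].
#' @return list with `by_class` (class_label, n, median cpm),
#'   `by_subgenome_pair` (inter-subgenome classes only), `homeolog`
#'   (medians for homeolog vs non-homeolog inter-subgenome pairs), and
#'   `hierarchy_ok` (TRUE iff median intra >= same-subgenome >=
#'   cross-subgenome).
#' @export
median_by_class <- function(tab) {
  if (nrow(tab) == 0L) stop("empty table")
  coarse <- function(x) ifelse(startsWith(x, "inter_subgenome"),
                               "inter_subgenome", x)
  by_class <- tab[, .(n = .N, median = median(cpm)),
                  by = .(class_label = coarse(class_label))]
  by_pair <- tab[startsWith(class_label, "inter_subgenome"),
                 .(n = .N, median = median(cpm)), by = class_label]
  hom <- tab[!is.na(homeolog),
             .(n = .N, median = median(cpm)), by = homeolog]
  g <- function(cl) {
    v <- by_class[class_label == cl]$median
    if (length(v)) v else NA_real_
  }
  hier <- c(g("intra_chromosome"), g("inter_same_subgenome"),
            g("inter_subgenome"))
  hierarchy_ok <- !anyNA(hier) && !is.unsorted(rev(hier))
  list(by_class = by_class[order(-median)], by_subgenome_pair = by_pair,
       homeolog = hom, hierarchy_ok = hierarchy_ok)
}
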