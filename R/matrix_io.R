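#' Read / write sparse-triplet contact matrices
#'
#' Native text format: TSV with header `chrom1 start1 chrom2 start2 count`,
#' one row per unordered bin pair, 0-based half-open bin starts aligned to
#' the bin grid.  `read_matrix(write_matrix(m))` reproduces `m` exactly.
#'
#' @param m contact_matrix.
#' @param path file path.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix <- function(m, path) {
  b <- m$bins
  out <- m$pixels[, .(chrom1 = b$chrom[i], start1 = b$start[i],
                      chrom2 = b$chrom[j], start2 = b$start[j], count)]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname matrix_io
#' @param layout genome_layout the triplets must live on.
#' @return `read_matrix`: a raw contact_matrix.
#' @export
read_matrix <- function(path, layout) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("chrom1", "chrom2")))
  need <- c("chrom1", "start1", "chrom2", "start2", "count")
  if (!all(need %in% names(dt)))
    stop("format error: expected columns ", paste(need, collapse = ", "))
  bins <- bin_table(layout)
  bs <- layout$bin_size
  for (side in 1:2) {
    ch <- dt[[paste0("chrom", side)]]
    st <- dt[[paste0("start", side)]]
    bad <- which(!(ch %in% bins$chrom))
    if (length(bad))
      stop(sprintf("format error at line %d: unknown chromosome '%s'",
                   bad[1L] + 1L, ch[bad[1L]]))
    bad <- which(st %% bs != 0)
    if (length(bad))
      stop(sprintf(
        "format error at line %d: start %s is not a multiple of bin size %s",
        bad[1L] + 1L, format(st[bad[1L]]), format(bs)))
  }
  key <- bins[, .(chrom, start, idx)]
  dt <- key[dt, on = c(chrom = "chrom1", start = "start1")]
  setnames(dt, "idx", "i")
  dt <- key[dt, on = c(chrom = "chrom2", start = "start2")]
  setnames(dt, "idx", "j")
  if (anyNA(dt$i) || anyNA(dt$j))
    stop("format error: bin start beyond chromosome end")
  px <- dt[, .(i = pmin(i, j), j = pmax(i, j), count)]
  dup <- duplicated(px, by = c("i", "j"))
  if (any(dup)) {
    # symmetric duplicates with equal counts are still an error: the format
    # stores each unordered pair exactly once
    stop(sprintf("format error at line %d: duplicate unordered bin pair",
                 which(dup)[1L] + 1L))
  }
  contact_matrix(layout, px)
}

#' Write the ICE bias vector as TSV (chrom, start, end, bias; NA = masked)
#' @param m balanced contact_matrix.
#' @param path file path.
#' @export
write_bias <- function(m, path) {
  if (!m$balanced) stop("matrix is not balanced")
  fwrite(m$bins[, .(chrom, start, end, bias = m$bias)], path, sep = "\t")
  invisible(path)
}
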