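#' Genome layouts for binned polyploid contact matrices
#'
#' A genome layout records the chromosomes of a (possibly polyploid) genome
#' -- name, subgenome, homeolog group and length -- together with the bin
#' size used to grid the genome.  All coordinates in the package are 0-based
#' half-open; the last bin of a chromosome may be short.
#'
#' @param chroms data.frame/data.table with columns `name`, `subgenome`,
#'   `homeolog_group` (integer), `length` (bp).
#' @param bin_size bin width in bp (> 0).
#' @return An object of class `genome_layout`: a list with `chroms`
#'   (data.table) and `bin_size`.
#' @export
genome_layout <- function(chroms, bin_size) {
  chroms <- as.data.table(chroms)
  need <- c("name", "subgenome", "homeolog_group", "length")
  if (!all(need %in% names(chroms)))
    stop("layout chroms must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("invalid parameter: bin_size must be a positive number")
  if (any(chroms$length <= 0))
    stop("invalid parameter: chromosome lengths must be > 0")
  if (anyDuplicated(chroms$name))
    stop("invalid parameter: duplicated chromosome names")
  # each homeolog group has at most one chromosome per subgenome
  dup <- chroms[, .N, by = .(subgenome, homeolog_group)][N > 1L]
  if (nrow(dup) > 0L)
    stop("invalid parameter: homeolog group ", dup$homeolog_group[1L],
         " has more than one chromosome in subgenome ", dup$subgenome[1L])
  chroms <- copy(chroms)[, `:=`(
    name = as.character(name),
    subgenome = as.character(subgenome),
    homeolog_group = as.integer(homeolog_group),
    length = as.numeric(length)
  )]
  structure(list(chroms = chroms, bin_size = as.numeric(bin_size)),
            class = "genome_layout")
}

#' Build a regular polyploid genome layout
#'
#' Convenience constructor for the common simulation case: `n_subgenomes`
#' subgenomes (labelled "A", "B", ... by default), each with
#' `chroms_per_subgenome` chromosomes of identical length.  The homeolog
#' group of a chromosome is its ordinal within its subgenome, so chromosome
#' "1A" is homeologous to "1B" and "1D".
#'
#' @param n_subgenomes number of subgenomes (>= 1).
#' @param chroms_per_subgenome chromosomes per subgenome (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin width in bp.
#' @param subgenome_labels optional character vector of labels.
#' @return A [genome_layout()].
#' @examples
#' make_layout(3, 2, 10e6, 100e3)
#' @export
make_layout <- function(n_subgenomes, chroms_per_subgenome, chrom_length,
                        bin_size,
                        subgenome_labels = LETTERS[seq_len(n_subgenomes)]) {
  for (a in list(n_subgenomes, chroms_per_subgenome, chrom_length, bin_size))
    if (!is.numeric(a) || length(a) != 1L || a <= 0)
      stop("invalid parameter: all arguments must be positive numbers")
  if (length(subgenome_labels) != n_subgenomes)
    stop("invalid parameter: need one label per subgenome")
  chroms <- CJ(homeolog_group = seq_len(chroms_per_subgenome),
               subgenome = subgenome_labels, sorted = FALSE)
  setorder(chroms, subgenome, homeolog_group)
  chroms[, `:=`(name = paste0(homeolog_group, subgenome),
                length = as.numeric(chrom_length))]
  genome_layout(chroms[, .(name, subgenome, homeolog_group, length)],
                bin_size)
}

#' Bin table of a layout
#'
#' Tiles every chromosome with `bin_size` bins (last bin may be short) and
#' assigns a global 1-based bin index in chromosome order.
#'
#' @param layout a [genome_layout()].
#' @return data.table with columns `chrom`, `start`, `end`, `idx` (global),
#'   `pos` (0-based bin ordinal within chromosome), `nbins` (bins on that
#'   chromosome), `subgenome`, `homeolog_group`.
#' @export
bin_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  bs <- layout$bin_size
  bins <- layout$chroms[, {
    n <- as.integer(ceiling(length / bs))
    s <- (seq_len(n) - 1L) * bs
    .(start = s, end = pmin(s + bs, length), pos = seq_len(n) - 1L,
      nbins = n, subgenome = subgenome, homeolog_group = homeolog_group)
  }, by = .(chrom = name)]
  bins[, idx := .I]
  setcolorder(bins, c("chrom", "start", "end", "idx", "pos", "nbins",
                      "subgenome", "homeolog_group"))
  bins[]
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %d subgenome(s), bin %s bp\n",
              nrow(x$chroms), length(unique(x$chroms$subgenome)),
              format(x$bin_size, big.mark = ",")))
  print(x$chroms)
  invisible(x)
}
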