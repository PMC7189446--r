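#' Default pipeline configuration
#'
#' Returns the fixture-sized simulation configuration: 3 subgenomes x 2
#' chromosomes x 2 Mb at 25 kb, two conditions sharing the planted truth,
#' and the standard analysis thresholds (insulation window 100 kb,
#' calling threshold 0.4; loop thresholds p < 0.05, z > 1.5, FDR < 0.1;
#' DE p < 0.01).  Any element can be overridden before [run_pipeline()].
#'
#' @param seed integer seed; all randomness derives from it.
#' @param outdir output directory.
#' @return nested list (class `pipeline_config`).
#' @export
default_config <- function(seed = 1L, outdir = tempfile("territoria_run_")) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    layout = list(n_subgenomes = 3L, chroms_per_subgenome = 2L,
                  chrom_length = 2e6, bin_size = 25e3),
    sim = list(decay_exponent = 0.8, base_rate = 60, f_intra = 1,
               f_subgenome = 0.2, f_inter = 0.05, homeolog_factor = 2,
               rabl_strength = 1.5, n_domains = 5, domain_depletion = 0.3,
               loop_rate = 12, loop_fold = 8, min_loop_distance = 8),
    stages = list(simulate = TRUE, balance = TRUE, territories = TRUE,
                  insulation = TRUE, loops = TRUE, hichip = TRUE,
                  ledger = TRUE, coregulation = TRUE),
    territories = list(super_bin = 500e3),
    insulation = list(window = 100e3, threshold = 0.4, min_bins = 2L),
    loops = list(p_max = 0.05, z_min = 1.5, q_max = 0.1,
                 min_distance_bins = 2L),
    hichip = list(occupancy_boost = 5, thinning = 0.5),
    coregulation = list(de_p_max = 0.01, n_quantiles = 4L)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; missing elements fall back to [default_config()].
#' @return pipeline_config.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1L,
                        outdir = user$outdir %||% tempfile("territoria_run_"))
  merge_into <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  structure(merge_into(unclass(cfg), user), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on a simulated polyploid genome
#'
#' Executes the stages in dependency order -- simulate (two conditions from
#' one planted truth), ICE balance, territory statistics, insulation and
#' domain calling, intra-/inter-chromosomal loop calling in both
#' conditions, Hi-ChIP emulation, the gene-pair ledger, and the
#' coregulation regressions -- writing every artifact under
#' `config$outdir` and returning a manifest with an MD5 checksum per file.
#' Rerunning with the same config and seed reproduces identical checksums.
#'
#' @param config a `pipeline_config` (see [default_config()]).
#' @return list with `manifest` (data.table: stage, file, md5) and
#'   `results` (in-memory stage outputs); the manifest is also written to
#'   `<outdir>/manifest.tsv`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  st <- cfg$stages
  # dependency validation before any computation
  if (isTRUE(st$ledger) && !isTRUE(st$loops))
    stop("configuration error: ledger stage requires the loops stage")
  if (isTRUE(st$coregulation) && !isTRUE(st$ledger))
    stop("configuration error: coregulation stage requires the ledger stage")
  if (isTRUE(st$balance) && !isTRUE(st$simulate))
    stop("configuration error: no input matrix (enable simulate)")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  emit <- function(stage, file) manifest[[length(manifest) + 1L]] <<-
    data.table(stage = stage, file = basename(file),
               md5 = unname(md5sum(file)))

  layout <- make_layout(cfg$layout$n_subgenomes,
                        cfg$layout$chroms_per_subgenome,
                        cfg$layout$chrom_length, cfg$layout$bin_size)
  pa <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed)))
  sim_a <- simulate_contacts(layout, pa)
  pb <- do.call(sim_params, c(cfg$sim, list(seed = cfg$seed + 1L)))
  sim_b <- simulate_contacts(layout, pb, truth = sim_a$truth)
  gx <- simulate_genes_and_expression(layout, sim_a$truth, pa)
  genes <- gx$genes; truth <- gx$truth
  results$truth <- truth
  f <- file.path(cfg$outdir, "matrix_a.tsv")
  write_matrix(sim_a$matrix, f); emit("simulate", f)
  f <- file.path(cfg$outdir, "matrix_b.tsv")
  write_matrix(sim_b$matrix, f); emit("simulate", f)
  f <- file.path(cfg$outdir, "genes.bed")
  write_genes(genes, f); emit("simulate", f)
  emit("simulate", paste0(f, ".attrs.tsv"))

  if (isTRUE(st$balance)) {
    bal <- ice_normalize(sim_a$matrix)
    results$balanced <- bal
    f <- file.path(cfg$outdir, "bias_a.tsv")
    write_bias(bal, f); emit("balance", f)
  }

  if (isTRUE(st$territories)) {
    tab <- classify_and_aggregate(results$balanced,
                                  super_bin = cfg$territories$super_bin)
    med <- median_by_class(tab)
    ht <- homeolog_test(tab)
    results$territories <- list(medians = med, homeolog = ht)
    f <- file.path(cfg$outdir, "territory_classes.tsv")
    fwrite(med$by_class, f, sep = "\t"); emit("territories", f)
    f <- file.path(cfg$outdir, "territory_homeolog.tsv")
    fwrite(data.table(U = ht$U, p = ht$p, cliffs_delta = ht$cliffs_delta,
                      n_homeolog = ht$n1, n_other = ht$n2), f, sep = "\t")
    emit("territories", f)
  }

  if (isTRUE(st$insulation)) {
    track <- insulation_index(results$balanced,
                              window = cfg$insulation$window)
    doms <- call_domains(track, threshold = cfg$insulation$threshold,
                         min_bins = cfg$insulation$min_bins)
    track <- partition_deciles(track)
    results$insulation <- list(track = track, domains = doms)
    f <- file.path(cfg$outdir, "insulation.bedgraph")
    write_bedgraph(track, f); emit("insulation", f)
    f <- file.path(cfg$outdir, "domains.bed")
    write_domains_bed(doms, f); emit("insulation", f)
    f <- file.path(cfg$outdir, "deciles.bed")
    fwrite(track[!is.na(decile), .(chrom, start, end, decile)], f,
           sep = "\t", col.names = FALSE)
    emit("insulation", f)
  }

  if (isTRUE(st$loops)) {
    la <- call_loops_intra(sim_a$matrix, p_max = cfg$loops$p_max,
                           z_min = cfg$loops$z_min, q_max = cfg$loops$q_max,
                           min_distance_bins = cfg$loops$min_distance_bins)
    lb <- call_loops_intra(sim_b$matrix, p_max = cfg$loops$p_max,
                           z_min = cfg$loops$z_min, q_max = cfg$loops$q_max,
                           min_distance_bins = cfg$loops$min_distance_bins)
    cons <- conserved_loops(la, lb)
    inter <- call_interactions_inter(sim_a$matrix, p_max = cfg$loops$p_max,
                                     z_min = cfg$loops$z_min,
                                     q_max = cfg$loops$q_max)
    results$loops <- list(a = la, b = lb, conserved = cons, inter = inter)
    for (nm in c("a", "b", "conserved", "inter")) {
      f <- file.path(cfg$outdir, sprintf("loops_%s.bedpe", nm))
      write_bedpe(results$loops[[nm]], f); emit("loops", f)
    }
  }

  if (isTRUE(st$hichip)) {
    hic <- simulate_hichip(sim_a$matrix, genes,
                           occupancy_boost = cfg$hichip$occupancy_boost,
                           thinning = cfg$hichip$thinning,
                           seed = cfg$seed + 2L)
    results$hichip <- hic
    f <- file.path(cfg$outdir, "matrix_hichip.tsv")
    write_matrix(hic, f); emit("hichip", f)
  }

  if (isTRUE(st$ledger)) {
    pairs <- annotate_anchors(results$loops$conserved, genes)
    results$pairs <- pairs
    if (nrow(pairs)) {
      feats <- intersect(c("expressed", "H3K9ac", "H3K36me3", "H3K27me3",
                           "RNAPII"), sub("_[12]$", "",
                                          grep("_1$", names(pairs),
                                               value = TRUE)))
      led <- association_matrix(pairs, feats)
      results$ledger <- led
      f <- file.path(cfg$outdir, "association_ledger.tsv")
      fwrite(led$symmetrized, f, sep = "\t"); emit("ledger", f)
      conc <- tryCatch(expression_concordance(pairs,
                n_quantiles = cfg$coregulation$n_quantiles),
                error = function(e) NULL)
      if (!is.null(conc)) {
        results$concordance <- conc
        f <- file.path(cfg$outdir, "expression_concordance.tsv")
        fwrite(as.data.table(conc$counts), f, sep = "\t"); emit("ledger", f)
      }
      pc <- partner_counts(pairs)
      results$partners <- pc
      f <- file.path(cfg$outdir, "partner_counts.tsv")
      fwrite(pc$counts, f, sep = "\t"); emit("ledger", f)
      f <- file.path(cfg$outdir, "pair_table.tsv")
      fwrite(pairs, f, sep = "\t"); emit("ledger", f)
    }
  }

  if (isTRUE(st$coregulation)) {
    de_pairs <- select_de_pairs(results$pairs,
                                p_max = cfg$coregulation$de_p_max)
    results$de_pairs <- de_pairs
    if (nrow(de_pairs) >= 3L) {
      reg <- regress_pair_logfc(de_pairs)
      strat <- stratified_regression(de_pairs, "strength",
                                     cfg$coregulation$n_quantiles)
      results$coregulation <- list(pooled = reg, stratified = strat)
      f <- file.path(cfg$outdir, "coregulation.tsv")
      fwrite(rbind(reg, strat[, names(reg), with = FALSE]), f, sep = "\t")
      emit("coregulation", f)
    }
  }

  manifest <- rbindlist(manifest)
  f <- file.path(cfg$outdir, "manifest.tsv")
  fwrite(manifest, f, sep = "\t")
  list(manifest = manifest, results = results)
}
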