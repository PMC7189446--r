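# Shared setup for the numbered analysis scripts.  Run every script from
# the repository root:  Rscript analysis/01_simulate.R
suppressPackageStartupMessages({
  library(territoria)
  library(data.table)
})

SEED <- as.integer(Sys.getenv("TERRITORIA_SEED", "1"))
OUT <- "results/analysis"
DATA <- file.path(OUT, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

# the study genome: 3 subgenomes x 2 homeolog groups, 3 Mb chromosomes at
# 25 kb (120 bins each), condensed domains, loops shared by two conditions
study_layout <- function() make_layout(3, 2, 120 * 25e3, 25e3)

study_params <- function(seed = SEED) {
  sim_params(seed = seed, decay_exponent = 0.6, base_rate = 60,
             f_intra = 1, f_subgenome = 0.02, f_inter = 0.005,
             homeolog_factor = 2, rabl_strength = 1.5,
             n_domains = 8, domain_depletion = 0.3,
             loop_rate = 25, loop_fold = 8,
             min_loop_distance = 8, max_loop_distance = 40)
}
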