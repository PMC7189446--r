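---
title: "Methods: polyploid chromatin architecture from binned contact matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polyploid chromatin architecture from binned contact matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`territoria` re-implements, as a tested pipeline, the statistical core of a
chromatin-architecture analysis of an allohexaploid genome (three
subgenomes, homeologous chromosome groups): genome-territory interaction
statistics, insulation-index profiling with calling of condensed folding
domains (ICONS, *intergenic condensed spacers*), significance-based
chromatin-loop detection, a gene-pair epigenetic feature-association
ledger, and regressions testing whether loop-joined differentially
expressed (DE) gene pairs change expression concordantly between two
conditions.  Raw-read processing (alignment, valid-pair extraction, peak
calling, DE model fitting) is out of scope: binned contact matrices, peak
intervals and DE tables are inputs.

Because the original wheat-scale data require external accessions, every
method is validated against a synthetic polyploid generator that plants
each structure with known parameters; the contract of the package is
*parameter recovery under the planted conditions*, not reproduction of any
organism-specific census.

# The generative model

`simulate_contacts()` draws an independent Poisson count for every
unordered bin pair around a deterministic expectation:

* **Intra-chromosomal**: `mu(d) = base_rate * f_intra * (1 + d)^-alpha`,
  with `d` the bin separation.  `alpha` (dimensionless, default 1) is the
  power-law decay exponent; `base_rate` (counts per pair at `d = 1`) sets
  sequencing depth.
* **Inter-chromosomal**: `base_rate * f_subgenome` within a subgenome and
  `base_rate * f_inter` across subgenomes, multiplied by
  `homeolog_factor` (>= 1) on homeologous chromosome pairs and by
  `rabl_strength` (>= 1) on mirrored-position pairs (bin `i` against bin
  `N - 1 - i`), the anti-diagonal signature of the Rabl configuration.
  The invariant `f_intra >= f_subgenome >= f_inter > 0` makes the
  three-layer interaction hierarchy generative.

**Condensed domains.** Planted domains are *contact-enriched* interiors:
pairs with both ends in the same domain are multiplied by
`1/domain_depletion`, while pairs whose interval crosses a domain edge
(one end inside, or spanning the domain) are multiplied by
`domain_depletion` (< 1).  One knob therefore condenses the interior and
insulates the flanks, which is what the insulation-index caller assumes:
interiors score high, the flanking boundary bins are deep local minima
where the generator places genes.  A domain must be at least
`2 * window_bins + 1` bins long for its interior insulation windows to be
dominated by within-domain pairs; the generator enforces a minimum length
of 9 bins against the default 100-kb window at 25-kb bins.

**Loops.** `loop_rate` bin pairs with distinct anchors, separated by
`min_loop_distance`..`max_loop_distance` bins, get expectation
`mu(d) * lambda` (`loop_fold`), exempt from domain modulation so the
planted fold is the true enrichment.  Bounding the anchor separation keeps
the decay baseline at the loops in a chosen range (the loop-power
experiments use a baseline of roughly 20-28 counts per pair).

**Genes and expression** (`simulate_genes_and_expression()`): every
boundary and loop-anchor bin hosts a gene; domain interiors are gene-poor
(`domain_gene_prob`, default 0.05) and the remaining bins intermediate
(0.4).  Marks (H3K9ac, H3K36me3, H3K27me3, RNAPII, ATAC) are drawn
conditional on an active/repressed state with active/repressive
anti-correlation; a looped partner copies its mate's mark set with
probability `mark_concordance`.  Expressed genes draw log-normal TPM
(`meanlog = 3`, `sdlog = 1.2`) over two conditions x three replicates,
partner log-TPMs correlated at `tpm_pair_rho = 0.8`; a gene is *expressed*
iff the median TPM of its replicates is positive.  Partner log2 fold
changes follow `lfc2 = beta * lfc1 + eps`; the defaults `beta = 0.483`
with noise sd `0.884` give a population R^2 of 0.23, the coupling regime
the coregulation module is designed to detect.  Coupled genes get DE
p-value `1e-4` (below the 0.01 filter), uncoupled genes `p = 1`, so the
DE-filtering logic is exercised.

Counts are Poisson rather than negative binomial: the loop-significance
model downstream is a Poisson tail, and overdispersion is deliberately a
non-goal.  One integer seed drives each simulation; a second condition
re-draws counts around the same planted truth from `seed + 1`.

# Matrix processing

Matrices are symmetric sparse upper-triangle triplet tables on a 0-based
half-open bin grid (the native interchange format is a five-column TSV).
`ice_normalize()` iteratively divides each pair by the product of its two
bins' marginal sums rescaled to mean 1 until the coefficient of variation
of the non-masked marginals falls below `tol = 1e-5` (default cap 200
iterations).  Bins with zero coverage plus the lowest 2% by coverage are
masked (`mask_fraction = 0.02`; the choice is documented, not inherited
from any upstream tool).  The bias vector satisfies
`balanced(i,j) = raw(i,j) / (bias_i * bias_j)` exactly, and the final
rescaling preserves the mean marginal of the retained bins, so totals are
comparable before and after balancing.

`decay_profile()` reports mean, SD and pair count of the intra-chromosomal
contact per bin separation, counting implicit zero pairs; it underlies
both the expected model of the loop caller and the decay-exponent
recovery tests.

# Territory statistics

`classify_and_aggregate()` sums balanced counts into 10-Mb super-bins
(never across chromosomes; trailing short super-bins are retained),
rescales to counts per million of the aggregated total, and labels each
unordered super-bin pair intra-chromosome, inter-same-subgenome, or
inter-subgenome (with the subgenome pair); inter-subgenome pairs carry a
homeolog flag when the chromosomes share a homeolog group.  Super-bin
self-pairs are kept in the intra class: the upstream description of
"interactions between 10-Mb bins" is ambiguous on this point, and keeping
them makes the intra class describe the full within-chromosome signal.
"Interaction frequency" is defined as CPM of ICE-balanced counts - a
documented, monotone-equivalent stand-in for an upstream tool's unstated
normalisation.

`mann_whitney_u()` uses exact enumeration of all labelings for
`n1 + n2 <= 12` (ties contribute 1/2) and the tie-corrected normal
approximation with continuity correction otherwise; `cliffs_delta()` is
the exact pairwise dominance statistic, so `delta = 2U/(n1 n2) - 1` on
tie-free data.  Both are cross-checked against `stats::wilcox.test()` in
the tests.

The territory recovery experiments use a deliberately shallow decay
(`alpha = 0.1`) so that, at the super-bin scale, the class factors - set
to the 8:4:1 hierarchy with a homeolog factor of 2 - dominate the medians;
with a steep decay the long-range intra signal would fall below a large
`f_subgenome`, which is a property of the synthetic class
parameterisation, not of the statistics.  The analysis fixture instead
uses realistic small inter levels (`f_subgenome = 0.02`,
`f_inter = 0.005` of base) under `alpha = 0.6`, where the hierarchy also
holds.

# Insulation and ICONS

For bin `i`, the raw insulation is the mean balanced contact over the
`w x w` square straddling the bin (`w = window/bin_size`; default 100 kb
at 25-kb bins), defined only where the square fits inside the chromosome
and at least half of its entries are non-masked.  The score is
`log2(raw_i / chromosome mean of defined raws)`, so scores are centred per
chromosome and *negative* means insulated.  The exact windowing variant of
the upstream tool is not printed in its reference; this square-window,
log2-to-chromosome-mean form is adopted and the contract is recovery of
planted structure, not value matching.  Whether the upstream 0.4 calling
threshold applied to normalised or raw values is likewise unstated;
normalised is assumed.

`call_domains()` returns maximal runs of at least `min_bins = 2`
consecutive defined bins with score >= 0.4 - the condensed, gene-poor
interiors.  `call_boundaries()` returns the (possibly tied) local minima
of the score below 0; on the synthetic genomes these land on the planted
boundary bins (recovery >= 90% within one bin), while the *edges* of the
called runs sit systematically ~`w - 1` bins inside the planted edges
because edge bins mix within- and cross-domain pairs in their windows.
Boundary recovery is therefore evaluated against the minima, matching the
field's definition of a boundary as an insulation minimum.

`partition_deciles()` ranks defined bins by score (ties broken by genomic
order), spreading the remainder over the lowest deciles (25 bins give
sizes 3,3,3,3,3,2,2,2,2,2); decile 1 is most insulated.  `assign_genes()`
maps a gene to the bin covering >= 50% of it, a 50/50 split going to the
left bin.  `metaprofile()` rescales region bodies to a fixed number of
meta-bins with fixed-width flanks (2 kb by default), reverses minus-strand
regions, treats uncovered base pairs as signal 0, and summarises across
regions with the median (the mean is available); profiles over gene
classes (marked vs unmarked, expressed vs not, insulation deciles) are
built by `insulation_over_genes()`.

# Loop significance

`call_loops_intra()` tests every intra-chromosomal pair at separation
>= 2 bins (diagonal and adjacent bins excluded to avoid trivial
self-interaction calls) against
`expected(i,j) = decay_mean(d) * cov_i * cov_j / mean_cov^2`,
a transparent coverage x distance-decay model standing in for the cited
tool's unpublished background.  The score is `z = (obs - exp)/sqrt(exp)`,
the p-value the upper Poisson tail, and FDR control is Benjamini-Hochberg
(the upstream report names only "FDR"; BH is adopted) pooled per
resolution and per kind (intra vs inter), genome-wide.  A loop must pass
all three of `p < 0.05`, `z > 1.5`, `q < 0.1` - thresholds taken verbatim
from the study design, with resolutions of 20 kb (gene-to-gene loops),
25 kb (RNAPII Hi-ChIP loops) and 50 kb (interchromosomal contacts).
`call_interactions_inter()` uses the coverage-product expectation
`2 * cov_i * cov_j / T`; the factor 2 reflects unordered-pair counting
and is documented so results are bit-reproducible.
`conserved_loops()` matches loops across conditions by >= 1 bp overlap of
both anchors in canonical order (works across resolutions) and attaches
the partner condition's z (maximum over multiple matches).

Null simulations keep the false-call count within the BH bound at
q = 0.1; planted five-fold loops on a ~20-count baseline are recovered
with sensitivity >= 0.9 and empirical false-discovery proportion <= 0.15,
and power is monotone in the planted fold.

# Gene-pair ledger

`annotate_anchors()` joins each loop anchor to genes by any overlap
(>= 1 bp), drops loops with a gene-less anchor, emits all cross
combinations, removes self-pairs, and orients intra pairs genomically
(gene1 upstream; inter pairs by chromosome name).  The 2x2 feature
association counts pairs by (feature on gene1) x (feature on gene2):
odds ratio `ad/bc` with the Haldane-Anscombe +0.5 on all cells iff any
cell is zero (needed for a finite log2 OR; the upstream text is silent on
zero cells), chi-square without continuity correction, and Cramer's V
`sqrt(chi2/n)`.  Because the orientation of "first" vs "second" gene is
not defined upstream and the published association heatmap is
near-symmetric, `association_matrix()` emits both the raw ledger and a
symmetrized one in which every unordered pair contributes both
orientations.

`expression_concordance()` restricts to pairs expressed on both sides,
computes quantile breaks independently per side (rank-based, left-closed,
ties to the lower quantile - bit-reproducible), and reports the count
matrix and diagonal fraction (quartiles for loops, deciles for
interchromosomal contacts).  `partner_counts()` counts distinct partners
per gene and the fractions with >= 4 and >= 10 partners.
`read_pair_table()` ingests an externally deposited pair table through a
configurable column mapping, converting 0/1 flag columns to logicals, so
the same ledger statistics can be recomputed on published tables when
they are available locally.

# Coregulation

`select_de_pairs()` keeps pairs on conserved loops whose two genes are
both DE at `p < 0.01`; pairs missing a fold change are dropped with a
warning count.  `regress_pair_logfc()` is ordinary least squares of the
second gene's log2 fold change on the first's, reporting slope,
intercept, R^2 and the F-test p-value on (1, n-2) df; the F p equals the
squared-t p and is invariant to swapping predictor and response (both
asserted).  `stratified_regression()` fits one regression per
loop-strength quartile combination (quartiles of z computed independently
per condition) or per distance quartile; cells with n < 3 are reported as
absent.  Pairs sharing a gene are kept as independent observations,
matching pair-wise tabulation upstream; the orientation choice
(upstream gene as predictor) is fixed for reproducibility and the swapped
fit is available by renaming columns.

Under the planted conditions - 1659 DE pairs at coupling 0.483 with noise
tuned to R^2 0.23, and a strength gradient from 0.2 (weak/weak) to 0.9
(strong/strong) - the recovered slopes are within ±0.05 and ±0.07 of the
planted values respectively.

# Pipeline, problem sizes, determinism

`run_pipeline()` executes simulate → balance → territories + insulation +
loops (+ Hi-ChIP) → ledger → coregulation from one configuration (R list
or YAML), validating stage dependencies before any computation, writing
every artifact (triplet TSV, bedGraph, BED, BEDPE, TSV tables) into a
write-once output directory and returning a manifest with an MD5 checksum
per file; the same config and seed reproduce identical checksums.  The
default fixture - 3 subgenomes x 2 chromosomes x 2 Mb at 25 kb - runs in
seconds.  The test suite and acceptance script use fixture-sized genomes
(120-180 bins per chromosome, 10-20 replicate seeds) chosen so every
recovery experiment has clear statistical margin while a full run stays
in the minutes range on one CPU.

# What passing tests do and do not show

The generator emulates hierarchical territory enrichment, the Rabl
anti-diagonal, condensed gene-poor domains with gene-rich boundaries,
gene-to-gene loops with concordant marks/expression, and two-condition
fold-change coupling.  It does not emulate restriction-fragment geometry,
ligation artifacts, copy-number or mappability biases, negative-binomial
overdispersion, or cell-to-cell heterogeneity.  Recovery under these
conditions therefore validates the statistical machinery - balancing,
scoring, thresholds, FDR control, ledger arithmetic - not the biological
completeness of any real dataset; organism-scale censuses (loop counts,
domain counts, effect sizes) require the original accessions and are
deliberately not reproduced.

# Known limitations

* The insulation caller reports run *interiors*; boundary localisation is
  via score minima, and run edges are biased inward by about the window
  size (documented above).
* The Poisson tail is anti-conservative under overdispersed real data;
  on such data the q-value threshold controls a nominal, not empirical,
  FDR.
* Exact Mann-Whitney enumeration is limited to `n1 + n2 <= 12` by design;
  beyond that the tie-corrected normal approximation is used.
* `expression_concordance()` marginals are balanced only up to ties and
  remainder; heavily tied TPM vectors can unbalance the quantile
  occupancy (all-identical TPMs are rejected).
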