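---
title: "Models and methods behind plateseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plateseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateseq)
```

# The assay this package processes

Pooled, well-barcoded 3'-end RNA-Seq screens profile every well of a
multi-well plate in a single sequencing library. Each well's cDNA carries a
well-identifying DNA barcode read out as read 1 (the barcode followed by
the oligo(dT) tract), while read 2 is a short fragment from the 3' end of a
transcript. Wells hold drug-treated or vehicle-control (DMSO) cells, with
replicates per condition. The computational work is therefore:
demultiplexing reads to wells through an error-tolerant barcode code,
turning transcriptome alignments into per-gene counts under a
unique-mapping rule, and summarising perturbation effects as signatures,
protein activities and replicate-noise statistics.

`plateseq` implements that processing plus a complete synthetic-run
simulator, so every stage is exercised and validated end-to-end with no
external sequencing data.

# Well barcodes as an error-correcting code

Barcodes are fixed-length DNA words (default $k = 8$) with minimum
pairwise Hamming distance $d \ge 3$. A distance-3 code corrects any single
substitution: the Hamming balls of radius 1 around codewords are disjoint,
so an observed word within distance 1 of a codeword identifies it
uniquely. `design_barcode_set()` uses seeded greedy random accumulation
(propose random $k$-mers, keep those at distance $\ge d$ from all kept
words) with a homopolymer-run filter ($\le 3$ identical bases) for
sequencer robustness; any valid code passes the independent brute-force
validation in `validate_barcode_set()`. Feasibility is pre-checked against
the sphere-packing bound $4^k / \sum_{i \le t}\binom{k}{i}3^i$,
$t = \lfloor (d-1)/2 \rfloor$.

Decoding (`correct_barcode()`, vectorised in `assign_wells()`) allows an
edit distance of one. We interpret "edit distance" as Hamming distance on
the fixed-length prefix by default, since substitutions dominate on
short-read sequencers and the barcode field has fixed length; an optional
Levenshtein mode compares prefixes of length $k-1$, $k$, $k+1$ and allows
one indel. Reads within range of two or more barcodes (possible only if
$d < 3$, or via indels) are conservatively discarded as ambiguous.

# The unique-mapping counting rule

Read 2 maps strand-specifically: a genuine fragment aligns to the
transcript's sense strand. A read is counted for a gene if and only if the
maximum alignment score among its sense-strand alignments belongs to
transcripts of exactly one gene. Isoform ties within a gene therefore
still count; ties spanning genes are discarded (no multi-mapping rescue),
antisense-only reads are discarded, and spike-in transcripts are tallied
in a separate block, never as genes. Reads are counted, not
deduplicated — the protocol has no UMIs. Ties between a gene and a
spike-in at the same score are discarded and logged separately.

Alignments are consumed from SAM/BAM (scores from the `AS` tag, falling
back to CIGAR match length); `pseudo_align()` is a deliberately small
exact-seed, ungapped matcher used so the test suite and simulator need no
external aligner. It is not a replacement for a production aligner — it
seeds at three fixed read offsets on both strands and extends without
gaps — but on simulated reads its top hit is provably the true transcript,
which is all the counting rule needs.

# The simulator and its ground truth

The simulator emulates the structure of a 96-well screen: 8-base
distance-3 barcodes, 7 drugs plus vehicle at 12 replicates, 26-cycle
read 1 / 66-cycle read 2, and negative-binomial counts.

* **Counts.** Gene baseline means are drawn log-normally around
  `base_mean`; a perturbed well multiplies targeted genes' means by
  $2^{\mathrm{lfc}}$. Counts are NB with dispersion $\alpha$
  ($\mathrm{Var} = \mu + \alpha\mu^2$; $\alpha = 0$ gives Poisson), then
  rescaled to exactly `reads_per_well` total reads per well by multinomial
  thinning, mirroring fixed sequencing depth. The Poisson-limit
  (variance/mean $\to$ 1) behaviour holds in the thinning regime,
  i.e. when `reads_per_well` is well below the raw NB total.
* **Reads.** Fragment starts are uniform over the 3'-most `frag_window`
  bases (default 250 bp). Real 3' libraries have an empirical positional
  bias that is not publicly characterised for this protocol; the uniform
  window is a stated stand-in. Substitution errors are i.i.d. per base;
  indel errors, quality-score structure and flow-cell effects are not
  modelled. Quality strings are constant and nothing downstream reads
  them.
* **Truth.** Per-read well and transcript of origin, expected NB means and
  realized counts are all recorded, enabling exact end-to-end checks: with
  zero error rate, demultiplexing plus the built-in matcher plus the
  counting rule reproduce the realized count matrix entry for entry.

Passing these tests shows the pipeline implements its stated rules
exactly on data matching its assumptions; it does not certify behaviour
on real libraries (adapter contamination, polyA mispriming, genomic DNA,
positional bias), which only real data can probe.

Perturbations act either on explicit gene sets or through a regulon
(`regulon_perturbation()`): each target is shifted by
$\mathrm{lfc} \times \mathrm{mode}$, so repressed targets move against
the regulator — the pattern protein-activity inference should recover.

# Expression, signatures and MDS

Size factors are median-of-ratios: for sample $j$,
$s_j = \mathrm{median}_g (x_{gj} / \tilde{x}_g)$ over genes positive in
all samples, with $\tilde{x}_g$ the geometric mean, rescaled so the
factors have geometric mean 1 (so on the `(c, 2c)` two-column toy they are
exactly $(1/\sqrt 2, \sqrt 2)$). The variance-stabilising transform is the
closed form $\log_2(x_{gj}/s_j + 1)$ — a documented stand-in for a fitted
dispersion-based VST: the downstream steps need only a depth-normalised,
variance-stabilised log scale, and the closed form is dependency-free and
exactly invertible in tests. The transform name is recorded in the
matrix's attributes.

Signatures subtract the row-wise mean of the vehicle columns from every
column; vehicle columns are kept as residuals. The vehicle-column mean is
zero by construction; in floating point we refine the subtraction until
the residual is below one unit in the last place (~1e-17 for typical
scales — extended-precision accumulation in `rowMeans` makes a bit-exact
zero unattainable, and we treat anything at or below machine epsilon as
zero).

Top-$k$ differential features rank by the absolute mean signature across
a condition's replicates (default $k = 40$), with ties broken
deterministically by identifier. Sample maps use classical (Torgerson)
MDS on Euclidean distances via `stats::cmdscale`; for genuinely
low-dimensional input the embedding reproduces coordinates up to
rotation/reflection (verified by Procrustes residual), and negative
eigenvalues beyond tolerance trigger a non-Euclidean warning.

# Protein activity: simplified two-tail regulon enrichment

Each signature column is rank-transformed to normal quantile scores
$q_g = \Phi^{-1}((r_g - 1/2)/n)$ with average ranks for ties. For a
regulon with target modes $m_i \in [-1, 1]$ and likelihood weights
$w_i \in (0, 1]$, the normalised enrichment score is

$$\mathrm{NES} = \frac{\sum_i w_i m_i q_i}{\sqrt{\sum_i w_i^2 m_i^2}},$$

which is exactly $N(0,1)$ when the $q_i$ are i.i.d. standard normal. This
is a deliberate simplification of the published three-tail VIPER/aREA
family: no three-tail integration, pleiotropy or shadow correction
(output metadata labels it `aREA-2T-simplified`). Targets absent from the
signature are dropped; below a minimum effective size (default 10
targets) the entry is flagged `NA` rather than reported. A permutation
oracle (`nes_permutation_oracle()`) validates the analytic null: because
rank-derived scores are a fixed finite population, permutation nulls
carry a finite-population correction of order $\sqrt{(n-m)/(n-1)}$, which
is why oracle agreement is asserted to 0.15 rather than machine
precision. At the defaults used in the tests ($n \ge 500$, $m \approx
25$) the discrepancy is a few percent of one NES unit.

# QC, saturation and replicate noise

Genes detected per well counts genes at or above a threshold (default 1
read), excluding spike-ins. Saturation curves subsample the uniquely
mapped count columns — a multivariate hypergeometric draw, exactly
equivalent to uniform subsampling of the underlying read multiset — at a
fraction grid (default 0.1–1.0, 10 repetitions), reporting the mean over
wells and repetitions with the s.e.m. across wells. We subsample uniquely
mapped counts rather than raw reads: detection depends only on the
counts, and the distinction from raw-read subsampling is a documented
operational choice.

Replicate noise follows the duplicate-pair methodology: per gene and
duplicate pair, the mean and the sample CV ($n-1$ denominator, i.e.
$|x_1 - x_2|/(\sqrt2\,\bar x)$), averaged across pairs where defined;
zero-mean pairs are excluded and visible in the per-gene pair count.
Note a statistical subtlety: the expected sample CV of two replicates is
$c_4(2) = \sqrt{2/\pi} \approx 0.798$ times the population CV, so the
paper-style mean CV systematically sits below the generative CV. The
table therefore also reports `cv_rms` (root mean squared CV), and the
mean-CV law of the NB model — population CV $= \sqrt{1/\mu + \alpha}$ —
is checked with the consistent pooled estimator
$\sqrt{\overline{s^2}}/\bar{\mu}$. CVs default to size-factor-normalised
linear counts. Fold-change distributions are $\log_2$ ratios to the
vehicle-column mean with a pseudocount (default 0.5) guarding zeros.

# Pipeline, configuration and determinism

`run_pipeline()` chains every stage under a layered YAML configuration
(`default_config()` documents each parameter), writes text tables only,
logs JSON lines, and records a manifest with md5 checksums plus a
resolved copy of the configuration. A rerun with an unchanged
configuration and intact outputs skips all stages. All randomness derives
from one master seed through fixed per-stage offsets, so a fixed
configuration yields byte-identical numeric tables across runs. The
`plateseq` script under the package's `exec/` directory exposes the same
operations as shell subcommands.

Default simulation sizes (60 genes, 2 000 reads per well in the pipeline
defaults; up to 50 genes x 96 wells x 2x10^5 reads and 100-replicate
recovery studies in the validation suite) are chosen so the whole
validation runs in minutes on one core while keeping every statistical
check well-powered; they are desk-scale stand-ins for production depths
(hundreds of thousands of uniquely mapped reads per well).

# Known limitations

* The matcher is test-grade; production use should feed `bwa-mem`-style
  SAM/BAM into `read_alignments()`. The counting rule sees only the
  alignments the aligner reports, so secondary-alignment reporting
  settings affect multi-gene discards.
* The VST is not a fitted-dispersion transform; differential-expression
  testing is intentionally out of scope (external DE results can drive
  gene selection for MDS).
* The activity statistic is the two-tail simplification described above;
  its NES values are not numerically comparable to full three-tail
  implementations.
* The simulator's uniform 3' window, substitution-only errors and
  constant qualities idealise real libraries.
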