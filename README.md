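# plateseq

Processing toolkit for pooled, well-barcoded 3'-end RNA-Seq screens — the
assay family in which every well of a multi-well plate (drug-treated and
vehicle-control cells) is tagged with a well barcode on read 1 and pooled
into a single 3'-biased sequencing library. The package covers the full
computational path from raw paired reads to biological summaries, plus a
synthetic-run simulator with complete ground truth so that every stage can
be validated without external sequencing data.

It is aimed at people building or auditing plate-screen pipelines:
computational biologists processing such screens, and method developers who
need a transparent, fully testable reference implementation.

## What it computes

* **Barcode design and decoding.** Fixed-length DNA well barcodes with
  guaranteed minimum pairwise Hamming distance *d* ≥ 3 form a
  single-error-correcting code; decoding allows an edit distance of one and
  is exact by construction (any word within distance 1 of a codeword
  decodes uniquely). Feasibility is checked against the sphere-packing
  bound 4^k / Σ_{i≤t} C(k,i)·3^i.
* **Unique-mapping gene counting.** A read counts for a gene iff the
  maximum alignment score among its sense-strand alignments belongs to a
  single gene; isoform ties count, cross-gene ties and antisense-only reads
  are discarded, spike-ins are tallied separately. Alignments come from
  SAM/BAM, or from a built-in exact-seed matcher for self-contained runs.
* **QC and saturation.** Genes detected per well and subsampling saturation
  curves (multivariate hypergeometric draws on the count columns).
* **Signatures and MDS.** Median-of-ratios size factors, closed-form
  log2 VST, per-sample signatures referenced to the vehicle-control mean,
  top-k differential selection, and classical (Torgerson) MDS.
* **Protein activity.** Simplified two-tail weighted regulon enrichment:
  per-sample NES = Σ wᵢmᵢqᵢ / √(Σ wᵢ²mᵢ²) over rank-quantile scores
  qᵢ = Φ⁻¹((rᵢ−½)/n), exactly N(0,1) under the i.i.d. null, with a
  permutation oracle validating the analytic null.
* **Replicate noise.** Per-gene CV vs mean expression across duplicate
  pairs and perturbation-vs-vehicle fold-change distributions.

See `vignettes/plateseq-methods.Rmd` for the models, parameter meanings and
numerical choices.

## Worked example

A self-contained screen: 96 wells (one drug acting through a regulon,
plus DMSO), simulated reads with 1% substitution errors, demultiplexed,
counted, and pushed through signatures to protein activity.

```r
library(plateseq)

bs <- design_barcode_set(n = 96, k = 8, min_distance = 3, seed = 1)
bs
#> BarcodeSet: 96 barcodes, k = 8, min Hamming distance >= 3

tx   <- simulate_transcriptome(n_genes = 50, iso_per_gene = 2, seed = 1)
regs <- simulate_regulons(unique(unname(tx$tx2gene)),
                          n_regulons = 10, targets_per = 12, seed = 2)
conds <- list(DMSO  = perturbation(),
              drug1 = regulon_perturbation(regs[[1]], -1.5))
plate <- make_plate_design(conds, replicates = 12)
truth <- simulate_counts(tx, plate, base_mean = 50,
                         reads_per_well = 2000, seed = 3)
run   <- simulate_run(truth, tx, bs, plate, sub_error_rate = 0.01, seed = 4)

wa <- assign_wells(run$read1, bs)
sprintf("assigned %d of %d reads (%.3f)",
        wa$stats$assigned, wa$stats$total, wa$stats$assigned / wa$stats$total)
#> "assigned 47886 of 48000 reads (0.998)"

aln <- pseudo_align(run$read2, tx)
cm  <- count_unique(aln, wa, tx$tx2gene,
                    well_labels = bs$well_labels, n_wells = 96)
cm
#> CountMatrix: 50 genes x 96 wells; 47759 uniquely mapped reads

sig <- signature(vst(cm$counts[, plate$wells$well_label]), plate)
act <- activity_matrix(sig, regs, min_size = 10)
treated <- plate$wells$well_label[!plate$wells$is_vehicle]
sort(rowMeans(act[, treated]))[1:3]
#>     REG001     REG005     REG009
#> -4.9181111 -0.7836814 -0.3152218
```

The assigned fraction 0.998 matches the closed form
(1−r)⁸ + 8r(1−r)⁷ = 0.9973 for r = 0.01 up to sampling error (reads with
two or more barcode errors are dropped rather than guessed). The planted
regulator `REG001` is recovered as by far the most deactivated protein
(mean NES ≈ −4.9 across treated wells): its targets were shifted
mode-aligned by −1.5 log2 units, and the activity statistic aggregates
those shifts while the other regulons stay near the N(0,1) null.

An end-to-end run with one command, writing every table plus a checksum
manifest into an output directory:

```r
run_pipeline(NULL, "outdir")          # defaults; or a YAML/config list
```

or from the shell via the installed CLI:

```sh
Rscript <library>/plateseq/exec/plateseq pipeline -o outdir
Rscript <library>/plateseq/exec/plateseq design-barcodes --n 96 --k 8 \
    --min-dist 3 --seed 1 -o barcodes.tsv
```

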