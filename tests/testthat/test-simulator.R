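test_that("simulated transcriptomes have consistent structure and are seed-stable", {
  tx <- simulate_transcriptome(50, 2, c(300, 1000), seed = 3)
  expect_length(tx$seqs, 100)
  expect_identical(sort(names(tx$seqs)), sort(names(tx$tx2gene)))
  expect_length(unique(unname(tx$tx2gene)), 50)
  expect_true(all(grepl("^[ACGT]+$", tx$seqs)))
  expect_true(all(nchar(tx$seqs) >= 300 & nchar(tx$seqs) <= 1000))
  one <- simulate_transcriptome(1, 1, c(300, 400), seed = 1)
  expect_length(one$seqs, 1)
  expect_identical(unname(one$tx2gene), "G0001")
  ## byte-identical FASTA for a repeated seed
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_transcriptome(simulate_transcriptome(20, 2, seed = 7), f1, t1)
  write_transcriptome(simulate_transcriptome(20, 2, seed = 7), f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_transcriptome(5, 1, c(50, 100), read_length = 66),
               "below the read length")
})

test_that("transcriptomes round-trip through FASTA + tx2gene TSV", {
  tx <- simulate_transcriptome(10, 2, c(300, 500), n_spikes = 3, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fa")
  t2g <- withr::local_tempfile(fileext = ".tsv")
  write_transcriptome(tx, fa, t2g)
  tx2 <- read_transcriptome(fa, t2g)
  expect_identical(tx2$seqs, tx$seqs)
  expect_identical(tx2$tx2gene, tx$tx2gene)
  expect_identical(tx2$spike_ins, tx$spike_ins)
})

test_that("plate designs enforce vehicle and barcode-uniqueness invariants", {
  conds <- list(DMSO = perturbation(),
                drugA = perturbation(c(G0001 = 2)))
  plate <- make_plate_design(conds, replicates = 12)
  expect_identical(nrow(plate$wells), 24L)
  expect_identical(sum(plate$wells$is_vehicle), 12L)
  expect_false(anyDuplicated(plate$wells$barcode_index) > 0)
  expect_error(make_plate_design(list(DMSO = perturbation(c(G0001 = 1)),
                                      d = perturbation())),
               "empty target map")
})

test_that("NB count simulation plants effects at the stated magnitude", {
  sc <- tiny_screen(n_genes = 40, replicates = 12, lfc = c(drugA = 2),
                    seed = 21)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 100,
                           dispersion = 0.05, reads_per_well = 20000,
                           seed = 22)
  ## realized columns sum to the per-well read budget exactly
  expect_true(all(colSums(truth$realized_counts) == 20000))
  ## expected means: perturbed well mean = base mean x 2^lfc
  wA <- sc$plate$wells$well_label[sc$plate$wells$condition == "drugA"]
  wV <- sc$plate$wells$well_label[sc$plate$wells$is_vehicle]
  g <- sc$genes[1]
  expect_equal(truth$expected_counts[g, wA[1]] / truth$expected_counts[g, wV[1]],
               4, tolerance = 1e-12)
  ## realized ratio approx 4 within 3 s.e. across 12+12 replicates
  rA <- truth$realized_counts[g, wA]
  rV <- truth$realized_counts[g, wV]
  ratio <- mean(rA) / mean(rV)
  se <- ratio * sqrt(stats::var(rA) / (12 * mean(rA)^2) +
                     stats::var(rV) / (12 * mean(rV)^2))
  expect_lt(abs(ratio - 4), 3 * se + 1e-9)
})

test_that("null plates are exchangeable and the Poisson limit holds", {
  ## reads_per_well well below the raw NB total so the multinomial rescale
  ## is a true thinning (the Poisson-limit regime)
  sc <- tiny_screen(n_genes = 50, replicates = 12, lfc = c(drugA = 0),
                    seed = 31)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 50, dispersion = 0,
                           reads_per_well = 250, mean_sdlog = 0, seed = 32)
  ## all expected means equal across wells when no effect is planted
  expect_true(all(truth$expected_counts == truth$expected_counts[, 1]))
  ## per-gene means agree across the two conditions within Monte-Carlo error
  wA <- sc$plate$wells$well_label[sc$plate$wells$condition == "drugA"]
  wV <- sc$plate$wells$well_label[sc$plate$wells$is_vehicle]
  mA <- rowMeans(truth$realized_counts[, wA])
  mV <- rowMeans(truth$realized_counts[, wV])
  se <- sqrt((apply(truth$realized_counts[, wA], 1, var) +
              apply(truth$realized_counts[, wV], 1, var)) / 12)
  expect_true(all(abs(mA - mV) <= 4 * se + 1e-9))
  ## dispersion 0: variance/mean near 1 across replicate wells
  vm <- apply(truth$realized_counts[, c(wA, wV)], 1, var) /
    rowMeans(truth$realized_counts[, c(wA, wV)])
  expect_lt(abs(mean(vm) - 1), 0.15)
})

test_that("error-free runs emit decodable barcodes and exact 3' fragments", {
  sc <- tiny_screen(n_genes = 20, replicates = 3, seed = 41)
  bs <- design_barcode_set(nrow(sc$plate$wells), 8, 3, seed = 42)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 30,
                           reads_per_well = 800, seed = 43)
  run <- simulate_run(truth, sc$tx, bs, sc$plate, sub_error_rate = 0,
                      seed = 44)
  expect_identical(sort(run$per_read$read_id), sort(names(run$read1)))
  ## read 1 = barcode + oligo(dT) fill, 26 cycles
  expect_true(all(nchar(run$read1) == 26))
  bc_field <- substr(run$read1, 1, 8)
  expect_identical(unname(bc_field),
                   unname(bs$sequences[run$per_read$well_index]))
  ## every read 2 is an exact sense substring within the 3' window
  idx <- seq_len(min(500, length(run$read2)))
  hit <- vapply(idx, function(i) {
    s <- sc$tx$seqs[[run$per_read$transcript_id[i]]]
    p <- regexpr(run$read2[[i]], s, fixed = TRUE)[1]
    p > 0 && (nchar(s) - (p + 66 - 1)) < 250
  }, logical(1))
  expect_true(all(hit))
  ## determinism
  run2 <- simulate_run(truth, sc$tx, bs, sc$plate, sub_error_rate = 0,
                       seed = 44)
  expect_identical(run$read1, run2$read1)
  expect_identical(run$read2, run2$read2)
  expect_error(simulate_run(truth, sc$tx, bs, sc$plate, frag_window = 50),
               "frag_window")
})

test_that("spike-in reads carry their flag through the per-read truth", {
  sc <- tiny_screen(n_genes = 10, replicates = 2, n_spikes = 2, seed = 51)
  bs <- design_barcode_set(nrow(sc$plate$wells), 8, 3, seed = 52)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 50,
                           reads_per_well = 1000, seed = 53)
  run <- simulate_run(truth, sc$tx, bs, sc$plate, seed = 54)
  sp_reads <- run$per_read[run$per_read$transcript_id %in% sc$tx$spike_ins, ]
  expect_gt(nrow(sp_reads), 0)
  expect_true(all(sp_reads$transcript_id %in% sc$tx$spike_ins))
})

test_that("FASTQ output round-trips reads and ids", {
  reads <- c(r1 = "ACGTACGT", r2 = "TTTTCCCC")
  f <- withr::local_tempfile(fileext = ".fastq.gz")
  write_fastq(reads, f)
  back <- plateseq:::as_read_vector(f)
  expect_identical(back, reads)
})
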