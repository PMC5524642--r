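test_that("well assignment decodes error-free runs completely and exactly", {
  sc <- tiny_screen(n_genes = 12, replicates = 2, seed = 71)
  bs <- design_barcode_set(nrow(sc$plate$wells), 8, 3, seed = 72)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 30,
                           reads_per_well = 400, seed = 73)
  run <- simulate_run(truth, sc$tx, bs, sc$plate, sub_error_rate = 0,
                      seed = 74)
  wa <- assign_wells(run$read1, bs)
  expect_identical(wa$stats$assigned, wa$stats$total)
  expect_identical(wa$stats$unassigned + wa$stats$ambiguous, 0L)
  ## every decode hits the true well at distance 0
  m <- merge(wa$assignments, run$per_read, by = "read_id")
  expect_true(all(m$well_index.x == m$well_index.y))
  expect_true(all(m$distance == 0L))
})

test_that("undecodable and colliding inputs are handled", {
  bs <- design_barcode_set(8, 8, 3, seed = 75)
  wa <- assign_wells(c(rn = strrep("N", 26)), bs)
  expect_identical(wa$assignments$status, "unassigned")
  expect_identical(wa$stats$unassigned, 1L)
  dup <- c(a = strrep("A", 26), a = strrep("C", 26))
  expect_error(assign_wells(dup, bs), "collision")
  expect_error(assign_wells(c(x = "ACGT"), bs), "truncated")
})

test_that("the counting rule handles its canonical single-read cases", {
  t2g <- c(tx1 = "G", tx2 = "G", tx3 = "H", sp1 = "sp1")
  spikes <- "sp1"
  mk <- function(tx, strand, score) {
    data.table::data.table(read_id = "r", transcript_id = tx,
                           strand = strand, score = score)
  }
  wmap <- wells_from_map(list(r = 1L))
  ## single sense record -> counted for its gene
  cm <- count_unique(mk("tx1", "sense", 60L), wmap, t2g, spikes, n_wells = 2)
  expect_identical(cm$counts["G", 1], 1L)
  expect_identical(cm$stats$unique[1], 1L)
  ## isoform tie at the max -> still a single gene, counted
  cm <- count_unique(mk(c("tx1", "tx2", "tx3"), "sense", c(60L, 60L, 50L)),
                     wmap, t2g, spikes, n_wells = 2)
  expect_identical(cm$counts["G", 1], 1L)
  expect_identical(cm$counts["H", 1], 0L)
  ## cross-gene tie at the max -> discarded as multi-gene
  cm <- count_unique(mk(c("tx1", "tx3"), "sense", c(60L, 60L)),
                     wmap, t2g, spikes, n_wells = 2)
  expect_identical(sum(cm$counts), 0L)
  expect_identical(cm$stats$multi_gene[1], 1L)
  ## antisense-only group -> wrong-strand discard
  cm <- count_unique(mk("tx1", "antisense", 60L), wmap, t2g, spikes,
                     n_wells = 2)
  expect_identical(sum(cm$counts), 0L)
  expect_identical(cm$stats$wrong_strand[1], 1L)
  ## antisense records never veto a sense winner
  cm <- count_unique(mk(c("tx1", "tx3"), c("sense", "antisense"),
                        c(50L, 60L)), wmap, t2g, spikes, n_wells = 2)
  expect_identical(cm$counts["G", 1], 1L)
  ## spike-in winner goes to the spike block, never the gene matrix
  cm <- count_unique(mk("sp1", "sense", 60L), wmap, t2g, spikes, n_wells = 2)
  expect_identical(sum(cm$counts), 0L)
  expect_identical(cm$spike_counts["sp1", 1], 1L)
  ## gene/spike tie at the max -> discarded and logged
  cm <- count_unique(mk(c("tx1", "sp1"), "sense", c(60L, 60L)),
                     wmap, t2g, spikes, n_wells = 2)
  expect_identical(sum(cm$counts) + sum(cm$spike_counts), 0L)
  expect_identical(cm$stats$gene_spike_tie[1], 1L)
})

test_that("counting matches an independent brute-force oracle on random groups", {
  tx <- simulate_transcriptome(12, 2, c(300, 400), n_spikes = 2, seed = 81)
  fix <- random_read_groups(300, tx$tx2gene, tx$spike_ins, n_wells = 4,
                            seed = 82)
  genes <- sort(setdiff(unique(unname(tx$tx2gene)), tx$spike_ins))
  oracle <- brute_force_count(fix$records, fix$well_of_read, tx$tx2gene,
                              tx$spike_ins, genes, 4)
  cm <- count_unique(data.table::as.data.table(fix$records),
                     wells_from_map(fix$well_of_read), tx$tx2gene,
                     tx$spike_ins, n_wells = 4)
  expect_identical(unname(cm$counts), unname(oracle$counts))
  ## read accounting is conserved per well
  with(cm$stats, expect_identical(
    assigned,
    unique + spike + multi_gene + wrong_strand + unmapped + gene_spike_tie))
})

test_that("assigned reads without alignments are tallied as unmapped", {
  t2g <- c(tx1 = "G")
  wmap <- wells_from_map(list(r1 = 1L, r2 = 1L))
  rec <- data.table::data.table(read_id = "r1", transcript_id = "tx1",
                                strand = "sense", score = 10L)
  cm <- count_unique(rec, wmap, t2g, n_wells = 1)
  expect_identical(cm$stats$unmapped[1], 1L)
  expect_identical(cm$stats$unique[1], 1L)
})

test_that("pooling wells sums counts and preserves the gene axis", {
  sc <- tiny_screen(n_genes = 10, replicates = 2, seed = 83)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 5,
                           reads_per_well = 200, seed = 84)
  m <- truth$realized_counts
  cm <- structure(list(counts = m,
                       spike_counts = matrix(0L, 0, ncol(m),
                                             dimnames = list(NULL, colnames(m))),
                       stats = data.frame(
                         well_label = colnames(m),
                         assigned = colSums(m), unique = colSums(m),
                         spike = 0L, multi_gene = 0L, wrong_strand = 0L,
                         unmapped = 0L, gene_spike_tie = 0L,
                         row.names = colnames(m))),
                  class = "CountMatrix")
  ## singleton groups are the identity
  ident <- pool_wells(cm, as.list(stats::setNames(colnames(m), colnames(m))))
  expect_identical(unname(ident$counts), unname(m))
  ## pooling everything gives the row sums
  all_pool <- pool_wells(cm, list(all = colnames(m)))
  expect_identical(unname(all_pool$counts[, 1]),
                   unname(as.integer(rowSums(m))))
  ## pooled detection dominates each member well
  g1 <- colnames(m)[1:2]
  pooled <- pool_wells(cm, list(p = g1))
  expect_gte(genes_detected(pooled$counts)[["p"]],
             max(genes_detected(m[, g1])))
  expect_error(pool_wells(cm, list(a = g1, b = colnames(m)[2:3])),
               "overlap")
})
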