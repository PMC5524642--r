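## Shared fixture builders and independent oracles. Everything is generated
## in code at test time; no stored data.

## Small standard screen: genes, two drugs + vehicle, 4 replicates each.
tiny_screen <- function(n_genes = 30, replicates = 4, lfc = c(drugA = 2),
                        n_spikes = 0, seed = 101) {
  tx <- simulate_transcriptome(n_genes, iso_per_gene = 2,
                               length_range = c(300, 800),
                               n_spikes = n_spikes, seed = seed)
  genes <- setdiff(unique(unname(tx$tx2gene)), tx$spike_ins)
  conds <- list(DMSO = perturbation())
  for (d in names(lfc)) {
    tg <- stats::setNames(lfc[[d]], genes[1])
    conds[[d]] <- perturbation(tg)
  }
  plate <- make_plate_design(conds, replicates = replicates)
  list(tx = tx, plate = plate, genes = genes)
}

## Independent brute-force implementation of the unique-mapping counting
## rule, written directly from its definition: per read, the maximum
## alignment score among correct-strand (sense) alignments must belong to a
## single gene. Returns a gene x well count matrix plus per-read verdicts.
brute_force_count <- function(records, well_of_read, tx2gene,
                              spike_ins = character(0), genes, n_wells) {
  counts <- matrix(0L, length(genes), n_wells,
                   dimnames = list(genes, NULL))
  verdict <- character(0)
  for (rid in unique(records$read_id)) {
    w <- well_of_read[[rid]]
    if (is.null(w) || is.na(w)) next
    g <- records[records$read_id == rid, , drop = FALSE]
    sense <- g[g$strand == "sense", , drop = FALSE]
    if (nrow(sense) == 0) { verdict[rid] <- "wrong_strand"; next }
    mx <- max(sense$score)
    winners <- unique(tx2gene[sense$transcript_id[sense$score == mx]])
    is_sp <- winners %in% spike_ins
    if (length(winners) == 1 && !is_sp) {
      counts[winners, w] <- counts[winners, w] + 1L
      verdict[rid] <- "unique"
    } else if (length(winners) == 1 && is_sp) {
      verdict[rid] <- "spike"
    } else if (any(is_sp) && any(!is_sp)) {
      verdict[rid] <- "gene_spike_tie"
    } else {
      verdict[rid] <- "multi_gene"
    }
  }
  list(counts = counts, verdict = verdict)
}

## Randomised per-read alignment groups exercising isoform ties, cross-gene
## ties, antisense-only and spike cases.
random_read_groups <- function(n_reads, tx2gene, spike_ins = character(0),
                               n_wells = 4, seed = 1) {
  withr_seed <- function(code) plateseq:::with_seed(seed, code)
  withr_seed({
    txs <- names(tx2gene)
    rows <- lapply(seq_len(n_reads), function(i) {
      k <- sample(1:4, 1)
      data.frame(read_id = sprintf("q%05d", i),
                 transcript_id = sample(txs, k, replace = TRUE),
                 strand = sample(c("sense", "antisense"), k, replace = TRUE,
                                 prob = c(0.8, 0.2)),
                 score = sample(c(40L, 50L, 60L), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    well_of_read <- stats::setNames(
      as.list(sample.int(n_wells, n_reads, replace = TRUE)),
      sprintf("q%05d", seq_len(n_reads)))
    list(records = records, well_of_read = well_of_read)
  })
}

## WellAssignmentTable built directly from a read -> well map (bypasses
## barcode decoding for counting-rule tests).
wells_from_map <- function(well_of_read) {
  ids <- names(well_of_read)
  ass <- data.table::data.table(read_id = ids, status = "assigned",
                                well_index = unlist(well_of_read),
                                distance = 0L)
  structure(list(assignments = ass,
                 stats = list(total = length(ids), assigned = length(ids),
                              unassigned = 0L, ambiguous = 0L)),
            class = "WellAssignmentTable")
}

## Ordinary least-squares Procrustes residual (rotation + reflection +
## translation + scale), used to compare MDS embeddings to ground truth.
procrustes_ss <- function(X, Y) {
  fit <- vegan::procrustes(X, Y, symmetric = FALSE)
  fit$ss
}
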