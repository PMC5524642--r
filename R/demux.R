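## Pipeline core: read-1 barcode decoding into wells, then gene counting
## under the unique-mapping rule: a read is counted iff the maximum
## alignment score among its correct-strand (sense) alignments is associated
## with a single gene. Multi-gene maxima are discarded, antisense-only reads
## are discarded, spike-in transcripts are tallied in a separate block.

#' Assign reads to wells by decoding read-1 barcodes
#'
#' Vectorised decoder: exact prefix matches decode at distance 0; remaining
#' reads are looked up in the precomputed single-substitution neighbourhood
#' of the code (distance 1). With a distance-3 code this implements
#' single-error correction; neighbourhood collisions (only possible for
#' min_distance < 3) yield status "ambiguous".
#'
#' @param read1 Named character vector of read-1 sequences, or FASTQ path.
#' @param barcodes A `BarcodeSet`.
#' @param max_distance 0 (exact only) or 1 (default; error correction).
#' @return A `WellAssignmentTable`: list with `assignments` (data.table
#'   read_id, status, well_index, distance) and `stats` (total, assigned,
#'   unassigned, ambiguous).
#' @export
assign_wells <- function(read1, barcodes, max_distance = 1L) {
  read1 <- as_read_vector(read1)
  if (anyDuplicated(names(read1))) stop("read-id collision in read-1 input")
  k <- barcodes$length_k
  if (any(nchar(read1) < k)) {
    stop("truncated read(s): read 1 shorter than barcode length ", k)
  }
  obs <- substr(read1, 1L, k)
  idx0 <- match(obs, barcodes$sequences)
  well <- idx0
  dist <- ifelse(is.na(idx0), NA_integer_, 0L)
  status <- ifelse(is.na(idx0), "unassigned", "assigned")
  if (max_distance >= 1L) {
    tbl <- barcode_decode_table(barcodes)
    miss <- which(is.na(idx0))
    if (length(miss)) {
      j <- match(obs[miss], tbl$nb_keys)
      hit <- !is.na(j)
      hidx <- tbl$nb_idx[j[hit]]
      well[miss[hit]] <- hidx
      dist[miss[hit]] <- 1L
      status[miss[hit]] <- ifelse(is.na(hidx), "ambiguous", "assigned")
    }
  }
  ass <- data.table::data.table(read_id = names(read1), status = status,
                                well_index = well, distance = dist)
  stats <- list(total = nrow(ass),
                assigned = sum(status == "assigned"),
                unassigned = sum(status == "unassigned"),
                ambiguous = sum(status == "ambiguous"))
  structure(list(assignments = ass, stats = stats),
            class = "WellAssignmentTable")
}

#' Count uniquely mapped reads per gene per well
#'
#' Applies, per assigned read: (1) drop antisense records; (2) take the
#' maximum score among the remaining sense records; (3) map the max-score
#' transcripts to genes; (4) count the read for that gene iff the max-score
#' set touches exactly one gene, else discard it as multi-gene. Reads whose
#' max-score set is a single spike-in are tallied in the spike-in block;
#' max-score ties spanning a gene and a spike-in are discarded and logged.
#'
#' @param alignments Output of [read_alignments()] or [pseudo_align()] (a
#'   records data.table, optionally a list with `records`/`unmapped_ids`).
#' @param wells A `WellAssignmentTable` from [assign_wells()].
#' @param tx2gene Named character map transcript -> gene.
#' @param spike_ins Character vector of spike-in transcript ids.
#' @param well_labels Labels for well columns, parallel to barcode indices
#'   (default "well<i>").
#' @param n_wells Number of well columns (default max barcode index seen).
#' @return A `CountMatrix`: list with `counts` (gene x well integer matrix),
#'   `spike_counts`, `stats` (per-well data.frame: assigned, unique, spike,
#'   multi_gene, wrong_strand, unmapped, gene_spike_tie).
#' @export
count_unique <- function(alignments, wells, tx2gene,
                         spike_ins = character(0),
                         well_labels = NULL, n_wells = NULL) {
  rec <- if (is.list(alignments) && !is.data.frame(alignments)) {
    alignments$records
  } else alignments
  rec <- data.table::as.data.table(rec)
  ass <- wells$assignments[status == "assigned",
                           .(read_id, well_index)]
  if (is.null(n_wells)) {
    n_wells <- max(ass$well_index, 1L)
  }
  if (is.null(well_labels)) well_labels <- paste0("well", seq_len(n_wells))
  stopifnot(length(well_labels) == n_wells)
  genes <- sort(setdiff(unique(unname(tx2gene)), spike_ins))
  counts <- matrix(0L, length(genes), n_wells,
                   dimnames = list(genes, well_labels))
  spike_counts <- matrix(0L, length(spike_ins), n_wells,
                         dimnames = list(spike_ins, well_labels))
  stats <- data.frame(well_label = well_labels,
                      assigned = 0L, unique = 0L, spike = 0L,
                      multi_gene = 0L, wrong_strand = 0L, unmapped = 0L,
                      gene_spike_tie = 0L, row.names = well_labels)
  tab_ass <- table(factor(ass$well_index, levels = seq_len(n_wells)))
  stats$assigned <- as.integer(tab_ass)
  if (nrow(ass) == 0) {
    return(structure(list(counts = counts, spike_counts = spike_counts,
                          stats = stats), class = "CountMatrix"))
  }
  rec <- rec[ass, on = "read_id", nomatch = NULL]
  unknown <- setdiff(unique(rec$transcript_id), names(tx2gene))
  if (length(unknown)) {
    stop("transcript(s) absent from tx2gene: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  has_aln <- unique(rec$read_id)
  ## reads assigned to a well but with no alignment record at all
  no_aln <- ass[!read_id %in% has_aln]
  if (nrow(no_aln)) {
    t <- table(factor(no_aln$well_index, levels = seq_len(n_wells)))
    stats$unmapped <- stats$unmapped + as.integer(t)
  }
  sense <- rec[strand == "sense"]
  anti_only <- setdiff(has_aln, unique(sense$read_id))
  if (length(anti_only)) {
    wi <- ass[read_id %in% anti_only, well_index]
    t <- table(factor(wi, levels = seq_len(n_wells)))
    stats$wrong_strand <- stats$wrong_strand + as.integer(t)
  }
  if (nrow(sense)) {
    sense[, gene := tx2gene[transcript_id]]
    sense[, is_spike := transcript_id %in% spike_ins]
    verdict <- sense[, {
      mx <- max(score)
      g <- unique(gene[score == mx])
      sp <- unique(is_spike[score == mx])
      list(well_index = well_index[1],
           n_gene = sum(!(g %in% spike_ins)) + 0L,
           n_spike = sum(g %in% spike_ins) + 0L,
           gene = g[1])
    }, by = read_id]
    uniq <- verdict[n_gene == 1L & n_spike == 0L]
    if (nrow(uniq)) {
      inc <- uniq[, .N, by = .(gene, well_index)]
      counts[cbind(match(inc$gene, genes), inc$well_index)] <-
        counts[cbind(match(inc$gene, genes), inc$well_index)] + inc$N
      t <- table(factor(uniq$well_index, levels = seq_len(n_wells)))
      stats$unique <- stats$unique + as.integer(t)
    }
    sponly <- verdict[n_gene == 0L & n_spike == 1L]
    if (nrow(sponly)) {
      inc <- sponly[, .N, by = .(gene, well_index)]
      spike_counts[cbind(match(inc$gene, spike_ins), inc$well_index)] <-
        spike_counts[cbind(match(inc$gene, spike_ins), inc$well_index)] + inc$N
      t <- table(factor(sponly$well_index, levels = seq_len(n_wells)))
      stats$spike <- stats$spike + as.integer(t)
    }
    tie_gs <- verdict[n_gene >= 1L & n_spike >= 1L]
    if (nrow(tie_gs)) {
      t <- table(factor(tie_gs$well_index, levels = seq_len(n_wells)))
      stats$gene_spike_tie <- stats$gene_spike_tie + as.integer(t)
    }
    multi <- verdict[(n_gene >= 2L & n_spike == 0L) |
                     (n_gene == 0L & n_spike >= 2L)]
    if (nrow(multi)) {
      t <- table(factor(multi$well_index, levels = seq_len(n_wells)))
      stats$multi_gene <- stats$multi_gene + as.integer(t)
    }
  }
  ## conservation: assigned = unique + spike + multi + wrong_strand +
  ## unmapped + gene_spike_tie, per well
  lhs <- stats$assigned
  rhs <- stats$unique + stats$spike + stats$multi_gene +
    stats$wrong_strand + stats$unmapped + stats$gene_spike_tie
  if (!all(lhs == rhs)) stop("internal error: read-accounting mismatch")
  structure(list(counts = counts, spike_counts = spike_counts, stats = stats),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " wells; ", sum(x$counts), " uniquely mapped reads",
      if (nrow(x$spike_counts)) paste0(" (+", sum(x$spike_counts),
                                       " spike-in)") else "", "\n", sep = "")
  invisible(x)
}

#' Pool wells by summing their count columns
#'
#' @param cm A `CountMatrix`.
#' @param groups Named list of well-label vectors; must not overlap.
#' @return A `CountMatrix` with one column per group (stats summed).
#' @export
pool_wells <- function(cm, groups) {
  all_members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_members)) stop("pooling groups overlap: not a partition")
  if (!all(all_members %in% colnames(cm$counts))) {
    stop("unknown well label(s) in pooling groups")
  }
  if (is.null(names(groups))) names(groups) <- paste0("pool", seq_along(groups))
  pool_mat <- function(m) {
    out <- matrix(0L, nrow(m), length(groups),
                  dimnames = list(rownames(m), names(groups)))
    for (j in seq_along(groups)) {
      out[, j] <- as.integer(rowSums(m[, groups[[j]], drop = FALSE]))
    }
    out
  }
  stat_cols <- c("assigned", "unique", "spike", "multi_gene",
                 "wrong_strand", "unmapped", "gene_spike_tie")
  stats <- data.frame(well_label = names(groups), row.names = names(groups))
  for (sc in stat_cols) {
    stats[[sc]] <- vapply(groups, function(g) {
      sum(cm$stats[g, sc])
    }, numeric(1))
  }
  structure(list(counts = pool_mat(cm$counts),
                 spike_counts = pool_mat(cm$spike_counts),
                 stats = stats), class = "CountMatrix")
}

#' Write / read a CountMatrix as TSV
#' @param cm A `CountMatrix`.
#' @param counts_path,stats_path Output TSVs (genes as rows, wells as
#'   columns; spike-in rows carry their spike ids).
#' @rdname counts_io
#' @export
write_counts <- function(cm, counts_path, stats_path = NULL) {
  m <- rbind(cm$counts, cm$spike_counts)
  write_matrix_tsv(m, counts_path, feature_col = "gene")
  if (!is.null(stats_path)) {
    data.table::fwrite(cm$stats, stats_path, sep = "\t")
  }
  invisible(counts_path)
}

#' @param spike_ins Spike-in ids used to split rows back out.
#' @rdname counts_io
#' @export
read_counts <- function(counts_path, spike_ins = character(0),
                        stats_path = NULL) {
  m <- read_matrix_tsv(counts_path)
  storage.mode(m) <- "integer"
  sp <- rownames(m) %in% spike_ins
  stats <- if (!is.null(stats_path)) {
    as.data.frame(data.table::fread(stats_path, sep = "\t"))
  } else NULL
  structure(list(counts = m[!sp, , drop = FALSE],
                 spike_counts = m[sp, , drop = FALSE],
                 stats = stats), class = "CountMatrix")
}
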