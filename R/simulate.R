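## Synthetic-run simulator: toy transcriptome, plate layout, negative-binomial
## plate counts with planted perturbation effects, and barcoded paired FASTQ
## with substitution sequencing errors — all with full ground truth, so every
## downstream stage can be validated without external sequencing data.

#' Simulate a toy transcriptome
#'
#' Random i.i.d. DNA transcripts grouped into genes, plus optional spike-in
#' control transcripts (each spike-in maps to itself in `tx2gene` and is
#' flagged). Structure mirrors a transcriptome FASTA + transcript-to-gene
#' table; content is synthetic.
#'
#' @param n_genes Number of genes.
#' @param iso_per_gene Isoforms per gene.
#' @param length_range Transcript length range in bp (uniform).
#' @param n_spikes Number of spike-in transcripts (default 0).
#' @param read_length Minimum usable transcript length; `length_range[1]`
#'   below this is a configuration error.
#' @param seed Integer seed.
#' @return A `Transcriptome`: list with `seqs` (named character),
#'   `tx2gene` (named character, transcript -> gene), `spike_ins`.
#' @export
simulate_transcriptome <- function(n_genes, iso_per_gene = 2L,
                                   length_range = c(300L, 1000L),
                                   n_spikes = 0L, read_length = 66L,
                                   seed = 1L) {
  stopifnot(n_genes >= 1, iso_per_gene >= 1)
  if (length_range[1] < read_length) {
    stop("length_range lower bound (", length_range[1],
         ") is below the read length (", read_length, ")")
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  tx_ids <- as.vector(t(outer(genes, seq_len(iso_per_gene),
                              function(g, i) paste0(g, ".", i))))
  tx2gene <- rep(genes, each = iso_per_gene)
  names(tx2gene) <- tx_ids
  spike_ids <- if (n_spikes > 0) sprintf("SPIKE%03d", seq_len(n_spikes)) else character(0)
  if (n_spikes > 0) {
    sp <- spike_ids
    names(sp) <- spike_ids
    tx2gene <- c(tx2gene, sp)
  }
  all_ids <- c(tx_ids, spike_ids)
  seqs <- with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], length(all_ids), replace = TRUE)
    vapply(lens, function(L) paste(sample(DNA_BASES, L, replace = TRUE),
                                   collapse = ""), character(1))
  })
  names(seqs) <- all_ids
  structure(list(seqs = seqs, tx2gene = tx2gene, spike_ins = spike_ids),
            class = "Transcriptome")
}

#' Write / read a transcriptome
#' @param tx A `Transcriptome`.
#' @param fasta,tx2gene_path Output paths (FASTA; TSV transcript_id, gene_id,
#'   is_spike).
#' @rdname transcriptome_io
#' @export
write_transcriptome <- function(tx, fasta, tx2gene_path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tx$seqs), fasta)
  utils::write.table(
    data.frame(transcript_id = names(tx$tx2gene),
               gene_id = unname(tx$tx2gene),
               is_spike = as.integer(names(tx$tx2gene) %in% tx$spike_ins)),
    tx2gene_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tx)
}

#' @rdname transcriptome_io
#' @export
read_transcriptome <- function(fasta, tx2gene_path) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  df <- utils::read.table(tx2gene_path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  t2g <- df$gene_id
  names(t2g) <- df$transcript_id
  structure(list(seqs = seqs, tx2gene = t2g,
                 spike_ins = df$transcript_id[df$is_spike == 1]),
            class = "Transcriptome")
}

#' Perturbation specification
#'
#' Either explicit per-gene log2 fold changes, or a regulon whose targets
#' receive mode-aligned shifts (`lfc * mode`), mirroring a drug acting
#' through a regulatory protein.
#'
#' @param targets Named numeric vector gene_id -> log2 fold change (may be
#'   empty, e.g. for the vehicle condition).
#' @param regulator_id Optional regulator id annotation.
#' @return A `PerturbationSpec`.
#' @export
perturbation <- function(targets = numeric(0), regulator_id = NULL) {
  structure(list(targets = targets, regulator_id = regulator_id),
            class = "PerturbationSpec")
}

#' Build a perturbation acting through a regulon
#'
#' Each target gene receives `lfc * mode`, so activating targets move with
#' the regulator and repressed targets move against it.
#'
#' @param reg A `Regulon`.
#' @param lfc Log2 fold change applied to the regulator's activity.
#' @export
regulon_perturbation <- function(reg, lfc) {
  t <- reg$targets
  shifts <- lfc * t$mode
  names(shifts) <- t$gene_id
  perturbation(targets = shifts, regulator_id = reg$regulator_id)
}

#' Plate layout for a pooled screen
#'
#' Wells in plate order (A1..H12 for 96), each carrying a barcode index and
#' a condition; conditions are cycled in replicate blocks (default emulates
#' a screen of drugs plus vehicle controls with equal replicate counts).
#'
#' @param conditions Named list of `PerturbationSpec`s; the vehicle condition
#'   must have an empty target map.
#' @param replicates Replicate wells per condition.
#' @param vehicle Name of the vehicle-control condition in `conditions`.
#' @param barcode_indices Barcode index per well (default 1..n_wells).
#' @return A `PlateDesign`: list with `wells` (data.frame well_label,
#'   barcode_index, condition, is_vehicle) and `conditions`.
#' @export
make_plate_design <- function(conditions, replicates = 12L, vehicle = "DMSO",
                              barcode_indices = NULL) {
  stopifnot(vehicle %in% names(conditions))
  if (length(conditions[[vehicle]]$targets) != 0) {
    stop("vehicle condition must have an empty target map")
  }
  cond_per_well <- rep(names(conditions), each = replicates)
  n <- length(cond_per_well)
  if (is.null(barcode_indices)) barcode_indices <- seq_len(n)
  if (anyDuplicated(barcode_indices)) stop("barcode_index values must be unique")
  wells <- data.frame(well_label = plate_labels(n),
                      barcode_index = barcode_indices,
                      condition = cond_per_well,
                      is_vehicle = cond_per_well == vehicle,
                      stringsAsFactors = FALSE)
  structure(list(wells = wells, conditions = conditions, vehicle = vehicle),
            class = "PlateDesign")
}

#' Simulate plate counts under a negative-binomial model
#'
#' Per-gene baseline means are drawn once (log-normal spread around
#' `base_mean`); in a perturbed well the mean of gene g becomes
#' `mu_g * 2^lfc(g)`. Counts are NB-sampled with the stated dispersion
#' (`Var = mu + dispersion * mu^2`; `dispersion = 0` gives Poisson), then
#' each well is rescaled to exactly `reads_per_well` total reads by
#' multinomial thinning, mirroring fixed per-well sequencing depth.
#'
#' @param tx A `Transcriptome` (genes and spike-ins define the rows).
#' @param plate A `PlateDesign`.
#' @param base_mean Baseline NB mean per gene (scalar, or vector per gene).
#' @param dispersion NB dispersion alpha (0 = Poisson).
#' @param reads_per_well Total realized reads per well.
#' @param mean_sdlog Log-normal sd of per-gene baseline spread (ignored when
#'   `base_mean` is a vector).
#' @param seed Integer seed.
#' @return A `SimTruth`: list with `expected_counts` (NB means, gene x well),
#'   `realized_counts` (integers, columns summing to `reads_per_well`),
#'   `per_read` (filled by [simulate_run()]), `params`.
#' @export
simulate_counts <- function(tx, plate, base_mean = 100, dispersion = 0.1,
                            reads_per_well = 1e5, mean_sdlog = 1, seed = 1L) {
  genes <- unique(unname(tx$tx2gene))
  G <- length(genes)
  wells <- plate$wells
  W <- nrow(wells)
  with_seed(seed, {
    mu_g <- if (length(base_mean) == G) {
      base_mean
    } else if (mean_sdlog > 0) {
      base_mean * exp(stats::rnorm(G, 0, mean_sdlog) - mean_sdlog^2 / 2)
    } else rep(base_mean, G)
    names(mu_g) <- genes
    mu <- matrix(mu_g, G, W, dimnames = list(genes, wells$well_label))
    for (w in seq_len(W)) {
      tg <- plate$conditions[[wells$condition[w]]]$targets
      if (length(tg)) {
        if (any(!is.finite(tg))) stop("perturbation log2 fold changes must be finite")
        idx <- match(names(tg), genes)
        if (anyNA(idx)) stop("perturbation targets unknown gene(s): ",
                             paste(names(tg)[is.na(idx)], collapse = ", "))
        mu[idx, w] <- mu[idx, w] * 2^tg
      }
    }
    raw <- matrix(0L, G, W, dimnames = dimnames(mu))
    for (w in seq_len(W)) {
      raw[, w] <- if (dispersion > 0) {
        stats::rnbinom(G, mu = mu[, w], size = 1 / dispersion)
      } else stats::rpois(G, mu[, w])
    }
    realized <- matrix(0L, G, W, dimnames = dimnames(mu))
    for (w in seq_len(W)) {
      tot <- sum(raw[, w])
      if (tot == 0) next
      realized[, w] <- as.integer(stats::rmultinom(1, reads_per_well,
                                                   raw[, w] / tot))
    }
    structure(list(expected_counts = mu, realized_counts = realized,
                   per_read = NULL,
                   params = list(base_mean = base_mean, dispersion = dispersion,
                                 reads_per_well = reads_per_well,
                                 mean_sdlog = mean_sdlog, seed = seed)),
              class = "SimTruth")
  })
}

## Mutate a character vector of reads with iid substitutions at rate r.
apply_substitutions <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  len <- nchar(reads)
  n_err <- stats::rbinom(length(reads), len, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Emit a barcoded paired-FASTQ run from realized counts
#'
#' Read 1 is the well barcode followed by a T homopolymer (the oligo(dT)
#' tract) padded to `read1_len`; read 2 is a sense-strand fragment drawn
#' uniformly from the 3'-most `frag_window` bases of a transcript of the
#' counted gene. Both mates receive iid substitution errors at
#' `sub_error_rate`. Ground truth (true well and transcript per read) is
#' recorded for every emitted read.
#'
#' @param truth A `SimTruth` from [simulate_counts()].
#' @param tx The `Transcriptome` used for the counts.
#' @param barcodes A `BarcodeSet` (indexed by `plate$wells$barcode_index`).
#' @param plate The `PlateDesign`.
#' @param read1_len,read2_len Read lengths in cycles (protocol defaults
#'   26 and 66).
#' @param sub_error_rate Per-base substitution probability.
#' @param frag_window Size of the 3' window fragments start in (>= read2_len).
#' @param seed Integer seed.
#' @param out_prefix If non-NULL, write `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` (constant quality "I").
#' @return List with `read1`, `read2` (named character vectors, names = read
#'   ids), `per_read` (data.table read_id, well_label, well_index,
#'   transcript_id), `truth` (the input truth with `per_read` attached), and
#'   file paths when written.
#' @export
simulate_run <- function(truth, tx, barcodes, plate,
                         read1_len = 26L, read2_len = 66L,
                         sub_error_rate = 0, frag_window = 250L,
                         seed = 1L, out_prefix = NULL) {
  stopifnot(inherits(truth, "SimTruth"))
  if (frag_window < read2_len) {
    stop("frag_window (", frag_window, ") must be >= read2_len (", read2_len, ")")
  }
  counts <- truth$realized_counts
  wells <- plate$wells
  tx_by_gene <- split(names(tx$tx2gene), unname(tx$tx2gene))
  tx_len <- nchar(tx$seqs)
  with_seed(seed, {
    r1 <- character(0); r2 <- character(0)
    well_lab <- character(0); well_idx <- integer(0); tx_of <- character(0)
    for (w in seq_len(nrow(wells))) {
      col <- counts[, wells$well_label[w]]
      col <- col[col > 0]
      if (!length(col)) next
      gene_of_read <- rep(names(col), col)
      tx_choice <- character(length(gene_of_read))
      for (g in names(col)) {
        cand <- tx_by_gene[[g]]
        cand <- cand[tx_len[cand] >= read2_len]
        sel <- gene_of_read == g
        if (!length(cand)) {
          warning("all transcripts of ", g, " shorter than read2_len (",
                  read2_len, "); its reads are skipped")
          tx_choice[sel] <- NA_character_
          next
        }
        tx_choice[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE)]
      }
      keep <- !is.na(tx_choice)
      tx_choice <- tx_choice[keep]
      if (!length(tx_choice)) next
      L <- tx_len[tx_choice]
      lo <- pmax(1L, L - frag_window + 1L)
      hi <- L - read2_len + 1L
      start <- lo + floor(stats::runif(length(tx_choice)) * (hi - lo + 1L))
      frag <- substring(tx$seqs[tx_choice], start, start + read2_len - 1L)
      bc <- barcodes$sequences[wells$barcode_index[w]]
      r1w <- rep(paste0(bc, strrep("T", max(0L, read1_len - nchar(bc)))),
                 length(tx_choice))
      r1 <- c(r1, r1w); r2 <- c(r2, unname(frag))
      well_lab <- c(well_lab, rep(wells$well_label[w], length(tx_choice)))
      well_idx <- c(well_idx, rep(wells$barcode_index[w], length(tx_choice)))
      tx_of <- c(tx_of, tx_choice)
    }
    n <- length(r1)
    ids <- sprintf("r%08d", seq_len(n))
    ## shuffle so wells are interleaved as on a real flow cell
    ord <- sample.int(n)
    r1 <- r1[ord]; r2 <- r2[ord]
    well_lab <- well_lab[ord]; well_idx <- well_idx[ord]; tx_of <- tx_of[ord]
    r1 <- apply_substitutions(r1, sub_error_rate)
    r2 <- apply_substitutions(r2, sub_error_rate)
    names(r1) <- ids; names(r2) <- ids
    per_read <- data.table::data.table(read_id = ids, well_label = well_lab,
                                       well_index = well_idx,
                                       transcript_id = tx_of)
    truth$per_read <- per_read
    out <- list(read1 = r1, read2 = r2, per_read = per_read, truth = truth)
    if (!is.null(out_prefix)) {
      out$fastq1 <- paste0(out_prefix, "_R1.fastq.gz")
      out$fastq2 <- paste0(out_prefix, "_R2.fastq.gz")
      write_fastq(r1, out$fastq1)
      write_fastq(r2, out$fastq2)
    }
    out
  })
}

#' Write reads as 4-line gzip FASTQ (constant quality "I")
#' @param reads Named character vector (names = read ids).
#' @param path Output path (`.gz` gives gzip).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  lines <- character(4 * length(reads))
  lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", names(reads))
  lines[seq(2, by = 4, length.out = length(reads))] <- unname(reads)
  lines[seq(3, by = 4, length.out = length(reads))] <- "+"
  lines[seq(4, by = 4, length.out = length(reads))] <- strrep("I", nchar(reads))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a set of regulons
#'
#' Each regulon gets `targets_per` target genes sampled from `gene_ids`
#' (disjointly across regulons when `disjoint = TRUE`), modes drawn +-1 and
#' likelihood weights uniform on (0.5, 1].
#'
#' @param gene_ids Pool of target gene ids.
#' @param n_regulons,targets_per Regulon count and size.
#' @param disjoint Partition targets across regulons (needs
#'   `n_regulons * targets_per <= length(gene_ids)`).
#' @param seed Integer seed.
#' @return List of `Regulon` objects (see [regulon()]).
#' @export
simulate_regulons <- function(gene_ids, n_regulons = 50L, targets_per = 25L,
                              disjoint = FALSE, seed = 1L) {
  with_seed(seed, {
    if (disjoint) {
      stopifnot(n_regulons * targets_per <= length(gene_ids))
      pool <- sample(gene_ids, n_regulons * targets_per)
      tsets <- split(pool, rep(seq_len(n_regulons), each = targets_per))
    } else {
      tsets <- lapply(seq_len(n_regulons),
                      function(i) sample(gene_ids, targets_per))
    }
    lapply(seq_len(n_regulons), function(i) {
      regulon(sprintf("REG%03d", i),
              gene_id = tsets[[i]],
              mode = sample(c(-1, 1), targets_per, replace = TRUE),
              likelihood = stats::runif(targets_per, 0.5, 1))
    })
  })
}
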