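## Alignment evidence normalisation. The external aligner (bwa-mem in the
## original protocol) is consumed through SAM/BAM; a minimal exact-seed
## ungapped matcher is provided so the pipeline can be exercised end-to-end
## with no external aligner. Only transcript identity, strand relative to the
## transcript, and score ordering within a read matter to the counting rule;
## coordinates are never used downstream.

## Positional k-mer index over transcript forward strands.
build_kmer_index <- function(tx, seed_len = 15L) {
  seqs <- tx$seqs
  parts <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    L <- nchar(s)
    if (L < seed_len) return(NULL)
    starts <- seq_len(L - seed_len + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + seed_len - 1L),
                           transcript_id = id, pos = starts)
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, kmer)
  structure(list(index = idx, seed_len = seed_len, tx = tx),
            class = "KmerIndex")
}

## Count mismatches between equal-length string vectors a and b.
count_mismatch_vec <- function(a, b) {
  out <- integer(length(a))
  neq <- which(a != b)
  for (i in neq) out[i] <- sum(charToRaw(a[i]) != charToRaw(b[i]))
  out
}

#' Align reads with exact k-mer seeding and ungapped extension
#'
#' Test-grade stand-in for an external aligner: seeds at three fixed read
#' offsets on both strands, extends each candidate placement without gaps
#' across the full read, and scores `matches * match - mismatches *
#' mismatch`. All hits (ties and lower-scoring) are returned; a read with
#' no seed hit yields no records.
#'
#' @param reads Named character vector (names = read ids) or FASTQ path.
#' @param tx A `Transcriptome`, or a prebuilt index from `build_kmer_index()`.
#' @param seed_len Seed k-mer length (must not exceed the read length).
#' @param match,mismatch Match score and mismatch penalty (bwa-mem-like
#'   defaults 1 and 4).
#' @return data.table with columns read_id, transcript_id, strand
#'   ("sense"/"antisense"), score — the `AlignmentRecord` stream.
#' @export
pseudo_align <- function(reads, tx, seed_len = 15L, match = 1L, mismatch = 4L) {
  reads <- as_read_vector(reads)
  idx <- if (inherits(tx, "KmerIndex")) tx else build_kmer_index(tx, seed_len)
  seed_len <- idx$seed_len
  tx <- idx$tx
  if (!length(reads)) {
    return(data.table::data.table(read_id = character(0),
                                  transcript_id = character(0),
                                  strand = character(0), score = integer(0)))
  }
  rlen <- nchar(reads)
  if (any(rlen < seed_len)) stop("seed_len exceeds shortest read length")
  tx_len <- nchar(tx$seqs)
  reads_rc <- revcomp(reads)
  collect <- list()
  for (strand in c("sense", "antisense")) {
    qry <- if (strand == "sense") reads else reads_rc
    ## three seed offsets per read
    s1 <- rep(1L, length(qry))
    s2 <- (rlen - seed_len) %/% 2L + 1L
    s3 <- rlen - seed_len + 1L
    cand <- list()
    for (sv in list(s1, s2, s3)) {
      kmers <- substring(qry, sv, sv + seed_len - 1L)
      dt <- data.table::data.table(read_i = seq_along(qry), kmer = kmers,
                                   offset = sv)
      hit <- idx$index[dt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
      if (nrow(hit)) cand[[length(cand) + 1L]] <- hit
    }
    if (!length(cand)) next
    cand <- data.table::rbindlist(cand)
    cand[, start := pos - (offset - 1L)]
    cand <- unique(cand[, .(read_i, transcript_id, start)])
    cand <- cand[start >= 1L &
                 start + rlen[read_i] - 1L <= tx_len[transcript_id]]
    if (!nrow(cand)) next
    ref <- substring(tx$seqs[cand$transcript_id], cand$start,
                     cand$start + rlen[cand$read_i] - 1L)
    mm <- count_mismatch_vec(qry[cand$read_i], ref)
    cand[, score := (rlen[read_i] - mm) * match - mm * mismatch]
    best <- cand[, .(score = max(score)), by = .(read_i, transcript_id)]
    best[, `:=`(read_id = names(reads)[read_i], strand = strand)]
    collect[[strand]] <- best[, .(read_id, transcript_id, strand, score)]
  }
  if (!length(collect)) {
    return(data.table::data.table(read_id = character(0),
                                  transcript_id = character(0),
                                  strand = character(0), score = integer(0)))
  }
  out <- data.table::rbindlist(collect)
  ## keep the better strand per (read, transcript) placement, both if tied
  out[order(read_id, transcript_id, -score)]
}

cigar_match_length <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+(?=[M=X])", cigar, perl = TRUE)),
         function(x) sum(as.integer(x)), integer(1))
}

#' Read alignments from SAM/BAM into per-read records
#'
#' Secondary and supplementary records are included; the strand is taken
#' from the reverse-complement flag (set means antisense to the transcript);
#' scores come from the AS tag, falling back to CIGAR match length, and
#' records with neither are dropped with a logged count. Unmapped reads are
#' reported as empty groups via `unmapped_ids`.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @param tx2gene Optional named transcript -> gene map used to validate
#'   reference names.
#' @param on_unknown What to do with alignments to transcripts absent from
#'   `tx2gene`: `"error"` (default) or `"drop"` with a warning.
#' @return List with `records` (data.table read_id, transcript_id, strand,
#'   score), `unmapped_ids`, `n_dropped_noscore`.
#' @export
read_alignments <- function(path, tx2gene = NULL,
                            on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "cigar"), tag = "AS",
    flag = Rsamtools::scanBamFlag())
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  qname <- res$qname
  flag <- res$flag
  unmapped <- bitwAnd(flag, 4L) > 0L
  unmapped_ids <- unique(qname[unmapped])
  keep <- !unmapped
  score <- res$tag$AS
  if (is.null(score)) score <- rep(NA_integer_, length(qname))
  cig <- res$cigar
  need_fb <- keep & is.na(score) & !is.na(cig) & cig != "*"
  if (any(need_fb)) score[need_fb] <- cigar_match_length(cig[need_fb])
  noscore <- keep & is.na(score)
  n_dropped <- sum(noscore)
  if (n_dropped > 0) {
    message(n_dropped, " alignment record(s) without a score dropped")
  }
  keep <- keep & !noscore
  rec <- data.table::data.table(
    read_id = qname[keep],
    transcript_id = as.character(res$rname[keep]),
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0L, "antisense", "sense"),
    score = as.integer(score[keep]))
  if (!is.null(tx2gene)) {
    unknown <- setdiff(unique(rec$transcript_id), names(tx2gene))
    if (length(unknown)) {
      if (on_unknown == "error") {
        stop("alignment reference(s) absent from tx2gene: ",
             paste(utils::head(unknown, 5), collapse = ", "))
      }
      warning(length(unknown), " unknown reference(s) dropped")
      rec <- rec[!transcript_id %in% unknown]
    }
  }
  unmapped_ids <- setdiff(unmapped_ids, rec$read_id)
  list(records = rec, unmapped_ids = unmapped_ids,
       n_dropped_noscore = n_dropped)
}

#' Write alignment records as a minimal SAM file
#'
#' Emits an @SQ header per transcript and one line per record (flag 16 for
#' antisense, 0x100 added for non-primary records of a read, flag 4 lines
#' for `unmapped_ids`), carrying the score in the AS tag.
#'
#' @param records data.table/data.frame with read_id, transcript_id, strand,
#'   score, and optionally a cigar column (default "1M"; coordinates are
#'   irrelevant to counting).
#' @param tx A `Transcriptome` (for reference lengths).
#' @param path Output `.sam` path.
#' @param unmapped_ids Read ids to emit as unmapped records.
#' @export
write_sam <- function(records, tx, path, unmapped_ids = character(0)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(tx$seqs), nchar(tx$seqs)))
  rec <- data.table::as.data.table(records)
  lines <- character(0)
  if (nrow(rec)) {
    rec[, sec := seq_len(.N) > 1L, by = read_id]
    flag <- ifelse(rec$strand == "antisense", 16L, 0L) +
      ifelse(rec$sec, 256L, 0L)
    cig <- if ("cigar" %in% names(rec)) rec$cigar else rep("1M", nrow(rec))
    lines <- sprintf("%s\t%d\t%s\t1\t255\t%s\t*\t0\t0\t*\t*\tAS:i:%d",
                     rec$read_id, flag, rec$transcript_id, cig, rec$score)
  }
  if (length(unmapped_ids)) {
    lines <- c(lines,
               sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", unmapped_ids))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
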