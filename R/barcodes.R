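## Well-barcode design and error-correcting decoding.
##
## Well barcodes are fixed-length DNA tags read at the start of read 1. A set
## with minimum pairwise Hamming distance >= 3 is a single-error-correcting
## code: any observed barcode within Hamming distance 1 of a codeword decodes
## uniquely to that codeword.

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming("ACGT", "TGCA")  # 4
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming(): length mismatch (", nchar(a), " vs ", nchar(b), ")")
  }
  sum(charToRaw(a) != charToRaw(b))
}

## Hamming distance of one string against many (equal lengths assumed checked).
hamming_many <- function(x, seqs) {
  xr <- charToRaw(x)
  vapply(seqs, function(s) sum(charToRaw(s) != xr), integer(1), USE.NAMES = FALSE)
}

## Hamming sphere-packing bound for length-k quaternary codes of minimum
## distance d: |C| <= 4^k / sum_{i=0}^{t} C(k,i) 3^i with t = floor((d-1)/2).
sphere_packing_bound <- function(k, min_distance) {
  t <- (min_distance - 1) %/% 2
  vol <- sum(choose(k, 0:t) * 3^(0:t))
  4^k / vol
}

## Default plate-style labels A1..H12 column-major within rows.
plate_labels <- function(n) {
  if (n <= 96 * 26 / 8) {
    rows <- LETTERS[((seq_len(n) - 1L) %/% 12L) + 1L]
    cols <- ((seq_len(n) - 1L) %% 12L) + 1L
    paste0(rows, cols)
  } else {
    sprintf("W%04d", seq_len(n))
  }
}

max_homopolymer_run <- function(chars) max(rle(chars)$lengths)

#' Design an error-correcting well-barcode set
#'
#' Seeded greedy random accumulation: propose random k-mers, discard those
#' with a homopolymer run longer than `homopolymer_max`, and keep each
#' proposal that sits at Hamming distance >= `min_distance` from every
#' barcode kept so far. With `min_distance >= 3` the resulting code corrects
#' any single substitution.
#'
#' @param n Number of barcodes (e.g. 96 for a full plate).
#' @param k Barcode length in bases (8 in the standard protocol).
#' @param min_distance Minimum pairwise Hamming distance (>= 3 for
#'   single-error correction).
#' @param seed Integer seed; the same seed reproduces the same set.
#' @param homopolymer_max Longest allowed single-base run (default 3).
#' @param max_tries Proposal budget before declaring the search failed.
#' @param well_labels Optional well labels; defaults to plate-style A1..H12.
#' @return A `BarcodeSet`: list with `sequences`, `length_k`, `min_distance`,
#'   `well_labels`.
#' @examples
#' bs <- design_barcode_set(8, k = 6, min_distance = 3, seed = 1)
#' validate_barcode_set(bs)
#' @export
design_barcode_set <- function(n, k, min_distance, seed = 1L,
                               homopolymer_max = 3L, max_tries = 500000L,
                               well_labels = NULL) {
  stopifnot(n >= 1, k >= 1, min_distance >= 1)
  bound <- sphere_packing_bound(k, min_distance)
  if (n > bound) {
    stop("infeasible barcode design: n = ", n,
         " exceeds the Hamming sphere-packing bound ", floor(bound),
         " for (k = ", k, ", d = ", min_distance, ")")
  }
  kept <- character(0)
  kept_mat <- NULL
  with_seed(seed, {
    tries <- 0L
    while (length(kept) < n) {
      if (tries >= max_tries) {
        stop("barcode design search budget exhausted after ", max_tries,
             " proposals for (n = ", n, ", k = ", k, ", d = ", min_distance,
             "); sphere-packing bound is ", floor(bound))
      }
      tries <- tries + 1L
      cand <- sample(DNA_BASES, k, replace = TRUE)
      if (max_homopolymer_run(cand) > homopolymer_max) next
      if (!is.null(kept_mat)) {
        d <- rowSums(kept_mat != matrix(cand, nrow(kept_mat), k, byrow = TRUE))
        if (any(d < min_distance)) next
      }
      kept <- c(kept, paste(cand, collapse = ""))
      kept_mat <- rbind(kept_mat, cand)
    }
  })
  if (is.null(well_labels)) well_labels <- plate_labels(n)
  stopifnot(length(well_labels) == n)
  structure(list(sequences = kept, length_k = as.integer(k),
                 min_distance = as.integer(min_distance),
                 well_labels = well_labels),
            class = "BarcodeSet")
}

#' Validate a barcode set by brute force
#'
#' Independent O(n^2 k) scan: checks lengths, uniqueness, and that the
#' minimum pairwise Hamming distance meets the advertised `min_distance`.
#'
#' @param set A `BarcodeSet`.
#' @return Invisibly, the observed minimum pairwise distance (Inf for n = 1).
#' @export
validate_barcode_set <- function(set) {
  s <- set$sequences
  if (any(nchar(s) != set$length_k)) stop("barcode length != length_k")
  if (anyDuplicated(s)) stop("duplicate barcodes in set")
  dmin <- Inf
  if (length(s) > 1) {
    for (i in seq_len(length(s) - 1)) {
      d <- hamming_many(s[i], s[(i + 1):length(s)])
      dmin <- min(dmin, d)
    }
  }
  if (dmin < set$min_distance) {
    stop("observed minimum distance ", dmin, " < advertised ", set$min_distance)
  }
  invisible(dmin)
}

#' @export
print.BarcodeSet <- function(x, ...) {
  cat("BarcodeSet: ", length(x$sequences), " barcodes, k = ", x$length_k,
      ", min Hamming distance >= ", x$min_distance, "\n", sep = "")
  invisible(x)
}

## All 3k single-substitution Hamming neighbours of one barcode.
single_sub_neighbors <- function(bc) {
  k <- nchar(bc)
  chars <- strsplit(bc, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (pos in seq_len(k)) {
    for (b in setdiff(DNA_BASES, chars[pos])) {
      nb <- chars
      nb[pos] <- b
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

## Decoding table: every codeword (distance 0) and every single-substitution
## neighbour (distance 1) mapped to its barcode index. Neighbours claimed by
## more than one barcode (possible only when min_distance < 3) map to NA,
## i.e. ambiguous.
barcode_decode_table <- function(set) {
  exact <- set$sequences
  nb <- lapply(seq_along(exact), function(i) single_sub_neighbors(exact[i]))
  nb_keys <- unlist(nb, use.names = FALSE)
  nb_idx <- rep(seq_along(exact), vapply(nb, length, integer(1)))
  dup <- nb_keys %in% nb_keys[duplicated(nb_keys)]
  nb_idx[dup] <- NA_integer_
  keep <- !duplicated(nb_keys)
  list(exact_keys = exact,
       nb_keys = nb_keys[keep], nb_idx = nb_idx[keep])
}

#' Decode one observed barcode against a set
#'
#' Assigns the read iff exactly one barcode lies within `max_distance` of
#' the observed sequence; two or more barcodes within range is ambiguous
#' (impossible for substitutions under a distance-3 code with
#' `max_distance = 1`); otherwise unassigned.
#'
#' @param observed Observed read-1 sequence (at least `length_k` bases; the
#'   barcode field is its prefix).
#' @param set A `BarcodeSet`.
#' @param max_distance Maximum allowed distance (default 1, the
#'   single-error-correction radius of a distance-3 code).
#' @param mode `"hamming"` (fixed-length prefix, substitutions only; default)
#'   or `"levenshtein"` (extracts `length_k + 1` bases and also allows one
#'   indel).
#' @return A `BarcodeAssignment`: list with `status` (one of `"assigned"`,
#'   `"unassigned"`, `"ambiguous"`), `well_index` (only when assigned), and
#'   `edit_distance`.
#' @export
correct_barcode <- function(observed, set, max_distance = 1L,
                            mode = c("hamming", "levenshtein")) {
  mode <- match.arg(mode)
  k <- set$length_k
  want <- if (mode == "hamming") k else k + 1L
  if (nchar(observed) < k) {
    stop("truncated read: observed barcode field has ", nchar(observed),
         " bases, need ", k)
  }
  if (mode == "hamming") {
    obs <- substr(observed, 1L, k)
    d <- hamming_many(obs, set$sequences)
  } else {
    ## an indel in the barcode shifts the downstream sequence, so compare
    ## against observed prefixes of length k-1, k and k+1 and keep the best
    lens <- intersect((k - 1L):(k + 1L), seq_len(nchar(observed)))
    dmat <- vapply(lens, function(L) {
      as.integer(utils::adist(substr(observed, 1L, L), set$sequences))
    }, integer(length(set$sequences)))
    d <- apply(matrix(dmat, ncol = length(lens)), 1, min)
  }
  hits <- which(d <= max_distance)
  if (length(hits) == 1L) {
    structure(list(status = "assigned", well_index = hits,
                   edit_distance = d[hits]), class = "BarcodeAssignment")
  } else if (length(hits) >= 2L) {
    structure(list(status = "ambiguous", well_index = NULL,
                   edit_distance = min(d[hits])), class = "BarcodeAssignment")
  } else {
    structure(list(status = "unassigned", well_index = NULL,
                   edit_distance = NA_integer_), class = "BarcodeAssignment")
  }
}

#' Write / read a barcode table
#'
#' Headerless TSV with columns well_label, sequence.
#'
#' @param set A `BarcodeSet`.
#' @param path File path.
#' @rdname barcode_io
#' @export
write_barcodes <- function(set, path) {
  utils::write.table(data.frame(set$well_labels, set$sequences),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param min_distance Advertised minimum distance; if `NULL` it is measured
#'   by brute force.
#' @rdname barcode_io
#' @export
read_barcodes <- function(path, min_distance = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("well_label", "sequence"),
                          colClasses = "character")
  set <- structure(list(sequences = df$sequence,
                        length_k = nchar(df$sequence[1]),
                        min_distance = 1L,
                        well_labels = df$well_label),
                   class = "BarcodeSet")
  dmin <- validate_barcode_set(set)
  set$min_distance <- if (is.null(min_distance)) {
    as.integer(min(dmin, set$length_k))
  } else as.integer(min_distance)
  validate_barcode_set(set)
  set
}
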