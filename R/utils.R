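## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are untouched.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-stage seed derived from one master seed; kept well
## below 2^31 so it is always a valid integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

## Split strings into a character matrix (rows = strings), all equal length.
seq_to_matrix <- function(x, k = NULL) {
  if (is.null(k)) k <- nchar(x[1])
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = k, byrow = TRUE)
}

## Vectorised reverse complement on plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Read sequences from a named character vector or a FASTQ(.gz) path.
as_read_vector <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x, format = "fastq")
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("reads must be a named character vector (names = read ids) or a FASTQ path")
  }
  x
}

write_tsv <- function(x, path, rownames_col = NULL) {
  dt <- data.table::as.data.table(x, keep.rownames = rownames_col)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

## Matrix (rownames = features) -> TSV with a leading feature column.
write_matrix_tsv <- function(m, path, feature_col = "gene") {
  dt <- data.table::data.table(feature = rownames(m))
  data.table::setnames(dt, "feature", feature_col)
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  rn <- dt[[1]]
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- rn
  m
}
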