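## Per-well QC and gene-detection saturation by random subsampling of the
## uniquely-mapped read multiset (multivariate hypergeometric draws on the
## count columns — exactly equivalent to uniform read subsampling given the
## counts, and far cheaper than resampling FASTQ).

#' Genes detected per well
#'
#' @param cm A `CountMatrix` or a plain gene x well count matrix.
#' @param min_count Detection threshold (default 1). Spike-ins (kept in
#'   their own block) are excluded.
#' @return Named integer vector of genes with count >= threshold per well.
#' @export
genes_detected <- function(cm, min_count = 1L) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  colSums(m >= min_count)
}

#' Subsample a count column without replacement
#'
#' Draws `floor(fraction * total)` reads from the read multiset implied by
#' the counts (multivariate hypergeometric, via sequential conditional
#' hypergeometric draws); the result sums to exactly that draw size.
#'
#' @param column Non-negative integer vector of per-gene counts.
#' @param fraction Subsampling fraction in (0, 1].
#' @param seed Optional integer seed.
#' @return Integer vector of subsampled counts (same length/names).
#' @export
subsample_counts <- function(column, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  total <- sum(column)
  if (total == 0) return(column * 0L)
  if (fraction == 1) return(column)
  draw <- floor(fraction * total)
  with_seed(seed, {
    out <- integer(length(column))
    remaining <- total
    left <- draw
    for (i in seq_along(column)) {
      if (left == 0L) break
      xi <- column[i]
      if (xi == 0L) next
      out[i] <- stats::rhyper(1, xi, remaining - xi, left)
      left <- left - out[i]
      remaining <- remaining - xi
    }
    names(out) <- names(column)
    out
  })
}

#' Gene-detection saturation curve
#'
#' For each fraction on the grid, every well is subsampled `n_reps` times
#' and genes detected are recorded; the curve reports the mean over all
#' wells and repetitions, with the s.e.m. across wells of the per-well
#' repetition means. At fraction 1 the value equals full-data detection
#' exactly.
#'
#' @param cm A `CountMatrix` or count matrix.
#' @param fractions Grid in (0, 1] (default 0.1..1.0).
#' @param n_reps Subsampling repetitions per well and fraction.
#' @param min_count Detection threshold.
#' @param seed Integer seed.
#' @return A `SaturationCurve` data.frame: fraction, mean_genes, sem_genes,
#'   with `n_reps` as an attribute.
#' @export
saturation_curve <- function(cm, fractions = seq(0.1, 1, by = 0.1),
                             n_reps = 10L, min_count = 1L, seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  W <- ncol(m)
  full <- genes_detected(m, min_count)
  res <- with_seed(seed, {
    lapply(fractions, function(f) {
      if (f == 1) {
        well_means <- as.numeric(full)
      } else {
        well_means <- vapply(seq_len(W), function(w) {
          mean(vapply(seq_len(n_reps), function(r) {
            sum(subsample_counts(m[, w], f) >= min_count)
          }, numeric(1)))
        }, numeric(1))
      }
      c(mean = mean(well_means),
        sem = if (W > 1) stats::sd(well_means) / sqrt(W) else 0)
    })
  })
  out <- data.frame(fraction = fractions,
                    mean_genes = vapply(res, `[[`, numeric(1), "mean"),
                    sem_genes = vapply(res, `[[`, numeric(1), "sem"))
  attr(out, "n_reps") <- n_reps
  class(out) <- c("SaturationCurve", "data.frame")
  out
}

#' Per-well QC table
#'
#' Combines counting stats with genes detected and total unique reads.
#'
#' @param cm A `CountMatrix` (with `stats`).
#' @param min_count Detection threshold for genes detected.
#' @return data.frame per well: counting stats, genes_detected,
#'   unique_reads.
#' @export
qc_table <- function(cm, min_count = 1L) {
  stopifnot(inherits(cm, "CountMatrix"))
  out <- cm$stats
  out$genes_detected <- as.integer(genes_detected(cm, min_count))
  out$unique_reads <- as.integer(colSums(cm$counts))
  out
}
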