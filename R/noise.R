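## Replicate-noise methodology: per-gene CV vs mean expression across
## duplicate measurement pairs, and perturbation-vs-vehicle fold-change
## distributions — the metrics used to compare screening platforms.

#' Mean and CV of one duplicate pair
#'
#' Sample (n - 1 denominator) standard deviation over the two values —
#' `|x1 - x2| / sqrt(2)` — divided by their mean. Undefined (NA) when the
#' mean is zero.
#'
#' @param x1,x2 Non-negative expression values on a common linear scale
#'   (vectorised).
#' @return List with `mean` and `cv` (NA where mean is 0).
#' @export
per_pair_cv <- function(x1, x2) {
  if (any(x1 < 0) || any(x2 < 0)) {
    stop("per_pair_cv: expression values must be non-negative")
  }
  m <- (x1 + x2) / 2
  s <- abs(x1 - x2) / sqrt(2)
  cv <- ifelse(m > 0, s / m, NA_real_)
  list(mean = m, cv = cv)
}

#' Per-gene duplicate-noise table
#'
#' For each gene, the per-pair means and CVs are computed across the listed
#' duplicate column pairs and averaged over the pairs where the CV is
#' defined; zero-mean pairs are excluded and reflected in `n_pairs`. The
#' mean CV is the paper-style average of per-pair sample CVs; note that for
#' two replicates this estimator is biased low by c4(2) = sqrt(2/pi)
#' relative to the population CV (`cv_rms`, the root of the mean squared
#' CV, is also reported and is the better estimator of the population CV).
#'
#' @param expr Gene x sample matrix on a linear scale (e.g.
#'   [normalized_counts()]).
#' @param pairs List of length-2 character/integer vectors naming duplicate
#'   column pairs.
#' @return A `DuplicateNoiseTable` data.frame: gene, mean_expr, mean_cv,
#'   cv_rms, n_pairs.
#' @export
duplicate_noise_table <- function(expr, pairs) {
  stopifnot(length(pairs) >= 1)
  for (p in pairs) {
    if (length(p) != 2) stop("each duplicate pair must have exactly 2 columns")
    if (is.character(p) && !all(p %in% colnames(expr))) {
      stop("pair references unknown column(s): ",
           paste(setdiff(p, colnames(expr)), collapse = ", "))
    }
  }
  G <- nrow(expr)
  mean_sum <- cv_sum <- cv2_sum <- numeric(G)
  n_def <- integer(G)
  mean_all <- numeric(G)
  for (p in pairs) {
    pc <- per_pair_cv(expr[, p[1]], expr[, p[2]])
    def <- !is.na(pc$cv)
    mean_sum[def] <- mean_sum[def] + pc$mean[def]
    cv_sum[def] <- cv_sum[def] + pc$cv[def]
    cv2_sum[def] <- cv2_sum[def] + pc$cv[def]^2
    n_def <- n_def + def
    mean_all <- mean_all + pc$mean
  }
  out <- data.frame(
    gene = if (is.null(rownames(expr))) as.character(seq_len(G)) else rownames(expr),
    mean_expr = ifelse(n_def > 0, mean_sum / n_def, mean_all / length(pairs)),
    mean_cv = ifelse(n_def > 0, cv_sum / n_def, NA_real_),
    cv_rms = ifelse(n_def > 0, sqrt(cv2_sum / n_def), NA_real_),
    n_pairs = n_def, row.names = NULL)
  class(out) <- c("DuplicateNoiseTable", "data.frame")
  out
}

#' Perturbation-vs-vehicle fold-change distribution
#'
#' Log2 ratio of each non-vehicle measurement to the mean of the
#' vehicle-control columns, with a pseudocount guarding zeros, plus
#' distribution quantiles.
#'
#' @param expr Gene x sample matrix on a linear scale.
#' @param plate A `PlateDesign` or character vector of vehicle column names.
#' @param pseudocount Added to numerator and denominator (default 0.5).
#' @param probs Quantiles to summarise (default 1%, 5%, 25%, 50%, 75%, 95%,
#'   99%).
#' @return List with `lfc` (gene x perturbation-sample log2 fold-change
#'   matrix) and `quantiles`.
#' @export
fold_change_distribution <- function(expr, plate, pseudocount = 0.5,
                                     probs = c(.01, .05, .25, .5, .75, .95, .99)) {
  vehicle <- if (inherits(plate, "PlateDesign")) {
    plate$wells$well_label[plate$wells$is_vehicle]
  } else plate
  vehicle <- intersect(vehicle, colnames(expr))
  if (!length(vehicle)) stop("no vehicle-control samples among the columns")
  ref <- rowMeans(expr[, vehicle, drop = FALSE])
  pert <- setdiff(colnames(expr), vehicle)
  lfc <- log2(sweep(expr[, pert, drop = FALSE] + pseudocount, 1,
                    ref + pseudocount, "/"))
  list(lfc = lfc, quantiles = stats::quantile(lfc, probs = probs, names = TRUE))
}
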