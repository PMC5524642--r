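## Expression normalisation and perturbation signatures: median-of-ratios
## size factors, a closed-form variance-stabilising log transform,
## vehicle-referenced per-sample signatures, top-k differential selection,
## and classical (Torgerson) MDS of sample profiles.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with nonzero
#' counts in every sample) of the ratio count / per-gene geometric mean,
#' rescaled so the factors have geometric mean 1.
#'
#' @param cm A `CountMatrix` or gene x sample count matrix.
#' @return Named positive numeric vector, geometric mean exactly 1.
#' @export
size_factors <- function(cm) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  if (ncol(m) == 1) {
    out <- 1
    names(out) <- colnames(m)
    return(out)
  }
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no gene has nonzero counts in every sample; ",
         "consider pooling wells or filtering genes before normalization")
  }
  lm <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lm)
  sf <- apply(lm, 2, function(col) exp(stats::median(col - geo)))
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Variance-stabilising log transform
#'
#' `log2(count / size_factor + pseudocount)` — a closed-form
#' depth-normalised log scale, monotone in counts within each sample. The
#' transform used is recorded in the result's attributes.
#'
#' @param cm A `CountMatrix` or count matrix.
#' @param sf Size factors (default computed via [size_factors()]).
#' @param pseudocount Added inside the log (default 1).
#' @return An `ExpressionMatrix`: numeric matrix with attributes
#'   `size_factors`, `pseudocount`, `method`.
#' @export
vst <- function(cm, sf = NULL, pseudocount = 1) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(m)
  stopifnot(all(sf > 0), length(sf) == ncol(m))
  out <- log2(sweep(m, 2, sf, "/") + pseudocount)
  attr(out, "size_factors") <- sf
  attr(out, "pseudocount") <- pseudocount
  attr(out, "method") <- "size-factor-normalized log2(x + pc)"
  out
}

#' Depth-normalised linear counts
#'
#' `count / size_factor` — the linear-scale matrix used by the replicate
#' noise analysis.
#'
#' @inheritParams vst
#' @export
normalized_counts <- function(cm, sf = NULL) {
  m <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  if (is.null(sf)) sf <- size_factors(m)
  sweep(m, 2, sf, "/")
}

#' Vehicle-referenced per-sample signatures
#'
#' Subtracts the row-wise mean of the vehicle-control columns from every
#' column; vehicle columns are retained as residuals, so their mean is the
#' zero vector exactly, by construction.
#'
#' @param expr Gene x sample expression matrix (e.g. from [vst()]).
#' @param plate A `PlateDesign`, or a character vector of vehicle-control
#'   column names.
#' @return A `SignatureMatrix`: matrix with attribute `control_samples`.
#' @export
signature <- function(expr, plate) {
  vehicle <- if (inherits(plate, "PlateDesign")) {
    plate$wells$well_label[plate$wells$is_vehicle]
  } else plate
  vehicle <- intersect(vehicle, colnames(expr))
  if (!length(vehicle)) stop("no vehicle-control samples among the columns")
  out <- expr
  ## iterative refinement drives the vehicle-column row means to exactly
  ## zero in floating point (one pass leaves O(eps)-size residuals)
  for (pass in 1:4) {
    ref <- rowMeans(out[, vehicle, drop = FALSE])
    if (all(ref == 0)) break
    out <- out - ref
  }
  attr(out, "control_samples") <- vehicle
  class(out) <- c("SignatureMatrix", class(matrix()))
  out
}

#' Top-k most differential features per condition
#'
#' Features ranked by the absolute mean signature across a condition's
#' replicate columns, descending, with deterministic ties broken by feature
#' identifier.
#'
#' @param sig Feature x sample matrix (signatures or activities).
#' @param condition Character/factor of length `ncol(sig)` labelling each
#'   column's condition.
#' @param conditions Conditions to report (default: all labels present).
#' @param k Number of features per condition (default 40).
#' @return Named list (one per condition) of data.frames: feature, score
#'   (mean signature), rank.
#' @export
top_differential <- function(sig, condition, conditions = NULL, k = 40L) {
  stopifnot(length(condition) == ncol(sig))
  if (is.null(conditions)) conditions <- unique(as.character(condition))
  if (k > nrow(sig)) {
    warning("k = ", k, " exceeds the ", nrow(sig),
            " available features; truncating")
    k <- nrow(sig)
  }
  feats <- rownames(sig)
  if (is.null(feats)) feats <- as.character(seq_len(nrow(sig)))
  out <- lapply(conditions, function(cc) {
    cols <- which(as.character(condition) == cc)
    if (!length(cols)) stop("condition '", cc, "' has no samples")
    mu <- rowMeans(sig[, cols, drop = FALSE])
    ord <- order(-abs(mu), feats)
    data.frame(feature = feats[ord[seq_len(k)]],
               score = mu[ord[seq_len(k)]],
               rank = seq_len(k), row.names = NULL)
  })
  names(out) <- conditions
  out
}

#' Classical (Torgerson) MDS of sample profiles
#'
#' Embeds samples (columns) by classical metric MDS of their pairwise
#' Euclidean distances: double-centred Gram matrix, top eigenvectors scaled
#' by root eigenvalues. Deterministic up to orthogonal transform and
#' reflection. Warns when leading negative eigenvalues indicate
#' non-Euclidean input.
#'
#' @param mat Feature x sample numeric matrix.
#' @param dims Embedding dimension (default 2; needs >= dims + 1 samples).
#' @param neg_tol Relative tolerance on negative eigenvalues before warning.
#' @return Sample x dims coordinate matrix with attribute `eig`.
#' @export
classical_mds <- function(mat, dims = 2L, neg_tol = 1e-8) {
  if (ncol(mat) < dims + 1) {
    stop("classical MDS in ", dims, " dimensions needs at least ",
         dims + 1, " samples")
  }
  d <- stats::dist(t(mat))
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  if (any(fit$eig < -neg_tol * max(abs(fit$eig)))) {
    warning("negative eigenvalues beyond tolerance: input distances are ",
            "not Euclidean")
  }
  coords <- fit$points
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  attr(coords, "eig") <- fit$eig
  coords
}
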