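test_that("median-of-ratios size factors match their closed forms", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  ## column2 = 2 x column1: factors (1/sqrt2, sqrt2), geometric mean 1
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  ## single sample -> factor 1
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  ## no gene expressed everywhere -> informative error
  m3 <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(size_factors(m3), "pooling")
})

test_that("size factors agree with the DESeq2 median-of-ratios cross-check", {
  set.seed(7)
  m <- matrix(rnbinom(600, mu = 50, size = 5), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("the VST is a depth-normalised log2 with the stated fixed points", {
  m <- matrix(c(0, 7, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  e <- vst(m, sf = c(1, 1))
  expect_equal(e["g1", "a"], 0)     # log2(0 + 1)
  expect_equal(e["g2", "a"], 3)     # log2(7 + 1)
  ## doubling a sample's counts and its size factor leaves it unchanged
  e2 <- vst(cbind(a = m[, 1], b = 2 * m[, 1]), sf = c(1, 2))
  expect_equal(unname(e2[, "a"]), unname(e2[, "b"]))
  ## monotone in counts per sample
  expect_true(all(diff(vst(matrix(c(1, 5, 9), 3, 1,
                                  dimnames = list(1:3, "s")),
                           sf = 1)[, 1]) > 0))
})

test_that("signatures are vehicle-referenced with exactly zero control mean", {
  set.seed(11)
  m <- matrix(rnorm(60, 8), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  sig <- signature(m, c("s1", "s2"))
  expect_equal(max(abs(rowMeans(sig[, c("s1", "s2")]))), 0)
  ## identical columns -> all-zero signatures
  same <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), c("v", "a", "b")))
  expect_true(all(signature(same, "v") == 0))
  ## adding a per-gene constant offset to every sample changes nothing
  off <- m + matrix(rnorm(10), 10, 6)
  expect_equal(unname(signature(off, c("s1", "s2"))),
               unname(signature(m, c("s1", "s2"))))
  expect_error(signature(m, "nope"), "vehicle")
})

test_that("a planted fold change is recovered in the signatures", {
  sc <- tiny_screen(n_genes = 40, replicates = 12, lfc = c(drugA = 2),
                    seed = 111)
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 200,
                           dispersion = 0.05, reads_per_well = 4e4,
                           seed = 112)
  expr <- vst(truth$realized_counts)
  sig <- signature(expr, sc$plate)
  g <- sc$genes[1]
  wA <- sc$plate$wells$well_label[sc$plate$wells$condition == "drugA"]
  est <- sig[g, wA]
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 2), 3 * se + 0.05)
})

test_that("top-k differential selection matches a brute-force sort", {
  set.seed(13)
  m <- matrix(rnorm(800), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:8)))
  cond <- rep(c("x", "y"), each = 4)
  got <- top_differential(m, cond, conditions = "x", k = 10)[["x"]]
  mu <- rowMeans(m[, 1:4])
  ord <- order(-abs(mu), names(mu))
  expect_identical(got$feature, names(mu)[ord[1:10]])
  expect_equal(got$score, unname(mu[ord[1:10]]))
  ## k = 1 on a single nonzero row finds that row
  z <- matrix(0, 5, 2, dimnames = list(paste0("g", 1:5), c("a", "b")))
  z["g4", ] <- c(3, 3)
  expect_identical(top_differential(z, c("c", "c"), k = 1)[["c"]]$feature,
                   "g4")
  ## k beyond the feature count truncates with a warning
  expect_warning(td <- top_differential(z, c("c", "c"), k = 99), "truncat")
  expect_identical(nrow(td[["c"]]), 5L)
})

test_that("classical MDS recovers planted low-dimensional structure", {
  set.seed(17)
  pts <- matrix(rnorm(40), 20, 2)
  emb <- rbind(t(pts), matrix(0, 98, 20))
  dimnames(emb) <- list(paste0("f", 1:100), paste0("s", 1:20))
  xy <- classical_mds(emb, dims = 2)
  expect_lt(procrustes_ss(pts, xy), 1e-8)
  ## pairwise distances preserved exactly for genuinely 2-D input
  expect_equal(as.matrix(dist(xy)), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## identical samples land on coincident points
  dup <- emb; dup[, 2] <- dup[, 1]
  xy2 <- classical_mds(dup, dims = 2)
  expect_lt(sqrt(sum((xy2[1, ] - xy2[2, ])^2)), 1e-10)
  ## collinear samples have a vanishing second dimension
  lin <- rbind(seq(0, 1, length.out = 5), matrix(0, 9, 5))
  dimnames(lin) <- list(paste0("f", 1:10), paste0("s", 1:5))
  xy3 <- classical_mds(lin, dims = 2)
  expect_lt(max(abs(xy3[, 2])), 1e-6)
  expect_error(classical_mds(emb[, 1:2], dims = 2), "at least")
})

test_that("replicates of strong planted conditions cluster in MDS space", {
  sc <- tiny_screen(n_genes = 40, replicates = 12,
                    lfc = c(drugA = 2, drugB = -2), seed = 121)
  ## make drugB hit a different gene than drugA
  sc$plate$conditions$drugB <- perturbation(stats::setNames(-2, sc$genes[2]))
  truth <- simulate_counts(sc$tx, sc$plate, base_mean = 150,
                           dispersion = 0.05, reads_per_well = 3e4,
                           seed = 122)
  sig <- signature(vst(truth$realized_counts), sc$plate)
  treated <- !sc$plate$wells$is_vehicle
  xy <- classical_mds(sig[, sc$plate$wells$well_label[treated]], dims = 2)
  cond <- sc$plate$wells$condition[treated]
  d <- as.matrix(dist(xy))
  same <- outer(cond, cond, "==") & upper.tri(d)
  diff_ <- outer(cond, cond, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_]))
})
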