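make_em <- function(counts, lib = NULL, features = NULL) {
  expression_matrix(counts, tag = "counts", lib_sizes = lib,
                    features = features)
}

test_that("abundance filter applies >= 1 RPM in >= 50% of samples inclusively", {
  lib <- rep(1e6, 4)
  counts <- rbind(lowall = rep(0.5, 4),        # RPM 0.5 everywhere: dropped
                  boundary = c(1, 1, 0, 0),    # RPM 1 in exactly 50%: kept
                  high = rep(10, 4))
  colnames(counts) <- paste0("S", 1:4)
  em <- make_em(counts, lib)
  kept <- filter_low_expression(em)
  expect_identical(rownames(kept$values), c("boundary", "high"))

  # hand-computed RPM oracle on an uneven-library toy
  lib2 <- c(2e6, 5e5, 1e6, 1e6)
  counts2 <- rbind(f1 = c(3, 0, 0, 0), f2 = c(2, 1, 1, 1))
  colnames(counts2) <- paste0("S", 1:4)
  rpm <- sweep(counts2, 2, lib2 / 1e6, "/")
  survivors <- rownames(counts2)[rowMeans(rpm >= 1) >= 0.5]
  kept2 <- filter_low_expression(make_em(counts2, lib2))
  expect_identical(rownames(kept2$values), survivors)
  expect_error(filter_low_expression(make_em(counts2, c(0, lib2[-1]))),
               "library")
})

test_that("multi-precursor dedup keeps the highest-count entry", {
  counts <- rbind(e1 = c(60, 40), e2 = c(50, 40), e3 = c(5, 5))
  colnames(counts) <- c("S1", "S2")
  feats <- data.frame(mature_id = c("miR-x", "miR-x", "miR-y"),
                      precursor_id = c("precA", "precB", "precC"))
  em <- dedup_multi_precursor(make_em(counts, features = feats))
  expect_identical(em$features$precursor_id, c("precA", "precC"))
  expect_identical(rownames(em$values), c("miR-x", "miR-y"))

  # tie on totals: lexicographically smaller precursor wins with a warning
  counts2 <- rbind(e1 = c(50, 50), e2 = c(60, 40))
  colnames(counts2) <- c("S1", "S2")
  feats2 <- data.frame(mature_id = c("miR-x", "miR-x"),
                       precursor_id = c("precB", "precA"))
  expect_warning(em2 <- dedup_multi_precursor(make_em(counts2,
                                                      features = feats2)),
                 "tie")
  expect_identical(em2$features$precursor_id, "precA")

  # no duplicates: identity
  em3 <- dedup_multi_precursor(make_em(counts, features = data.frame(
    mature_id = c("a", "b", "c"), precursor_id = c("pa", "pb", "pc"))))
  expect_equal(unname(em3$values), unname(counts))
})

test_that("TMM normalization matches an independent formula evaluation", {
  set.seed(7)
  counts <- matrix(rnbinom(300 * 3, mu = 60, size = 3), 300, 3,
                   dimnames = list(paste0("g", 1:300), paste0("S", 1:3)))
  counts[1:20, 2] <- counts[1:20, 2] * 8  # asymmetry so factors differ from 1
  em <- normalize_log2(make_em(counts, lib = colSums(counts)))
  expect_equal(attr(em, "norm_factors"), oracle_tmm_factors(counts),
               tolerance = 1e-8)

  # identical samples: all factors 1
  cc <- matrix(rep(counts[, 1], 3), ncol = 3,
               dimnames = dimnames(counts))
  em_id <- normalize_log2(make_em(cc, lib = colSums(cc)))
  expect_equal(attr(em_id, "norm_factors"), rep(1, 3))

  # uniform doubling of one sample leaves its normalized values unchanged
  # (tested in the large-count regime where the prior count is negligible)
  set.seed(8)
  big <- matrix(rnbinom(300 * 100, mu = 5e4, size = 10), 300, 100,
                dimnames = list(paste0("g", 1:300), paste0("S", 1:100)))
  bd <- big
  bd[, 3] <- big[, 3] * 2
  em_a <- normalize_log2(make_em(big, lib = colSums(big)))
  em_b <- normalize_log2(make_em(bd, lib = colSums(bd)))
  expect_equal(em_a$values[, 3], em_b$values[, 3], tolerance = 1e-6)
})

test_that("outlier removal finds planted extremes and spares clean data", {
  set.seed(11)
  metrics <- data.frame(total_reads = rnorm(200, 2e7, 1e6),
                        mapped_rate = rnorm(200, 0.7, 0.02))
  rownames(metrics) <- sprintf("S%03d", 1:200)
  batch <- factor(rep(1:2, each = 100))
  metrics$total_reads[7] <- 2e7 + 10 * 1e6  # 10 SD out
  res <- remove_outlier_samples(metrics, "batch_metric", batch = batch)
  expect_identical(res$removed, "S007")

  # homogeneous Gaussian metrics at n = 600: < 1% removed in expectation
  removed <- vapply(1:10, function(s) {
    set.seed(100 + s)
    m <- data.frame(a = rnorm(600), b = rnorm(600))
    rownames(m) <- sprintf("S%03d", 1:600)
    length(remove_outlier_samples(m, "batch_metric",
                                  batch = factor(rep(1:6, 100)))$removed)
  }, numeric(1))
  expect_lt(mean(removed) / 600, 0.01)

  # PCA mode recovers exactly one planted extreme sample
  set.seed(12)
  vals <- matrix(rnorm(50 * 80), 50, 80,
                 dimnames = list(paste0("g", 1:50), sprintf("S%02d", 1:80)))
  vals[, 13] <- vals[, 13] + 12
  em <- expression_matrix(vals, tag = "log2cpm")
  res_pca <- remove_outlier_samples(em, "pca")
  expect_identical(res_pca$removed, "S13")
})

test_that("surrogate variables recover a planted hidden factor", {
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    n <- 150
    hidden <- rnorm(n)
    known <- cbind(1, rnorm(n))
    Y <- matrix(rnorm(100 * n), 100, n)
    Y <- Y + outer(rnorm(100, 0, 1.5), hidden)
    colnames(Y) <- sprintf("S%03d", 1:n)
    rownames(Y) <- paste0("g", 1:100)
    sv <- estimate_surrogate_variables(Y, known, n_sv = 5)
    max(abs(cor(sv, hidden)))
  }, numeric(1))
  expect_gt(min(hits), 0.9)

  # SVs orthogonal to the known covariates and to each other
  set.seed(21)
  Y <- matrix(rnorm(60 * 120), 60, 120,
              dimnames = list(paste0("g", 1:60), paste0("S", 1:120)))
  X <- cbind(1, rnorm(120), rbinom(120, 1, 0.5))
  sv <- estimate_surrogate_variables(Y, X, n_sv = 6)
  expect_lt(max(abs(crossprod(qr.resid(qr(X), sv) - sv))), 1e-8)
  cp <- crossprod(sv)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6)
  expect_error(estimate_surrogate_variables(Y, X, n_sv = 119), "n_sv")
})

test_that("residualization matches the normal-equations oracle", {
  set.seed(31)
  n <- 5
  X <- cbind(1, c(1, 2, 3, 4, 5))
  y <- c(2.0, 2.9, 4.2, 4.8, 6.1)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, X), as.vector(y - X %*% beta),
               tolerance = 1e-10)

  # intercept only: centered values
  expect_equal(residualize(y, matrix(1, n)), y - mean(y))
  # exact linear combination: residuals vanish
  expect_lt(max(abs(residualize(as.vector(X %*% c(1, 2)), X))), 1e-8)
  # collinear column dropped with a warning
  Xc <- cbind(X, 2 * X[, 2])
  expect_warning(r <- residualize(y, Xc), "collinear")
  expect_equal(r, as.vector(y - X %*% beta), tolerance = 1e-10)
})

test_that("feature operations commute with sample reordering", {
  p <- simulate_genotypes(80, 10, seed = 71)
  tr <- sim_truth(data.frame(feature = "m1", snp = p$snps$snp[1],
                             var_frac = 0.05))
  sim <- simulate_mirna_counts(p, tr, n_features = 12, seed = 72)
  em <- sim$expr
  perm <- sample(ncol(em$values))
  em_p <- expression_matrix(em$values[, perm], tag = "counts",
                            lib_sizes = em$lib_sizes[perm],
                            features = em$features)
  a <- normalize_log2(filter_low_expression(em))
  b <- normalize_log2(filter_low_expression(em_p))
  expect_equal(a$values[, colnames(b$values)], b$values, tolerance = 1e-10)
})
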