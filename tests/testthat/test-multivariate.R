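test_that("PC scores match a dense eigendecomposition oracle", {
  set.seed(5)
  m <- matrix(rnorm(20), 5, 4)
  z <- zscore_columns(m)
  fit <- sts(z)
  ty <- pca_typing(fit, k = 2, seed = 1)
  centred <- sweep(z, 2, colMeans(z))
  e <- eigen(crossprod(centred) / (nrow(z) - 1), symmetric = TRUE)
  oracle_scores <- centred %*% e$vectors
  for (j in 1:2) {
    got <- ty$prcomp$x[, j]
    expect_true(max(abs(got - oracle_scores[, j])) < 1e-10 ||
                  max(abs(got + oracle_scores[, j])) < 1e-10)
  }
  expect_equal(ty$variance_explained,
               e$values / sum(e$values), tolerance = 1e-10)
})

test_that("rank-1 data concentrates all variance on PC1, oriented with STS", {
  base <- c(2, 1, 0, -1, -2)
  z <- cbind(base, 2 * base, -base)
  rownames(z) <- letters[1:5]
  ty <- pca_typing(sts(z), k = 2, seed = 1)
  expect_equal(ty$variance_explained[1], 1, tolerance = 1e-12)
  expect_gte(cor(ty$scores$PC1, sts(z)$score), 0)
})

test_that("PCA reconstruction error equals the discarded eigenvalue mass", {
  set.seed(8)
  z <- zscore_columns(matrix(rnorm(60), 10, 6))
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  for (d in 1:3) {
    recon <- pc$x[, 1:d, drop = FALSE] %*% t(pc$rotation[, 1:d, drop = FALSE])
    resid <- sweep(z, 2, colMeans(z)) - recon
    expect_equal(sum(resid^2), sum(pc$sdev[-(1:d)]^2) * (nrow(z) - 1),
                 tolerance = 1e-8)
  }
})

test_that("well-separated classes are recovered by typing", {
  cfg <- cohort_config(n_accessions = 60,
                       tolerance_range = list(tolerant = c(0.85, 0.95),
                                              intermediate = c(0.55, 0.65),
                                              sensitive = c(0.25, 0.35)),
                       noise = list(count = 1, biomass = 0.05),
                       rng_seed = 21)
  co <- simulate_cohort(cfg)
  fit <- cohort_to_sts(co)
  ty <- pca_typing(fit, seed = 2)
  truth_class <- co$truth$class[match(ty$scores$accession,
                                      co$truth$accession)]
  expect_gte(mean(ty$scores$class == truth_class), 0.9)
  expect_equal(length(unique(ty$scores$cluster)), 3)
  # class labels ordered by mean STS regardless of k-means label order
  ms <- tapply(fit$score[ty$scores$accession], ty$scores$class, mean)
  expect_gt(ms[["tolerant"]], ms[["intermediate"]])
  expect_gt(ms[["intermediate"]], ms[["sensitive"]])
})

test_that("trait correlations match the textbook Pearson formula", {
  x <- c(1, 3, 4, 6, 8, 9)
  m <- cbind(x = x, y = 2 * x + 1, w = c(2, 1, 5, 4, 0, 3))
  r <- trait_correlations(m)
  expect_equal(r["x", "x"], 1)
  expect_equal(r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(r["x", "w"], o_pearson(x, m[, "w"]), tolerance = 1e-12)
  expect_equal(r, t(r))
  const <- cbind(a = x, b = rep(2, 6))
  rc <- suppressWarnings(trait_correlations(const))
  expect_true(is.na(rc["a", "b"]))
})

test_that("cross-environment correlation recovers constructed signs", {
  acc <- sprintf("a%d", 1:10)
  ck <- seq(10, 55, 5)
  tt <- rbind(
    data.frame(accession = acc, treatment = "CK", trait = "GI_mean",
               value = ck),
    data.frame(accession = acc, treatment = "NaCl150", trait = "GI_mean",
               value = 0.5 * ck),
    data.frame(accession = acc, treatment = "CK", trait = "GR_mean",
               value = ck),
    data.frame(accession = acc, treatment = "NaCl150", trait = "GR_mean",
               value = rev(ck)))
  ce <- cross_env_correlation(tt)
  expect_equal(ce$r[ce$trait == "GI_mean"], 1, tolerance = 1e-12)
  expect_equal(ce$r[ce$trait == "GR_mean"], -1, tolerance = 1e-12)
  expect_lt(ce$p[ce$trait == "GI_mean"], 1e-6)
})

test_that("cross-environment correlation is near zero for independent arms", {
  set.seed(14)
  acc <- sprintf("a%03d", 1:200)
  tt <- rbind(
    data.frame(accession = acc, treatment = "CK", trait = "GI_mean",
               value = rnorm(200)),
    data.frame(accession = acc, treatment = "NaCl150", trait = "GI_mean",
               value = rnorm(200)))
  ce <- cross_env_correlation(tt)
  expect_lt(abs(ce$r), 0.15)
})

test_that("canonical correlations behave at the known limits", {
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4)
  same <- cca_consistency(X, X)
  expect_equal(same$cor[1], 1, tolerance = 1e-6)
  expect_true(all(diff(same$cor) <= 1e-8))
  x1 <- rnorm(30); y1 <- 0.5 * x1 + rnorm(30, 0, 0.3)
  one <- cca_consistency(cbind(x1), cbind(y1))
  expect_equal(one$cor[1], abs(o_pearson(x1, y1)), tolerance = 1e-6)
  set.seed(7)
  indep <- cca_consistency(matrix(rnorm(600), 200, 3),
                           matrix(rnorm(600), 200, 3))
  expect_lt(indep$cor[1], 0.5)
  expect_true(all(indep$cor >= 0 & indep$cor <= 1))
})

test_that("canonical analysis agrees with stats::cancor when well-posed", {
  set.seed(9)
  X <- matrix(rnorm(200), 50, 4)
  Y <- X %*% matrix(rnorm(12), 4, 3) + matrix(rnorm(150), 50, 3) * 0.5
  ours <- cca_consistency(X, Y, ridge = 1e-12)
  ref <- cancor(scale(X), scale(Y))
  expect_equal(ours$cor, ref$cor, tolerance = 1e-6)
})

test_that("a planted outlier in log2R space is flagged", {
  set.seed(3)
  m <- matrix(rnorm(99 * 5, 0, 0.1), 99, 5)
  m <- rbind(m, rep(8, 5))
  rownames(m) <- sprintf("a%03d", 1:100)
  rep1 <- detect_anomalies(m, contamination = 0.01, seed = 10)
  expect_equal(sum(rep1$report$flag), 1)
  expect_equal(rep1$report$accession[rep1$report$flag], "a100")
  # flag count follows the ceiling rule
  rep5 <- detect_anomalies(m, contamination = 0.05, seed = 10)
  expect_equal(sum(rep5$report$flag), 5)
  # row order does not unseat a strong outlier
  perm <- sample(100)
  rep_p <- detect_anomalies(m[perm, ], contamination = 0.01, seed = 10)
  expect_equal(rep_p$report$accession[rep_p$report$flag], "a100")
  expect_error(detect_anomalies(m, contamination = 0.7), "between 0 and 0.5")
})
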