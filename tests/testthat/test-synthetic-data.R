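test_that("configuration errors are caught", {
  expect_error(cohort_config(class_proportions = c(tolerant = 0.6,
                                                   intermediate = 0.6,
                                                   sensitive = -0.2)),
               "sum to 1")
  expect_error(cohort_config(daily_hazard_ck = c(0.5, 1.2), n_days = 2),
               "hazards")
  expect_error(cohort_config(seeds_per_unit = 0), "seeds_per_unit")
  expect_error(cohort_config(tolerance_range = list(tolerant = c(0, 0.9),
                                                    intermediate = c(0.5, 0.7),
                                                    sensitive = c(0.2, 0.4))),
               "tolerance_range")
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulate_cohort(cohort_config(n_accessions = 10, rng_seed = 5))
  b <- simulate_cohort(cohort_config(n_accessions = 10, rng_seed = 5))
  c <- simulate_cohort(cohort_config(n_accessions = 10, rng_seed = 6))
  expect_identical(a$germination, b$germination)
  expect_identical(a$biomass, b$biomass)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$germination$n_new, c$germination$n_new))
})

test_that("seeded simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(rnorm(1))
  invisible(simulate_cohort(cohort_config(n_accessions = 5, rng_seed = 9)))
  after <- c(NA, rnorm(2))
  expect_identical(before[2:3], after[2:3])
})

test_that("cumulative germination is non-decreasing and capped at seeds sown", {
  co <- default_cohort()
  g <- co$germination
  key <- paste(g$accession, g$treatment, g$replicate)
  for (k in unique(key)[1:25]) {
    u <- g[key == k, ]
    u <- u[order(u$day), ]
    expect_true(all(u$n_new >= 0))
    expect_lte(sum(u$n_new), u$n_total[1])
  }
  expect_true(all(co$biomass$dry_g <= co$biomass$fresh_g + 1e-12))
})

test_that("latent tau is monotone with class and inside each class range", {
  truth <- default_cohort()$truth
  m <- tapply(truth$tau, truth$class, mean)
  expect_gt(m[["tolerant"]], m[["intermediate"]])
  expect_gt(m[["intermediate"]], m[["sensitive"]])
  rng <- cohort_config()$tolerance_range
  for (cl in names(rng)) {
    tau <- truth$tau[truth$class == cl]
    expect_true(all(tau >= rng[[cl]][1] & tau <= rng[[cl]][2]))
  }
})

test_that("tau fixed at 1 with zero noise reproduces CK exactly under stress", {
  co <- simulate_cohort(null_config(n = 8, noise = list(count = 0, biomass = 0),
                                    seed = 3))
  g <- co$germination
  ck <- g[g$treatment == "CK", c("accession", "replicate", "day", "n_new")]
  sa <- g[g$treatment == "NaCl150", c("accession", "replicate", "day", "n_new")]
  ord <- function(d) d[order(d$accession, d$replicate, d$day), ]
  expect_equal(ord(ck)$n_new, ord(sa)$n_new)
  rm <- build_retention_matrix(build_trait_table(g, co$biomass))
  expect_true(all(abs(rm$R - 1) < 1e-12))
})

test_that("expected trait retention grows with tau (zero-noise tau grid)", {
  taus <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  gr_ret <- gi_ret <- numeric(length(taus))
  for (i in seq_along(taus)) {
    cfg <- cohort_config(n_accessions = 2,
                         tolerance_range = list(tolerant = rep(taus[i], 2),
                                                intermediate = rep(taus[i], 2),
                                                sensitive = rep(taus[i], 2)),
                         noise = list(count = 0, biomass = 0), rng_seed = 1)
    co <- simulate_cohort(cfg)
    rm <- build_retention_matrix(build_trait_table(co$germination, co$biomass))
    gr_ret[i] <- rm$R[1, "GR_mean"]
    gi_ret[i] <- rm$R[1, "GI_mean"]
  }
  expect_true(all(diff(gr_ret) > 0))
  expect_true(all(diff(gi_ret) > 0))
})

test_that("Ct table: null fold change gives unit expression, 4-fold gives -2 cycles", {
  truth <- data.frame(accession = c("A", "B"), tau = c(0.9, 0.3),
                      class = c("tolerant", "sensitive"))
  null_cfg <- expression_config(
    fold_change_tolerant = c(ion_transport = 1, core_response = 1,
                             transcription_factor = 1),
    fold_change_sensitive = c(ion_transport = 1, core_response = 1,
                              transcription_factor = 1),
    ct_noise_sd = 0, rng_seed = 1)
  e <- ddct(simulate_ct_table(null_cfg, truth))
  expect_true(all(abs(e$rel_expr - 1) < 1e-12))

  four_cfg <- expression_config(
    fold_change_tolerant = c(ion_transport = 4, core_response = 4,
                             transcription_factor = 4),
    fold_change_sensitive = c(ion_transport = 4, core_response = 4,
                              transcription_factor = 4),
    ct_noise_sd = 0, rng_seed = 1)
  ct <- simulate_ct_table(four_cfg, truth)
  shift <- mean(ct$ct_target[ct$treatment == "CK"]) -
    mean(ct$ct_target[ct$treatment == "NaCl150"])
  expect_equal(shift, 2, tolerance = 1e-12)
})

test_that("Ct generation rejects unknown accessions and bad categories", {
  truth <- data.frame(accession = "A", tau = 1, class = "tolerant")
  expect_error(simulate_ct_table(expression_config(), truth, "ZZZ"),
               "not present")
  expect_error(expression_config(genes = data.frame(gene = "g",
                                                    category = "mystery")),
               "unknown gene category")
})

test_that("tolerant vs sensitive contrast is detected at the panel's n = 5", {
  co <- default_cohort()
  ex <- select_extremes(default_sts(), q = 0.05)
  ct <- simulate_ct_table(expression_config(rng_seed = 11), co$truth,
                          c(ex$tolerant, ex$sensitive))
  tests <- expression_contrasts(ddct(ct))
  it_stress <- tests[grepl("^IT", tests$gene) &
                       tests$contrast == "tolerant_vs_sensitive:NaCl150", ]
  expect_true(all(it_stress$p < 0.05))
  expect_true(all(it_stress$t > 0)) # induced more strongly in tolerant
})
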