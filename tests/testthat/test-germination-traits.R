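test_that("trait formulas reproduce hand-worked examples", {
  all_in <- data.frame(day = 1:3, n_new = c(50, 0, 0), n_total = 50)
  none <- data.frame(day = 1:3, n_new = c(0, 0, 0), n_total = 50)
  some <- data.frame(day = 1:5, n_new = c(10, 20, 15, 0, 0), n_total = 50)
  expect_equal(germination_rate(all_in), 100)
  expect_equal(germination_rate(none), 0)
  expect_equal(germination_rate(some), 90)
  expect_equal(germination_potential(some, gp_day = 3), 60 + 30)
  expect_equal(germination_potential(
    data.frame(day = 1:3, n_new = c(10, 20, 0), n_total = 50), 3), 60)
  expect_equal(germination_potential(none, 3), 0)
  expect_equal(germination_index(data.frame(day = 1, n_new = 10,
                                            n_total = 50)), 10)
  expect_equal(germination_index(none), 0)
  expect_equal(germination_index(
    data.frame(day = 1:3, n_new = c(2, 3, 5), n_total = 50)),
    2 / 1 + 3 / 2 + 5 / 3)
  expect_equal(vigor_index(10, 0.05), 0.5)
  expect_equal(vigor_index(0, 0.05), 0)
  expect_equal(vigor_index(10, 0), 0)
})

test_that("invalid observations are rejected", {
  expect_error(germination_rate(data.frame(day = 1:2, n_new = c(1, 1),
                                           n_total = 0)), "positive")
  expect_error(germination_index(data.frame(day = c(1, 1), n_new = c(1, 1),
                                            n_total = 50)), "duplicate")
  expect_error(germination_rate(data.frame(day = 1:2, n_new = c(40, 20),
                                           n_total = 50)), "exceeds")
  expect_error(vigor_index(-1, 0.1), "non-negative")
})

test_that("traits match brute-force oracles on 100 random instances", {
  set.seed(2024)
  for (i in 1:100) {
    obs <- rand_obs()
    gp_day <- sample(1:6, 1)
    w <- runif(1, 0, 0.2)
    expect_equal(germination_rate(obs),
                 o_germination_rate(obs$n_new, obs$n_total[1]),
                 tolerance = 1e-12)
    expect_equal(germination_potential(obs, gp_day),
                 o_germination_potential(obs$n_new, obs$day, gp_day,
                                         obs$n_total[1]),
                 tolerance = 1e-12)
    expect_equal(germination_index(obs),
                 o_germination_index(obs$n_new, obs$day),
                 tolerance = 1e-12)
    expect_equal(vigor_index(germination_index(obs), w),
                 o_vigor_index(o_germination_index(obs$n_new, obs$day), w),
                 tolerance = 1e-12)
  }
})

test_that("GP is non-decreasing in the census day and reaches GR", {
  set.seed(77)
  for (i in 1:20) {
    obs <- rand_obs()
    gp <- vapply(seq_len(max(obs$day)),
                 function(d) germination_potential(obs, d), numeric(1))
    expect_true(all(diff(gp) >= 0))
    expect_equal(gp[length(gp)], germination_rate(obs))
  }
})

test_that("GI ignores trailing zero-count days", {
  obs <- data.frame(day = 1:4, n_new = c(5, 8, 2, 0), n_total = 50)
  padded <- rbind(obs, data.frame(day = 5:7, n_new = 0, n_total = 50))
  expect_equal(germination_index(padded), germination_index(obs))
})

test_that("trait table lays out replicate traits and their means", {
  g <- expand.grid(accession = c("A", "B"), treatment = c("CK", "NaCl150"),
                   replicate = 1:3, day = 1:3, stringsAsFactors = FALSE)
  g$n_total <- 50
  # replicate r of accession A germinates (3+r) seeds on day 2, B fixed 5
  g$n_new <- ifelse(g$day == 2,
                    ifelse(g$accession == "A", 3 + g$replicate, 5), 0)
  b <- expand.grid(accession = c("A", "B"), treatment = c("CK", "NaCl150"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  b$fresh_g <- 0.04
  b$dry_g <- 0.006
  tt <- build_trait_table(g, b)
  pick <- function(acc, tr, trait)
    tt$value[tt$accession == acc & tt$treatment == tr & tt$trait == trait]
  expect_equal(pick("A", "CK", "GI_1"), 4 / 2)
  expect_equal(pick("A", "CK", "GI_3"), 6 / 2)
  expect_equal(pick("A", "CK", "GI_mean"), mean(c(4, 5, 6) / 2))
  expect_equal(pick("B", "CK", "GI_mean"), pick("B", "CK", "GI_1"))
  expect_equal(pick("A", "CK", "VI_2"), (5 / 2) * 0.04)
  expect_equal(pick("A", "CK", "GR_2"), 100 * 5 / 50)
})

test_that("missing biomass leaves germination traits intact, VI missing", {
  g <- data.frame(accession = "A", treatment = rep(c("CK", "NaCl150"), each = 2),
                  replicate = 1, day = rep(1:2, 2),
                  n_new = c(10, 5, 6, 3), n_total = 50)
  tt <- build_trait_table(g, biomass = NULL)
  expect_true(all(is.na(tt$value[grepl("^VI", tt$trait)])))
  expect_false(anyNA(tt$value[grepl("^G", tt$trait)]))
})

test_that("mean-only layout collapses replicates", {
  co <- default_cohort()
  tt <- build_trait_table(co$germination, co$biomass,
                          replicate_suffix = FALSE)
  expect_true(all(grepl("_mean$", tt$trait)))
})
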