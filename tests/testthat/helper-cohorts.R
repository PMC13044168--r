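# Shared synthetic cohorts, cached so expensive fixtures are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

default_cohort <- function(seed = 42) {
  cached(paste0("default", seed),
         simulate_cohort(cohort_config(rng_seed = seed)))
}

default_sts <- function(seed = 42) {
  cached(paste0("sts", seed), {
    co <- default_cohort(seed)
    tt <- build_trait_table(co$germination, co$biomass)
    sts(build_retention_matrix(tt))
  })
}

# deterministic (noise-free) cohort: traits are exact functions of tau
noise_free_cohort <- function(n = 30, seed = 7) {
  simulate_cohort(cohort_config(n_accessions = n,
                                noise = list(count = 0, biomass = 0),
                                rng_seed = seed))
}

# tau pinned at 1 in every class: the generator's no-stress-effect null
null_config <- function(n = 30, noise = list(count = 1, biomass = 0.10),
                        seed = NULL) {
  cohort_config(n_accessions = n,
                tolerance_range = list(tolerant = c(1, 1),
                                       intermediate = c(1, 1),
                                       sensitive = c(1, 1)),
                noise = noise, rng_seed = seed)
}

cohort_to_sts <- function(cohort, ...) {
  tt <- build_trait_table(cohort$germination, cohort$biomass, ...)
  sts(build_retention_matrix(tt))
}
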