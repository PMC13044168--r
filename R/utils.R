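#' @keywords internal
"_PACKAGE"

# Formatted stop/warning without the call in the message
stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
# A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # force RNG initialisation so we have a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# Columns every germination record table must carry
.germ_cols <- c("accession", "treatment", "replicate", "day", "n_new", "n_total")
.biomass_cols <- c("accession", "treatment", "replicate", "fresh_g", "dry_g")
.ct_cols <- c("accession", "group", "treatment", "replicate", "gene",
              "ct_target", "ct_reference")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
  invisible(df)
}
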