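# Internal helpers shared across modules.

#' @importFrom data.table data.table fread fwrite setnames setattr as.data.table
NULL

.datatable.aware <- TRUE

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never perturbs user randomness.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derived sub-seed: keeps each simulator stage individually deterministic
# while all stages remain a pure function of the config seed.
subSeed <- function(seed, k) as.integer((as.numeric(seed) * 31L + k) %% 2147483647)

# x*log(x/y) with the 0*log(0) = 0 convention (G-statistic terms).
xlogxy <- function(x, y) ifelse(x > 0, x * log(x / y), 0)

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
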