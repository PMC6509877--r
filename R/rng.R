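# Deterministic per-replicate seed streams.
#
# Each Monte-Carlo replicate gets its own seed derived from the experiment's
# root seed and the replicate counter by an integer hash, so replicate i is
# bit-identical no matter how many replicates are run, in what order, or on
# how many workers. All arithmetic stays below 2^53 so it is exact in
# doubles; results are reduced into [1, 2^31 - 2] for set.seed().

#' Derive the seed for one replicate from a root seed
#'
#' @param root_seed Integer root seed of the experiment.
#' @param i Replicate counter (1-based), vectorized.
#' @return Integer seed(s) in \[1, 2^31 - 2\].
#' @export
replicate_seed <- function(root_seed, i) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(root_seed) %% m + 1) * 48271 %% m
  x <- (x + as.numeric(i) * 2654435761) %% m
  # two multiplicative mixing rounds (Lehmer-style)
  x <- (x * 69621) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
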