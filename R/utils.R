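#' @importFrom rlang abort warn .data
#' @importFrom stats pnorm rnorm runif optimize sd var pf cor
#' @importFrom utils head
#' @useDynLib numerosense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive independent sub-seeds from a master seed
#'
#' Experiments are orchestrated from a single master seed; each stochastic
#' stage (stimulus generation, weight initialisation, training order, ...)
#' receives its own deterministic sub-seed so stages can be re-run in
#' isolation without disturbing one another.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_subseeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# run code under a temporary seed, restoring RNG state afterwards;
# seed = NULL means "use the current RNG stream"
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1) + 1))
  force(code)
}
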