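#' Order of magnitude of a combinatorial pattern count
#'
#' Number of decimal digits (order of magnitude) of `states^n_sites`, computed
#' in log space so that astronomically large counts (e.g. the number of binary
#' modification patterns over all modifiable histone residues of a nucleosome)
#' never overflow.
#'
#' @param n_sites number of independently modifiable sites.
#' @param states number of states per site (2 for a binary modification).
#' @return integer order of magnitude: `floor(log10(states^n_sites))`.
#' @examples
#' pattern_order_of_magnitude(160) # 48: 2^160 ~ 10^48
#' @export
pattern_order_of_magnitude <- function(n_sites, states = 2) {
  stopifnot(n_sites >= 1, states >= 2)
  as.integer(floor(n_sites * log10(states)))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All randomized operations in the package go
# through this so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a reproducible child seed from a base seed and a stream label,
# kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h + 1)
}

# Format numbers for text output deterministically across platforms.
fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
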