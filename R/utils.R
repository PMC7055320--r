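#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows inner_join n
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators never disturb each other.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seeds below 2^31, spread out so consecutive parents do
# not collide across streams.
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Centered rolling sum with windows truncated at the vector ends (window k
# means up to floor(k/2) neighbours on each side).
rolling_sum <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n == 0) return(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1)
  hi <- pmin(i + half, n)
  cs[hi + 1] - cs[lo]
}

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}
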