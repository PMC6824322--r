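# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  All user-facing stochastic entry points funnel
# through this so that identical seeds give bit-identical output.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number.", class = "crosspop_invalid")
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "crosspop_invalid")

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_invalid(sprintf("`%s` must be a single number in [%s, %s].",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}

# Recombine two equal-length 0/1 haplotypes: a crossover occurs between
# consecutive sites with probability `rate`; the starting parent is random.
recombine_pair <- function(h1, h2, rate) {
  l <- length(h1)
  if (rate <= 0) {
    return(if (runif(1) < 0.5) h1 else h2)
  }
  switches <- c(runif(1) < 0.5, runif(l - 1L) < rate)
  parent <- cumsum(switches) %% 2L
  ifelse(parent == 0L, h1, h2)
}

hap_strings <- function(mat) {
  apply(mat, 1L, paste0, collapse = "")
}
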