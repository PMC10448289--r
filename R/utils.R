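# Seed plumbing and numeric helpers.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  force(code)
}

# Independent per-unit substreams derived from one master seed, so any
# subject (or replicate) is regenerable in isolation.
derive_seeds <- function(master, n) {
  if (n == 0) return(integer(0))
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
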