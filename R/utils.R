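# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which is not
# what integer IP weights need: a ratio of exactly x.5 must go up).
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  `seed = NULL` uses the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child-seed scheme: under the master seed, child seeds are the
# first `m` draws of a single integer stream.  Growing `m` therefore extends
# the sequence without perturbing earlier repetitions.
child_seeds <- function(seed, m) {
  with_seed_(seed, sample.int(2147483646L, m, replace = FALSE))
}

stop_ipcorr <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol)
}
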