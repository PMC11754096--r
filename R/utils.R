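# Seed scoping: run seeded code without clobbering the caller's RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Derive a stream of child seeds from one parent seed so that stages draw
# independent randomness; kept below 2^31 - 1.
child_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 48271 + salt * 1103 + seq_len(n) * 7919) %% 2147483647
}
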