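# Derive a per-module seed from the configuration seed, kept inside the
# 32-bit integer range.
.module_seed <- function(seed, k) {
  (as.integer(seed) %% 214748363L) * 10L + as.integer(k)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
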