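# Deterministic seed derivation: one master seed spawns a reproducible seed
# per (stage, index) so any stage can be re-run in isolation.  Arithmetic is
# kept under 2^53 so the modulo is exact in double precision.
STAGE <- c(
  simulate = 1L, split = 2L, cv_run = 3L, final_fit = 4L,
  test_eval = 5L, subsample = 6L
)

derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.double(seed)) %% m) * 69621 + stage * 10007 + index * 97
  as.integer(h %% m)
}

# Majority-class indices are drawn with a local RNG state so callers' RNG
# streams are never disturbed.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code, .rng_kind = "Mersenne-Twister")
}
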