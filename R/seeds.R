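# Deterministic sub-seed derivation.
#
# Replicates and grid cells each get their own RNG seed derived from a master
# seed by a fixed mixing map over the Mersenne prime 2^31 - 1, so any
# (seed, index) pair reproduces bit-identically regardless of execution order.
# All arithmetic stays below 2^53, exact in doubles; results stay below 2^31.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master_seed)) %% m)
  k <- as.numeric(index) %% m
  mixed <- (s * 48271 + k * 1299709 + 12345) %% m
  # one more multiplicative round decorrelates adjacent indices
  as.integer((mixed * 16807 + 2147483629) %% m)
}

with_sub_seed <- function(master_seed, index, code) {
  withr::with_seed(derive_seed(master_seed, index), code)
}
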