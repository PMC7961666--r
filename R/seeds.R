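# Internal seed handling.
#
# R initializes the Mersenne-Twister state by iterating the LCG
# s -> 69069*s + 1 from the user seed, so two seeds related by that map
# (e.g. 0 and 1) produce shifted copies of the same state, and sample()
# then yields nearly identical permutations. Every set.seed() inside this
# package therefore goes through a few Lehmer (48271 mod 2^31-1) steps,
# which keeps all arithmetic exact in doubles and places related user
# seeds on unrelated generator states. Determinism in the user seed is
# preserved.
scramble_seed <- function(seed) {
  x <- (abs(as.double(seed)) %% 2147483646) + 1
  for (i in 1:3) x <- (48271 * x) %% 2147483647
  as.integer(x)
}

set_seed <- function(seed) {
  set.seed(scramble_seed(seed))
}
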