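# Independent oracles and small fixtures used across the suite.

# Single-expression rational closed form of the SRK/T refraction, derived
# by hand from the vergence-chain algebra (eliminate the intermediate
# vergences and clear denominators). Used only to cross-check the chain.
srkt_closed_form <- function(AL, r, A, P, V = 12) {
  na <- 1.336
  ncm1 <- 0.3375 # keratometric index minus 1 (337.5/r corneal power)
  L <- AL + 0.65696 - 0.02029 * AL
  C <- elp_srkt(AL, r, A)
  num <- 1000 * na * (na * r - ncm1 * L) - P * (L - C) * (na * r - ncm1 * C)
  den <- na * (V * (na * r - ncm1 * L) + L * r) -
    0.001 * P * (L - C) * (V * (na * r - ncm1 * C) + C * r)
  num / den
}

# Exact two-sided Wilcoxon signed-rank p-value by brute-force enumeration
# of all 2^n sign assignments (tie-free differences only).
wilcoxon_exact_enum <- function(d) {
  stopifnot(length(d) <= 12, all(d != 0), !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(rk[d > 0])
  v_all <- vapply(
    0:(2^n - 1),
    function(m) sum(rk[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]), 0
  )
  center <- n * (n + 1) / 4
  p <- if (v_obs > center) 2 * mean(v_all >= v_obs) else 2 * mean(v_all <= v_obs)
  min(p, 1)
}

# Constants map with every field populated, for tests that need fixed
# (un-optimized) constants.
fixed_constants <- function(models = "YP2.2", A = 119.2) {
  entry <- c(list(A = A, SF = 1.8, pACD = 5.6), haigis_constants_from_A(A))
  stats::setNames(rep(list(entry), length(models)), models)
}

# Small default-population cohort for unit tests.
small_cohort <- function(n_patients = 80, seed = 1, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients, seed = seed, ...))
}

# Deterministic grid of plausible eyes (no RNG state consumed).
eye_grid <- function(n = 100) {
  data.frame(
    patient_id = sprintf("G%03d", seq_len(n)),
    eye_id = sprintf("G%03d-R", seq_len(n)),
    laterality = "right",
    age = 70,
    axial_length = seq(20.5, 29.5, length.out = n),
    corneal_radius = seq(6.9, 8.7, length.out = n),
    acd = seq(2.2, 4.2, length.out = n),
    lens_thickness = seq(3.8, 5.4, length.out = n),
    wtw = seq(10.8, 12.8, length.out = n),
    iol_model = "YP2.2",
    iol_power = seq(8, 30, length.out = n),
    postop_se = NA_real_
  )
}
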