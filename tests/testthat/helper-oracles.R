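# Independent oracles used across the suite.

# Spherical-average oracle for an axisymmetric tensor: Monte Carlo mean
# of exp(-b e' D e) over uniform unit vectors e. Only the polar cosine
# matters by symmetry. Returns the mean and its standard error.
spherical_average_oracle <- function(b, D_L, D_T, n = 1e6, seed = 1) {
  set.seed(seed)
  c2 <- (2 * stats::runif(n) - 1)^2   # cos(polar) is uniform on [-1, 1]
  vals <- exp(-b * (D_T + (D_L - D_T) * c2))
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(n))
}

# Reduced gyromagnetic ratio used package-wide (mT/m, ms, um units).
gamma_um <- 2.6751525e-4
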