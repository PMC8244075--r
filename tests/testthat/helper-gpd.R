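# Gaussian-phase-distribution (van Gelderen) closed form for restricted
# diffusion in an impermeable cylinder with the gradient perpendicular to
# the axis, for an arbitrary balanced piecewise-constant waveform. Serves
# as the independent analytic oracle for the Monte Carlo module; it never
# shares code with the random-walk path.
#
# ln S = -(gamma^2 / 2) * sum_m B_m int int g(t1) g(t2)
#        exp(-D0 alpha_m^2 |t1 - t2| / r^2) dt1 dt2,
# with alpha_m the roots of J1'(alpha) = 0 and
# B_m = 2 r^2 / (alpha_m^2 (alpha_m^2 - 1)) the spectral weights of the
# transverse position autocorrelation (sum B_m = r^2/4).
gpd_cylinder_lnS <- function(w, r, D0, dt = 0.05) {
  alph <- c(1.8411838, 5.3314428, 8.5363164, 11.7060049, 14.8635886,
            18.0155279, 21.1643699)
  seg <- pamrs:::.effective_segments(w)
  Tend <- pamrs::waveform_duration(w)
  tm <- seq(dt / 2, Tend, by = dt)
  g <- numeric(length(tm))
  for (k in seq_len(nrow(seg))) {
    inside <- tm >= seg$t_start[k] & tm < seg$t_start[k] + seg$duration[k]
    gm <- c(seg$gx[k], seg$gy[k], seg$gz[k])
    g[inside] <- sqrt(sum(gm^2)) * sign(sum(gm))
  }
  ad <- abs(outer(tm, tm, "-"))
  phi2 <- 0
  for (a in alph) {
    Bm <- 2 * r^2 / (a^2 * (a^2 - 1))
    phi2 <- phi2 + Bm * as.numeric(t(g) %*% exp(-D0 * a^2 / r^2 * ad) %*% g) * dt^2
  }
  -gamma_um^2 * phi2 / 2
}
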