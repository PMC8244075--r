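# Noise-propagation and rotational-variance simulation studies: mean
# error (ME) and coefficient of variation (CoV) of the powder-model
# estimators under Gaussian amplitude noise and finite direction schemes.

# ---- vectorized batch fitting -------------------------------------------
#
# The study grids require ~1e4 independent fits per grid point; a
# projected, damped Gauss-Newton iteration vectorized across realizations
# fits the same constrained model as fit_powder_model() (tensor:
# parameters S0, D_L, f = D_T/D_L in [0,1]; stick: S0, D_L). A unit test
# checks agreement with the scalar optimizer on individual realizations.

.batch_fit_tensor <- function(b, Y, n_iter = 60, stick = FALSE, init = NULL) {
  # Y: n_real x n_b matrix of noisy powder amplitudes
  R <- nrow(Y)
  nb <- length(b)
  x_upper <- 200 / max(b[b > 0])
  if (is.null(init)) {
    # init: log-linear MD from positive amplitudes (clamped), D_L = 3 MD, f small
    logy <- log(pmax(Y, 1e-6))
    bc <- b - mean(b)
    slope <- as.numeric(logy %*% bc) / sum(bc^2)
    MD0 <- pmin(pmax(-slope, 1e-3), x_upper / 3)
    S0 <- pmax(Y[, which.min(b)], 1e-6)
    DL <- 3 * MD0
    f <- if (stick) rep(0, R) else rep(0.05, R)
  } else {
    S0 <- rep_len(init$S0, R)
    DL <- rep_len(init$D_L, R)
    f <- if (stick) rep(0, R) else rep_len(init$f, R)
  }
  lam <- 1e-6
  for (it in seq_len(n_iter)) {
    X <- outer(DL * (1 - f), b)            # R x nb, b * D_L * (1-f)
    A <- matrix(.stick_kernel(as.numeric(X)), R, nb)
    Ad <- matrix(.stick_kernel_d1(as.numeric(X)), R, nb)
    E <- exp(-outer(DL * f, b))
    S <- S0 * E * A
    Rres <- Y - S
    J1 <- E * A                                         # dS/dS0
    bm <- matrix(b, R, nb, byrow = TRUE)
    J2 <- S0 * E * (-bm * f * A + Ad * bm * (1 - f))    # dS/dD_L
    J3 <- -S0 * E * bm * DL * (A + Ad)                  # dS/df
    g1 <- rowSums(J1 * Rres); g2 <- rowSums(J2 * Rres); g3 <- rowSums(J3 * Rres)
    a11 <- rowSums(J1 * J1) + lam; a22 <- rowSums(J2 * J2) + lam
    a12 <- rowSums(J1 * J2); a13 <- rowSums(J1 * J3)
    a23 <- rowSums(J2 * J3); a33 <- rowSums(J3 * J3) + lam
    if (stick) {
      det2 <- a11 * a22 - a12^2
      dS0 <- (g1 * a22 - g2 * a12) / det2
      dDL <- (g2 * a11 - g1 * a12) / det2
      df <- 0
    } else {
      # 3x3 solve by adjugate
      det3 <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
        a13 * (a12 * a23 - a22 * a13)
      det3[abs(det3) < 1e-300] <- 1e-300
      dS0 <- (g1 * (a22 * a33 - a23^2) + g2 * (a13 * a23 - a12 * a33) +
                g3 * (a12 * a23 - a13 * a22)) / det3
      dDL <- (g1 * (a23 * a13 - a12 * a33) + g2 * (a11 * a33 - a13^2) +
                g3 * (a12 * a13 - a11 * a23)) / det3
      df <- (g1 * (a12 * a23 - a22 * a13) + g2 * (a12 * a13 - a11 * a23) +
               g3 * (a11 * a22 - a12^2)) / det3
    }
    # damped, projected update (step clamp keeps the iteration stable)
    S0n <- pmax(1e-6, S0 + pmin(pmax(dS0, -0.5 * S0), 0.5 * S0))
    DLn <- pmin(x_upper, pmax(0, DL + pmin(pmax(dDL, -0.3 * pmax(DL, 0.05)),
                                           0.3 * pmax(DL, 0.05))))
    fn <- if (stick) f else pmin(1, pmax(0, f + pmin(pmax(df, -0.1), 0.1)))
    last_step <- pmax(abs(S0n - S0) / pmax(S0, 1e-6),
                      abs(DLn - DL) / pmax(DL, 1e-6), abs(fn - f))
    S0 <- S0n; DL <- DLn; f <- fn
  }
  list(S0 = S0, D_L = DL, D_T = DL * f,
       MD = (DL + 2 * DL * f) / 3,
       uFA = ifelse(DL > 0, (DL - DL * f) / sqrt(DL^2 + 2 * (DL * f)^2), NA_real_),
       last_step = last_step)
}

# ---- noise propagation ---------------------------------------------------

#' Noise-propagation study over a microscopic-anisotropy grid
#'
#' For each ground-truth compartment (fixed `MD`, varying microscopic FA),
#' generates perfectly powder-averaged tensor-model signals on a b-value
#' ladder from linearly spaced gradient amplitudes
#' (`b_k = b_max (k/(n_b - 1))^2`), computes each data point over
#' `n_averages` repetitions carrying zero-mean Gaussian noise of standard
#' deviation `S0 / SNR` each (constant over b, referenced to the b = 0
#' single-measurement SNR; the averaged point therefore has sd
#' `S0 / (SNR sqrt(n_averages))`), refits the tensor model and reports
#' the mean error and coefficient of variation of each parameter over the
#' realizations. Set `n_averages = 1` to place the stated noise level
#' directly on the fitted point.
#'
#' @param SNR signal-to-noise ratio of a single b = 0 measurement.
#' @param b_max maximum b-value of the ladder (ms/um^2).
#' @param n_b number of b-values (amplitude-spaced, including 0).
#' @param MD ground-truth compartment mean diffusivity (um^2/ms).
#' @param mufa_grid ground-truth microscopic FA values.
#' @param n_realizations noise realizations per grid point.
#' @param n_averages repetitions averaged into each data point.
#' @param seed integer RNG seed.
#' @return A data.frame of class `study_report`: one row per grid point
#'   with `ME_*` and `CoV_*` columns (percent) for `D_L`, `D_T`, `MD`,
#'   `uFA`.
#' @export
run_noise_study <- function(SNR = 50, b_max = 14.5, n_b = 5, MD = 0.17,
                            mufa_grid = c(0.60, 0.70, 0.80, 0.90, 0.95,
                                          0.99, 0.995),
                            n_realizations = 1e4, n_averages = 12,
                            seed = 1L) {
  stopifnot(SNR > 0, n_realizations >= 2, n_averages >= 1)
  set.seed(seed)
  b <- b_max * (seq(0, n_b - 1) / (n_b - 1))^2
  S0 <- 1
  sd_point <- S0 / (SNR * sqrt(n_averages))
  rows <- lapply(mufa_grid, function(ufa) {
    dom <- domain_from_md_mufa(MD, ufa)
    s_true <- tensor_powder_signal(b, S0, dom)
    eps <- matrix(stats::rnorm(n_realizations * length(b), sd = sd_point),
                  n_realizations, length(b))
    Y <- matrix(s_true, n_realizations, length(b), byrow = TRUE) + eps
    fit <- .batch_fit_tensor(b, Y)
    truth <- c(D_L = dom$D_L, D_T = dom$D_T, MD = dom$MD, uFA = dom$uFA)
    est <- cbind(D_L = fit$D_L, D_T = fit$D_T, MD = fit$MD, uFA = fit$uFA)
    me <- 100 * (colMeans(est) - truth) / truth
    cov <- 100 * apply(est, 2, stats::sd) / abs(colMeans(est))
    data.frame(uFA_true = ufa, MD_true = MD,
               ME_D_L = me["D_L"], ME_D_T = me["D_T"], ME_MD = me["MD"],
               ME_uFA = me["uFA"],
               CoV_D_L = cov["D_L"], CoV_D_T = cov["D_T"], CoV_MD = cov["MD"],
               CoV_uFA = cov["uFA"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("study_report", "data.frame")
  out
}

#' Two-point stick noise study
#'
#' Precision of `D_L` from the shortest protocol: a perfectly
#' powder-averaged stick acquisition with only `b = 0` and one nonzero
#' b-value, Gaussian noise of sd `S0/SNR` on both points, fitted by the
#' exact constrained least squares of the two-point stick design.
#'
#' @param bDL dimensionless product of the nonzero b-value and the
#'   ground-truth `D_L` (default: the sensitivity optimum).
#' @param D_L ground-truth longitudinal diffusivity (um^2/ms).
#' @param SNR signal-to-noise ratio at b = 0.
#' @param n_realizations noise realizations.
#' @param seed integer RNG seed.
#' @return List with `CoV` and `ME` of the fitted `D_L` (percent), and
#'   the vector of estimates.
#' @export
run_two_point_noise_study <- function(bDL = optimal_sensitivity_point()$argmax,
                                      D_L = 0.5, SNR = 50,
                                      n_realizations = 1e4, seed = 1L) {
  set.seed(seed)
  b1 <- bDL / D_L
  s1 <- stick_powder_signal(b1, 1, D_L)
  y0 <- 1 + stats::rnorm(n_realizations, sd = 1 / SNR)
  y1 <- s1 + stats::rnorm(n_realizations, sd = 1 / SNR)
  ratio <- y1 / y0
  est <- numeric(n_realizations)
  ok <- y0 > 0 & y1 > 0 & ratio < 1
  est[ok] <- .stick_invert(ratio[ok]) / b1
  est[y0 > 0 & y1 > 0 & ratio >= 1] <- 0
  bad <- !(y0 > 0 & y1 > 0)
  est[bad] <- NA_real_
  list(CoV = 100 * stats::sd(est, na.rm = TRUE) / mean(est, na.rm = TRUE),
       ME = 100 * (mean(est, na.rm = TRUE) - D_L) / D_L,
       n_invalid = sum(bad), estimates = est)
}

# ---- rotational variance -------------------------------------------------

# Discrete powder average of a rotated axisymmetric substrate over the
# rows of e at dimensionless weighting x = b * D_L: for substrate axes u
# (n_rot x 3), S_j = mean_i exp(-b (D_T + (D_L - D_T) (e_i . u_j)^2)).
.discrete_powder <- function(e, axes, b, D_L, D_T) {
  c2 <- (axes %*% t(e))^2                 # n_rot x N
  rowMeans(exp(-b * (D_T + (D_L - D_T) * c2)))
}

#' Rotational-variance study of the discrete powder average
#'
#' For each scheme size `N` and each dimensionless weighting `bD_L`,
#' computes the discrete powder average of an axisymmetric substrate over
#' the `N`-direction electrostatic scheme for uniformly distributed
#' substrate orientations (noise-free), fits the stick model on the
#' (b = 0, b) pair, and reports the CoV and ME of the fitted `D_L` across
#' rotations.
#'
#' @param N_dirs scheme sizes.
#' @param bDL_grid dimensionless `b D_L` values.
#' @param D_L,D_T substrate diffusivities (um^2/ms).
#' @param n_rotations number of uniformly distributed substrate
#'   orientations.
#' @param seed integer RNG seed for the substrate orientations.
#' @param scheme_seed seed of the (fixed) electrostatic scheme design.
#' @return A data.frame of class `study_report` with columns `N`, `bDL`,
#'   `CoV_D_L`, `ME_D_L` (percent).
#' @export
run_rotation_study <- function(N_dirs = c(3, 6, 12, 24),
                               bDL_grid = optimal_sensitivity_point()$argmax,
                               D_L = 0.5, D_T = 0,
                               n_rotations = 1024, seed = 1L,
                               scheme_seed = 0L) {
  stopifnot(n_rotations >= 2)
  Rots <- uniform_rotations(n_rotations, seed = seed)
  axes <- t(apply(Rots, 3, function(R) R %*% c(0, 0, 1)))
  rows <- list()
  for (N in N_dirs) {
    e <- electrostatic_directions(N, seed = scheme_seed)$directions
    for (x in bDL_grid) {
      b <- x / D_L
      Sj <- .discrete_powder(e, axes, b, D_L, D_T)
      est <- .stick_invert(pmin(Sj, 1)) / b
      rows[[length(rows) + 1]] <- data.frame(
        N = N, bDL = x,
        CoV_D_L = 100 * stats::sd(est) / mean(est),
        ME_D_L = 100 * (mean(est) - D_L) / D_L)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_report", "data.frame")
  out
}

#' Combined rotational-variance and noise study
#'
#' Applies the finite-direction powder average and additive Gaussian
#' noise jointly: for each substrate orientation the `N`-direction powder
#' average at (b = 0, b) receives noise of sd `S0/SNR` on both points
#' before the two-point stick fit. Reports CoV over the joint
#' realizations per `(N, bD_L)` and the argmin of CoV over `bD_L` per
#' scheme size.
#'
#' @param N_dirs scheme sizes.
#' @param SNR signal-to-noise ratio at b = 0.
#' @param bDL_grid dimensionless `b D_L` grid (default resolution 0.25).
#' @param D_L,D_T substrate diffusivities (um^2/ms).
#' @param n_rotations substrate orientations (one noise draw each).
#' @param seed integer RNG seed.
#' @param scheme_seed seed of the (fixed) electrostatic scheme design.
#' @return List with `report` (a `study_report` with `N`, `bDL`,
#'   `CoV_D_L`) and `argmin` (data.frame `N`, `bDL_opt`).
#' @export
run_combined_study <- function(N_dirs = c(3, 6, 12), SNR = 50,
                               bDL_grid = seq(0.25, 5, by = 0.25),
                               D_L = 0.5, D_T = 0,
                               n_rotations = 1024, seed = 1L,
                               scheme_seed = 0L) {
  Rots <- uniform_rotations(n_rotations, seed = seed)
  axes <- t(apply(Rots, 3, function(R) R %*% c(0, 0, 1)))
  set.seed(seed + 1)
  rows <- list()
  for (N in N_dirs) {
    e <- electrostatic_directions(N, seed = scheme_seed)$directions
    for (x in bDL_grid) {
      b <- x / D_L
      Sj <- .discrete_powder(e, axes, b, D_L, D_T)
      y0 <- 1 + stats::rnorm(n_rotations, sd = 1 / SNR)
      y1 <- Sj + stats::rnorm(n_rotations, sd = 1 / SNR)
      ratio <- pmax(1e-12, y1) / pmax(1e-12, y0)
      est <- ifelse(ratio >= 1, 0, .stick_invert(pmin(ratio, 1)) / b)
      rows[[length(rows) + 1]] <- data.frame(
        N = N, bDL = x,
        CoV_D_L = 100 * stats::sd(est) / mean(est))
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("study_report", "data.frame")
  argmin <- do.call(rbind, lapply(split(report, report$N), function(d)
    data.frame(N = d$N[1], bDL_opt = d$bDL[which.min(d$CoV_D_L)])))
  rownames(argmin) <- NULL
  list(report = report, argmin = argmin)
}
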