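# The data-analysis pipeline: powder averaging, constrained model
# fitting, directional initial-slope (gamma) fits, macroscopic tensor
# estimation, dispersion angle and region comparison.

#' Directional dataset
#'
#' Quantified amplitudes per gradient direction, b-value and repetition.
#'
#' @param scheme a [gradient_scheme()].
#' @param amplitudes numeric array `[n_dir, n_b, n_reps]`; `n_b` follows
#'   `scheme$b_values` and `n_reps` must equal `scheme$n_reps`.
#' @param crlb_pct optional per-(direction, b) uncertainty (%, CRLB-like).
#' @param truth optional named list of ground-truth parameters (synthetic
#'   data only).
#' @return An object of class `directional_dataset`.
#' @export
directional_dataset <- function(scheme, amplitudes, crlb_pct = NULL, truth = NULL) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  amplitudes <- as.array(amplitudes)
  if (length(dim(amplitudes)) == 2) dim(amplitudes) <- c(dim(amplitudes), 1)
  d <- dim(amplitudes)
  if (d[1] != nrow(scheme$directions) || d[2] != length(scheme$b_values) ||
      d[3] != scheme$n_reps)
    stop(sprintf("amplitude dimensions [%s] inconsistent with scheme (%d dir x %d b x %d reps)",
                 paste(d, collapse = ", "), nrow(scheme$directions),
                 length(scheme$b_values), scheme$n_reps))
  if (any(amplitudes < 0))
    warning("negative amplitudes present; expected nonnegative quantified signals")
  structure(list(scheme = scheme, amplitudes = amplitudes,
                 crlb_pct = crlb_pct, truth = truth),
            class = "directional_dataset")
}

#' @export
print.directional_dataset <- function(x, ...) {
  d <- dim(x$amplitudes)
  cat(sprintf("directional_dataset: %d directions x %d b-values x %d reps\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Powder average of a directional dataset
#'
#' Averages repetitions first, then takes the unweighted mean over
#' gradient directions for each unique b-value, mimicking a fully
#' dispersed orientation distribution. The uncertainty is the standard
#' error over directions.
#'
#' @param data a [directional_dataset()].
#' @return A data.frame of class `powder_decay` with columns `b`,
#'   `amplitude`, `sd` (standard error over directions).
#' @export
powder_average <- function(data) {
  stopifnot(inherits(data, "directional_dataset"))
  if (length(data$amplitudes) == 0) stop("empty dataset")
  rep_mean <- apply(data$amplitudes, c(1, 2), mean)  # n_dir x n_b
  amp <- colMeans(rep_mean)
  n_dir <- nrow(rep_mean)
  se <- apply(rep_mean, 2, stats::sd) / sqrt(n_dir)
  out <- data.frame(b = data$scheme$b_values, amplitude = amp, sd = se)
  class(out) <- c("powder_decay", "data.frame")
  out
}

#' Powder decay from explicit values
#'
#' @param b b-values (ms/um^2), strictly increasing after sorting.
#' @param amplitude signal amplitudes.
#' @param sd optional standard deviations.
#' @return A `powder_decay` data.frame.
#' @export
powder_decay <- function(b, amplitude, sd = NA_real_) {
  if (any(b < 0)) stop("b must be nonnegative")
  o <- order(b)
  if (anyDuplicated(b)) stop("b values must be unique")
  out <- data.frame(b = b[o], amplitude = amplitude[o],
                    sd = if (length(sd) == 1) rep(sd, length(b)) else sd[o])
  class(out) <- c("powder_decay", "data.frame")
  out
}

# Invert the stick kernel A(x) = ratio for x >= 0, vectorized.
# Lookup on a dense log grid followed by Newton polishing with the
# analytic derivative. ratio must lie in (0, 1].
.stick_invert <- local({
  xg <- NULL
  Ag <- NULL
  function(ratio, x_max = 200) {
    if (is.null(xg)) {
      xg <<- c(0, exp(seq(log(1e-8), log(200), length.out = 4096)))
      Ag <<- .stick_kernel(xg)
    }
    x <- stats::approx(Ag, xg, xout = pmin(ratio, 1), rule = 2)$y
    for (i in 1:4) {
      f <- .stick_kernel(x) - ratio
      x <- pmin(x_max, pmax(0, x - f / .stick_kernel_d1(x)))
    }
    x
  }
})

# Exact constrained least-squares solution for the two-point stick design
# (b = 0 and one nonzero b): interior solutions interpolate both points;
# at the D_L >= 0 boundary the model is constant and S0 is the mean.
.fit_stick_two_point <- function(b1, y0, y1) {
  if (y0 <= 0 || y1 >= y0) {
    if (y1 + y0 <= 0) return(list(S0 = NA_real_, D_L = NA_real_, converged = FALSE))
    return(list(S0 = (y0 + y1) / 2, D_L = 0, converged = TRUE))
  }
  if (y1 <= 0) {
    # attenuation beyond the model's range at finite D_L; flag
    return(list(S0 = y0, D_L = 200 / b1, converged = FALSE))
  }
  x <- .stick_invert(y1 / y0)
  list(S0 = y0, D_L = x / b1, converged = TRUE)
}

#' Fit a powder-averaged compartment model
#'
#' Constrained nonlinear least squares of the stick
#' ([stick_powder_signal()]) or axisymmetric-tensor
#' ([tensor_powder_signal()]) model to a powder-averaged decay, including
#' the `b = 0` point. The constraints `D_L >= D_T >= 0` are enforced by
#' the reparameterization `D_T = f * D_L`, `f` in `[0, 1]`, with a bounded
#' (L-BFGS-B) optimizer; the fit is initialized from a log-linear mean
#' diffusivity fit as `D_L = 3 MD`, `D_T = 0`. For the two-point stick
#' design the exact constrained least-squares solution is used.
#'
#' @param decay a `powder_decay` (from [powder_average()] or
#'   [powder_decay()]).
#' @param model `"stick"` or `"tensor"`.
#' @param weights optional per-point weights (e.g. inverse variance);
#'   default unweighted.
#' @return A list of class `powder_fit`: `model`, `S0`, `D_L`, `D_T`,
#'   `MD`, `uFA`, `rss`, `converged`.
#' @examples
#' d <- powder_decay(c(0, 2, 4, 6, 9.4), stick_powder_signal(c(0, 2, 4, 6, 9.4), 1, 0.5))
#' fit_powder_model(d, "stick")$D_L
#' @export
fit_powder_model <- function(decay, model = c("stick", "tensor"), weights = NULL) {
  model <- match.arg(model)
  b <- decay$b
  y <- decay$amplitude
  nb <- length(unique(b))
  if (model == "stick" && nb < 2) stop("stick fit needs at least 2 unique b-values")
  if (model == "tensor" && nb < 3) stop("tensor fit needs at least 3 unique b-values")
  if (is.null(weights)) weights <- rep(1, length(b))

  if (model == "stick" && nb == 2 && length(b) == 2 && b[1] == 0 &&
      all(weights == weights[1])) {
    f2 <- .fit_stick_two_point(b[2], y[1], y[2])
    res <- list(model = "stick", S0 = f2$S0, D_L = f2$D_L, D_T = 0,
                converged = f2$converged)
    res$MD <- res$D_L / 3
    res$uFA <- 1
    res$rss <- if (f2$converged && f2$D_L > 0) 0 else
      sum(weights * (y - res$S0 * .stick_kernel(b * res$D_L))^2)
    class(res) <- "powder_fit"
    return(res)
  }

  # init: log-linear MD fit on positive amplitudes, D_L = 3 MD, D_T = 0
  pos <- y > 0
  MD0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ b[pos]))[2]
    max(1e-4, -as.numeric(sl))
  } else 0.1
  S00 <- max(y[b == min(b)][1], max(y) , 1e-12)

  if (model == "stick") {
    obj <- function(p) {
      sum(weights * (y - p[1] * .stick_kernel(b * p[2]))^2)
    }
    opt <- stats::optim(c(S00, 3 * MD0), obj, method = "L-BFGS-B",
                        lower = c(1e-12, 0), upper = c(Inf, 200 / max(b[b > 0])),
                        control = list(factr = 1e1, maxit = 1000))
    S0 <- opt$par[1]; D_L <- opt$par[2]; D_T <- 0
  } else {
    obj <- function(p) {
      sum(weights * (y - p[1] * exp(-b * p[3] * p[2]) *
                       .stick_kernel(b * p[2] * (1 - p[3])))^2)
    }
    opt <- stats::optim(c(S00, 3 * MD0, 0.02), obj, method = "L-BFGS-B",
                        lower = c(1e-12, 0, 0), upper = c(Inf, 200 / max(b[b > 0]), 1),
                        control = list(factr = 1e1, maxit = 1000))
    # polish from the solution with parameter-scaled steps; the (D_L, f)
    # valley is narrow near exact-model data
    opt <- stats::optim(opt$par, obj, method = "L-BFGS-B",
                        lower = c(1e-12, 0, 0), upper = c(Inf, 200 / max(b[b > 0]), 1),
                        control = list(factr = 1e1, maxit = 1000,
                                       parscale = pmax(abs(opt$par), 1e-3)))
    S0 <- opt$par[1]; D_L <- opt$par[2]; D_T <- opt$par[2] * opt$par[3]
  }
  if (all(weights == weights[1])) {
    # Gauss-Newton polish (quadratic convergence near the optimum)
    gn <- .batch_fit_tensor(b, matrix(y, 1, length(y)), n_iter = 80,
                            stick = (model == "stick"),
                            init = list(S0 = S0, D_L = D_L,
                                        f = if (D_L > 0) D_T / D_L else 0))
    rss_gn <- sum(weights * (y - gn$S0 * exp(-b * gn$D_T) *
                               .stick_kernel(b * (gn$D_L - gn$D_T)))^2)
    if (rss_gn <= opt$value) {
      S0 <- gn$S0; D_L <- gn$D_L; D_T <- gn$D_T
      opt$value <- rss_gn
      # a stationary polished iterate counts as converged even when
      # L-BFGS-B bailed out of its line search
      if (gn$last_step < 1e-8) opt$convergence <- 0
    }
  }
  res <- list(model = model, S0 = S0, D_L = D_L, D_T = D_T,
              MD = compartment_md(D_L, D_T),
              uFA = if (D_L > 0) mufa(D_L, D_T) else NA_real_,
              rss = opt$value, converged = opt$convergence == 0)
  if (!res$converged)
    warning("fit did not converge (", opt$message, ")")
  class(res) <- "powder_fit"
  res
}

#' @export
print.powder_fit <- function(x, ...) {
  cat(sprintf("powder_fit [%s]: S0 = %.4g, D_L = %.4g, D_T = %.4g um^2/ms (MD = %.4g, uFA = %.3f)%s\n",
              x$model, x$S0, x$D_L, x$D_T, x$MD, x$uFA,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Asymptotic-regime rescaling of a powder decay
#'
#' Rescales a fitted decay to the dimensionless coordinates in which the
#' stick model approaches a straight line through the origin at high b:
#' `x = (b D_L)^(-1/2)` against `y = S / S0`, with the asymptote
#' `y = (sqrt(pi)/2) x`. Points with `x < 0.5` (where the stick deviates
#' from the asymptote by less than 0.5%) are flagged as the asymptotic
#' regime; the `b = 0` point is excluded from the flag.
#'
#' @param decay a `powder_decay`.
#' @param fit a `powder_fit` supplying `S0` and `D_L`.
#' @return data.frame with columns `b`, `inv_sqrt_bDL`, `S_norm`,
#'   `asymptote`, `deviation`, `asymptotic`.
#' @export
asymptote_check <- function(decay, fit) {
  b <- decay$b
  x <- ifelse(b > 0, 1 / sqrt(b * fit$D_L), Inf)
  y <- decay$amplitude / fit$S0
  asym <- sqrt(pi) / 2 * ifelse(is.finite(x), x, NA_real_)
  data.frame(b = b, inv_sqrt_bDL = x, S_norm = y, asymptote = asym,
             deviation = y - asym,
             asymptotic = is.finite(x) & x < 0.5 & b > 0)
}

# Gamma-distributed-diffusivity decay: S(b) = S0 (1 + b var/mu)^(-mu^2/var),
# with the monoexponential limit S0 exp(-b mu) as var -> 0.
.gamma_signal <- function(b, S0, mu, v) {
  if (v < 1e-10) return(S0 * exp(-b * mu))
  S0 * (1 + b * v / mu)^(-mu^2 / v)
}

#' Initial-slope diffusivity via a gamma distribution of diffusivities
#'
#' Fits \eqn{S(b) = S_0 (1 + b\,\mathrm{var}/\mu)^{-\mu^2/\mathrm{var}}}
#' to a single attenuation curve. The gamma-convolved form accounts for
#' nonmonoexponential attenuation while its initial slope equals the mean
#' diffusivity \eqn{\mu}, which is the directional apparent diffusivity
#' used for macroscopic-tensor estimation.
#'
#' @param b b-values (ms/um^2), at least 3 unique.
#' @param amplitudes signal amplitudes along one gradient direction.
#' @return A list of class `gamma_fit`: `S0`, `mu` (initial slope,
#'   um^2/ms), `var` (um^4/ms^2), `rss`, `converged`.
#' @export
directional_adc_gamma <- function(b, amplitudes) {
  if (length(unique(b)) < 3) stop("gamma fit needs at least 3 unique b-values")
  y <- amplitudes
  pos <- y > 0
  # init from a quadratic cumulant fit: log S = log S0 - b mu + b^2 var/2
  init <- if (sum(pos) >= 3) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ b[pos] + I(b[pos]^2)))
    c(exp(cf[1]), max(1e-4, -as.numeric(cf[2])), max(1e-8, 2 * as.numeric(cf[3])))
  } else c(max(y, 1e-12), 0.1, 1e-3)
  obj <- function(p) sum((y - .gamma_signal(b, p[1], p[2], p[3]))^2)
  ctrl <- list(factr = 1e1, maxit = 2000, parscale = pmax(abs(init), 1e-4))
  opt <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(1e-12, 1e-6, 0), upper = c(Inf, 50, 100),
                      control = ctrl)
  # restart from the monoexponential edge guards against stalls of the
  # cumulant start when the curvature term is poorly determined
  opt2 <- stats::optim(c(init[1], init[2], 1e-8), obj, method = "L-BFGS-B",
                       lower = c(1e-12, 1e-6, 0), upper = c(Inf, 50, 100),
                       control = ctrl)
  if (opt2$value < opt$value) opt <- opt2
  res <- list(S0 = opt$par[1], mu = opt$par[2], var = opt$par[3],
              rss = opt$value, converged = opt$convergence == 0)
  class(res) <- "gamma_fit"
  res
}

#' Macroscopic (voxel-averaged) diffusion tensor from directional ADCs
#'
#' Solves the linear system \eqn{D_i = e_i \langle D \rangle e_i^\top} for
#' the six unique elements of the symmetric voxel-averaged tensor by least
#' squares, and summarizes it by its eigenvalues: `MD` (mean), `D_L`
#' (largest eigenvalue), `D_T` (mean of the two smaller), and the standard
#' fractional anisotropy.
#'
#' @param D_i per-direction apparent diffusivities (um^2/ms).
#' @param scheme a [gradient_scheme()] (or N x 3 direction matrix) whose
#'   rows correspond to `D_i`; at least 6 directions spanning the
#'   6-dimensional space of symmetric tensors.
#' @return A list of class `macro_tensor`: `tensor` (3 x 3), `evals`
#'   (decreasing), `MD`, `D_L`, `D_T`, `FA`.
#' @export
solve_macro_tensor <- function(D_i, scheme) {
  e <- if (inherits(scheme, "gradient_scheme")) scheme$directions else as.matrix(scheme)
  if (length(D_i) != nrow(e)) stop("length(D_i) must match the number of directions")
  X <- cbind(e[, 1]^2, e[, 2]^2, e[, 3]^2,
             2 * e[, 1] * e[, 2], 2 * e[, 1] * e[, 3], 2 * e[, 2] * e[, 3])
  qrX <- qr(X)
  if (qrX$rank < 6)
    stop(sprintf("rank-deficient design: directions span only %d of the 6 symmetric-tensor dimensions",
                 qrX$rank))
  d <- qr.coef(qrX, D_i)
  Dm <- matrix(c(d[1], d[4], d[5],
                 d[4], d[2], d[6],
                 d[5], d[6], d[3]), 3, 3)
  ev <- sort(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  md <- mean(ev)
  fa <- sqrt(1.5 * sum((ev - md)^2) / sum(ev^2))
  res <- list(tensor = Dm, evals = ev, MD = md, D_L = ev[1],
              D_T = (ev[2] + ev[3]) / 2, FA = fa)
  class(res) <- "macro_tensor"
  res
}

#' @export
print.macro_tensor <- function(x, ...) {
  cat(sprintf("macro_tensor: eigenvalues (%.3g, %.3g, %.3g), MD = %.3g, FA = %.3f\n",
              x$evals[1], x$evals[2], x$evals[3], x$MD, x$FA))
  invisible(x)
}

#' Angular spread of dispersed sticks from the macroscopic tensor
#'
#' Under the assumption of dispersed sticks with `D_L = 3 <MD>`, the
#' root-mean-square polar angle of the stick orientation distribution
#' about the tensor symmetry axis is
#' \deqn{\theta = \arccos\sqrt{\langle D_L \rangle / (3 \langle MD \rangle)}.}
#' An isotropic tensor gives the magic angle 54.74 degrees.
#'
#' @param macro_MD voxel-averaged mean diffusivity (um^2/ms).
#' @param macro_DL largest eigenvalue of the voxel-averaged tensor
#'   (um^2/ms), `macro_MD <= macro_DL <= 3 macro_MD`.
#' @return Angular spread theta in degrees.
#' @examples
#' dispersion_angle(0.19, 0.42) # ~31
#' @export
dispersion_angle <- function(macro_MD, macro_DL) {
  if (any(macro_MD <= 0)) stop("macro_MD must be positive")
  if (any(macro_DL > 3 * macro_MD + 1e-12))
    stop("macro_DL > 3 * macro_MD is inconsistent with the stick assumption")
  if (any(macro_DL < macro_MD - 1e-12))
    stop("macro_DL must be at least macro_MD")
  acos(sqrt(pmin(1, macro_DL / (3 * macro_MD)))) * 180 / pi
}

#' Compare fitted metrics between two regions
#'
#' Two-tailed two-sample t-test per metric column, with a significance
#' flag at `p < 0.05`. No multiple-testing correction is applied; raw
#' p-values are reported.
#'
#' @param groupA,groupB data.frames (or lists of `powder_fit`s) with the
#'   same numeric metric columns, one row per subject.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns `metric`, `mean_A`, `mean_B`, `p`,
#'   `significant`.
#' @export
region_compare <- function(groupA, groupB, alpha = 0.05) {
  to_df <- function(g) {
    if (is.data.frame(g)) return(g)
    do.call(rbind, lapply(g, function(f)
      data.frame(S0 = f$S0, D_L = f$D_L, D_T = f$D_T, MD = f$MD, uFA = f$uFA)))
  }
  A <- to_df(groupA); B <- to_df(groupB)
  metrics <- intersect(names(A), names(B))
  metrics <- metrics[vapply(A[metrics], is.numeric, TRUE)]
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 subjects per group")
  out <- lapply(metrics, function(m) {
    a <- A[[m]]; bb <- B[[m]]
    if (stats::sd(a) == 0 && stats::sd(bb) == 0) {
      if (isTRUE(all.equal(mean(a), mean(bb))))
        return(data.frame(metric = m, mean_A = mean(a), mean_B = mean(bb),
                          p = 1, significant = FALSE))
      stop("degenerate (zero) variance in both groups for metric ", m)
    }
    tt <- stats::t.test(a, bb, alternative = "two.sided")
    data.frame(metric = m, mean_A = mean(a), mean_B = mean(bb),
               p = tt$p.value, significant = tt$p.value < alpha)
  })
  do.call(rbind, out)
}
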