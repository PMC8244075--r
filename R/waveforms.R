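# Bipolar diffusion-encoding waveform synthesis and b-matrix computation.
#
# Gradient amplitudes are in mT/m, times in ms, lengths in um; the reduced
# gyromagnetic ratio below makes q = gamma * g * t come out in rad/um so
# that b = integral(q^2 dt) is in ms/um^2.

# 2.6751525e8 rad s^-1 T^-1 expressed per (ms * mT/m * um)
.gamma_um <- 2.6751525e-4

#' Piecewise-constant gradient waveform
#'
#' A diffusion-encoding waveform as rectangular segments of physical
#' gradient (3-vectors, mT/m) plus the times of refocusing (180-degree)
#' pulses, which flip the sign of the effective gradient. Times not
#' covered by a segment have zero gradient.
#'
#' @param segments data.frame with columns `t_start`, `duration` (ms) and
#'   `gx`, `gy`, `gz` (mT/m).
#' @param refocus_times numeric vector of refocusing-pulse times (ms).
#' @param meta optional named list of timing metadata (delta, Delta, tau, g).
#' @return An object of class `waveform`.
#' @export
waveform <- function(segments, refocus_times = numeric(), meta = list()) {
  need <- c("t_start", "duration", "gx", "gy", "gz")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segments missing columns: ", paste(miss, collapse = ", "))
  if (any(segments$duration <= 0)) stop("all durations must be positive")
  o <- order(segments$t_start)
  segments <- segments[o, , drop = FALSE]
  ends <- segments$t_start + segments$duration
  if (nrow(segments) > 1 &&
      any(segments$t_start[-1] < ends[-nrow(segments)] - 1e-9))
    stop("segments must not overlap")
  structure(list(segments = segments, refocus_times = sort(refocus_times),
                 meta = meta),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d segments over [0, %.3g] ms, %d refocusing pulses\n",
              nrow(x$segments), waveform_duration(x), length(x$refocus_times)))
  invisible(x)
}

#' Total duration of a waveform (ms)
#' @param w a [waveform()].
#' @export
waveform_duration <- function(w) {
  if (nrow(w$segments) == 0) return(0)
  max(w$segments$t_start + w$segments$duration)
}

# Effective-gradient segments: physical gradient multiplied by
# (-1)^(number of refocusing pulses before the segment). Segments are
# assumed not to straddle a refocusing pulse (true for the layouts built
# here, which place pulses in gradient-free gaps); straddling is an error.
.effective_segments <- function(w) {
  seg <- w$segments
  if (nrow(seg) == 0) return(seg)
  for (tr in w$refocus_times) {
    inside <- seg$t_start < tr & (seg$t_start + seg$duration) > tr
    if (any(inside)) stop("refocusing pulse inside a gradient segment")
  }
  nflip <- vapply(seg$t_start, function(t0) sum(w$refocus_times <= t0), 0L)
  sgn <- (-1)^nflip
  seg$gx <- seg$gx * sgn
  seg$gy <- seg$gy * sgn
  seg$gz <- seg$gz * sgn
  seg
}

#' Bipolar PRESS-style diffusion waveform
#'
#' Builds the bipolar encoding used around the two refocusing pulses of a
#' PRESS localization: per pulse, one pair of opposite-polarity rectangular
#' lobes of duration `delta/2` each, separated by a gradient-free gap `tau`
#' containing the refocusing pulse; the two pair centers are `Delta` apart.
#' With the sign pattern (+, -, +, -) the effective gradient after the two
#' sign flips is (+, +, -, -), so the effective zeroth moment vanishes at
#' the end of the train.
#'
#' `delta` is the total encoding gradient duration per bipolar pair (both
#' lobes around one refocusing pulse), matching acquisitions where
#' `Delta = delta + tau` makes the two pair trains contiguous.
#'
#' @param delta total encoding gradient duration per bipolar pair (ms).
#' @param Delta separation of the two pair centers (ms).
#' @param tau gradient-free bipolar delay between the lobes of a pair (ms).
#' @param g gradient amplitude (mT/m); `g = 0` gives a null waveform with
#'   b = 0.
#' @param direction unit 3-vector of the gradient direction.
#' @return A [waveform()] with `meta` recording the timing parameters.
#' @examples
#' w <- bipolar_press_waveform(45, 59, 14, 40, c(1, 0, 0))
#' sum(diag(b_matrix(w)$B)) # ~8.6 ms/um^2
#' @export
bipolar_press_waveform <- function(delta, Delta, tau, g, direction = c(1, 0, 0)) {
  if (delta <= 0 || Delta <= 0 || tau <= 0) stop("delta, Delta, tau must be positive")
  if (g < 0) stop("g must be nonnegative")
  direction <- direction / sqrt(sum(direction^2))
  lob <- delta / 2
  if (Delta < delta + tau - 1e-9)
    stop("infeasible timing: Delta must be at least delta + tau")
  pair1_start <- 0
  pair2_start <- Delta            # pair center separation Delta
  starts <- c(pair1_start, pair1_start + lob + tau,
              pair2_start, pair2_start + lob + tau)
  signs <- c(1, -1, 1, -1)
  seg <- data.frame(t_start = starts, duration = lob,
                    gx = g * direction[1] * signs,
                    gy = g * direction[2] * signs,
                    gz = g * direction[3] * signs)
  refocus <- c(pair1_start + lob + tau / 2, pair2_start + lob + tau / 2)
  waveform(seg, refocus_times = refocus,
           meta = list(delta = delta, Delta = Delta, tau = tau, g = g,
                       direction = direction))
}

#' Stejskal-Tanner rectangular gradient pair
#'
#' Two rectangular lobes of duration `delta` separated by `Delta`
#' (leading-edge to leading-edge), same polarity, with one refocusing
#' pulse between them, giving the textbook
#' \eqn{b = \gamma^2 g^2 \delta^2 (\Delta - \delta/3)}.
#'
#' @param delta lobe duration (ms).
#' @param Delta lobe separation (ms), `Delta >= delta`.
#' @param g gradient amplitude (mT/m).
#' @param direction unit 3-vector.
#' @return A [waveform()].
#' @export
stejskal_tanner_waveform <- function(delta, Delta, g, direction = c(1, 0, 0)) {
  if (delta <= 0 || Delta < delta) stop("need 0 < delta <= Delta")
  direction <- direction / sqrt(sum(direction^2))
  seg <- data.frame(t_start = c(0, Delta), duration = delta,
                    gx = g * direction[1],
                    gy = g * direction[2],
                    gz = g * direction[3])
  waveform(seg, refocus_times = (delta + Delta) / 2,
           meta = list(delta = delta, Delta = Delta, g = g, direction = direction))
}

#' b-matrix of a waveform
#'
#' Computes \eqn{B = \int_0^T q(t) q(t)^\top dt} with
#' \eqn{q(t) = \gamma \int_0^t g_{\mathrm{eff}}(t') dt'}, where the
#' effective gradient carries the refocusing-pulse sign flips. Cross-terms
#' between concurrent gradient components are included. The integral is
#' evaluated exactly per piecewise-linear segment of `q` unless a step
#' `dt` is given, in which case a midpoint Riemann sum is used (for
#' convergence checks).
#'
#' @param w a [waveform()].
#' @param dt optional time step (ms) for numerical integration; `NULL`
#'   (default) uses the exact piecewise closed form.
#' @return List of class `b_matrix` with `B` (symmetric 3 x 3, ms/um^2)
#'   and `b` (its trace).
#' @examples
#' b_matrix(stejskal_tanner_waveform(10, 30, 40))$b
#' @export
b_matrix <- function(w, dt = NULL) {
  seg <- .effective_segments(w)
  Tend <- waveform_duration(w)
  if (nrow(seg) == 0 || Tend == 0) {
    return(structure(list(B = matrix(0, 3, 3), b = 0), class = "b_matrix"))
  }
  gfun <- function(t) {
    # effective gradient at times t (vectorized), 3 columns
    out <- matrix(0, length(t), 3)
    for (k in seq_len(nrow(seg))) {
      inside <- t >= seg$t_start[k] & t < seg$t_start[k] + seg$duration[k]
      out[inside, ] <- matrix(rep(c(seg$gx[k], seg$gy[k], seg$gz[k]),
                                  each = sum(inside)), ncol = 3)
    }
    out
  }
  if (!is.null(dt)) {
    tm <- seq(dt / 2, Tend, by = dt)
    G <- gfun(tm)
    qv <- apply(G, 2, function(col) cumsum(col) * dt) * .gamma_um
    B <- t(qv) %*% qv * dt
    qend <- qv[nrow(qv), ]
  } else {
    # exact: q is piecewise linear between the breakpoints
    bp <- sort(unique(c(0, seg$t_start, seg$t_start + seg$duration, Tend)))
    B <- matrix(0, 3, 3)
    q <- c(0, 0, 0)
    for (k in seq_len(length(bp) - 1)) {
      h <- bp[k + 1] - bp[k]
      gmid <- as.numeric(gfun(bp[k] + h / 2))
      cvec <- .gamma_um * gmid
      B <- B + (q %o% q) * h + (q %o% cvec + cvec %o% q) * h^2 / 2 +
        (cvec %o% cvec) * h^3 / 3
      q <- q + cvec * h
    }
    qend <- q
  }
  if (sqrt(sum(qend^2)) > 1e-8 * max(1, sqrt(sum(diag(B)))))
    stop("unbalanced waveform: nonzero net q at end of train")
  structure(list(B = (B + t(B)) / 2, b = sum(diag(B))), class = "b_matrix")
}

#' @export
print.b_matrix <- function(x, ...) {
  cat(sprintf("b_matrix: trace b = %.4g ms/um^2\n", x$b))
  print(signif(x$B, 4))
  invisible(x)
}

#' Scale a waveform's gradient amplitude to a target b-value
#'
#' Uses the quadratic scaling of b with gradient amplitude:
#' `g' = g * sqrt(b_target / b(g))`.
#'
#' @param w a [waveform()] with nonzero b.
#' @param b_target target trace b-value (ms/um^2).
#' @return The rescaled [waveform()].
#' @export
scale_waveform_to_b <- function(w, b_target) {
  b0 <- b_matrix(w)$b
  if (b0 <= 0) stop("cannot scale a zero-b waveform")
  fac <- sqrt(b_target / b0)
  w$segments$gx <- w$segments$gx * fac
  w$segments$gy <- w$segments$gy * fac
  w$segments$gz <- w$segments$gz * fac
  if (!is.null(w$meta$g)) w$meta$g <- w$meta$g * fac
  w
}

#' Write a waveform's effective gradient as CSV
#'
#' Columns `t_start_ms`, `duration_ms`, `gx`, `gy`, `gz`; the
#' refocusing-pulse sign flips are applied before writing, so the file is
#' directly usable by the restricted-diffusion Monte Carlo module.
#'
#' @param w a [waveform()].
#' @param path output path.
#' @export
write_waveform_csv <- function(w, path) {
  seg <- .effective_segments(w)
  d <- data.frame(t_start_ms = seg$t_start, duration_ms = seg$duration,
                  gx = seg$gx, gy = seg$gy, gz = seg$gz)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(NULL)
}

#' Read an effective-gradient waveform CSV
#'
#' @param path CSV with columns `t_start_ms`, `duration_ms`, `gx`, `gy`, `gz`.
#' @return A [waveform()] (no refocusing pulses; gradients are effective).
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("t_start_ms", "duration_ms", "gx", "gy", "gz")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("waveform CSV missing columns: ", paste(miss, collapse = ", "))
  waveform(data.frame(t_start = d$t_start_ms, duration = d$duration_ms,
                      gx = d$gx, gy = d$gy, gz = d$gz))
}

# Effective gradient sampled at midpoints of n steps of width dt
# (3 x n matrix), for the Monte Carlo phase integral.
.waveform_step_gradients <- function(w, dt) {
  seg <- .effective_segments(w)
  Tend <- waveform_duration(w)
  n <- ceiling(Tend / dt)
  tm <- (seq_len(n) - 0.5) * dt
  G <- matrix(0, 3, n)
  for (k in seq_len(nrow(seg))) {
    inside <- tm >= seg$t_start[k] & tm < seg$t_start[k] + seg$duration[k]
    G[1, inside] <- seg$gx[k]
    G[2, inside] <- seg$gy[k]
    G[3, inside] <- seg$gz[k]
  }
  G
}
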