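# Gradient-direction scheme construction: electrostatic repulsion on the
# sphere, uniform rotation sampling, and FSL-style scheme I/O.

#' Gradient scheme
#'
#' A sampling geometry: `N` unit gradient directions, the b-value ladder
#' they are applied at, and the number of repetitions per condition.
#'
#' @param directions N x 3 matrix of unit row vectors.
#' @param b_values numeric vector of b-values (ms/um^2), nonnegative.
#' @param n_reps repetitions per (direction, b) condition.
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, b_values, n_reps = 1L) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3) stop("directions must be an N x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("directions must be unit vectors (|e| = 1 within 1e-9)")
  if (any(b_values < 0)) stop("b_values must be nonnegative")
  if (nrow(directions) < 1) stop("at least one direction required")
  structure(
    list(directions = directions, b_values = sort(unique(b_values)),
         n_reps = as.integer(n_reps)),
    class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient_scheme: %d directions, b = {%s} ms/um^2, %d reps\n",
              nrow(x$directions), paste(signif(x$b_values, 3), collapse = ", "),
              x$n_reps))
  invisible(x)
}

# Antipodally symmetric electrostatic energy of a direction set
# (rows of e): sum over pairs of 1/|ei - ej| + 1/|ei + ej|, computed from
# the Gram matrix (|ei -+ ej|^2 = 2 -+ 2 ei.ej).
.electrostatic_energy <- function(e) {
  G <- e %*% t(e)
  g <- pmin(1 - 1e-15, pmax(-1 + 1e-15, G[upper.tri(G)]))
  sum(1 / sqrt(2 - 2 * g) + 1 / sqrt(2 + 2 * g))
}

.scheme_cache <- new.env(parent = emptyenv())

.angles_to_dirs <- function(par) {
  th <- par[seq(1, length(par), by = 2)]
  ph <- par[seq(2, length(par), by = 2)]
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Electrostatically repelled gradient directions
#'
#' Constructs `N` unit vectors minimizing the antipodally symmetric
#' electrostatic (Coulomb) energy
#' \eqn{\sum_{i<j} 1/|e_i - e_j| + 1/|e_i + e_j|}, the standard scheme
#' design for uniformly distributed diffusion gradient directions. The
#' energy is minimized over spherical angles with BFGS from `n_starts`
#' random initializations (best-energy winner); deterministic for a given
#' seed.
#'
#' @param N number of directions, at least 3.
#' @param seed integer RNG seed for the multi-start initialization.
#' @param n_starts number of random starts.
#' @param b_values,n_reps passed through to [gradient_scheme()].
#' @return A [gradient_scheme()] whose minimum pairwise (antipodally
#'   folded) angle is maximal-energy-optimal for the given starts.
#' @examples
#' sc <- electrostatic_directions(6, seed = 0)
#' @export
electrostatic_directions <- function(N, seed = 0L, n_starts = 5L,
                                     b_values = 0, n_reps = 1L) {
  if (N < 3) stop("N must be at least 3")
  key <- sprintf("N%d_s%d_k%d", N, seed, n_starts)
  if (!is.null(.scheme_cache[[key]]))
    return(gradient_scheme(.scheme_cache[[key]], b_values = b_values,
                           n_reps = n_reps))
  set.seed(seed)
  best <- NULL
  best_en <- Inf
  for (s in seq_len(n_starts)) {
    e0 <- matrix(stats::rnorm(3 * N), ncol = 3)
    e0 <- e0 / sqrt(rowSums(e0^2))
    par0 <- as.vector(t(cbind(acos(pmin(1, pmax(-1, e0[, 3]))),
                              atan2(e0[, 2], e0[, 1]))))
    fn <- function(par) .electrostatic_energy(.angles_to_dirs(par))
    opt <- stats::optim(par0, fn, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    # polish with a second pass (flat valleys near permutation symmetry)
    opt <- stats::optim(opt$par, fn, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    if (opt$value < best_en) {
      best_en <- opt$value
      best <- .angles_to_dirs(opt$par)
    }
  }
  .scheme_cache[[key]] <- best
  gradient_scheme(best, b_values = b_values, n_reps = n_reps)
}

#' Minimum pairwise folded angle of a direction set
#'
#' Smallest angle between any two directions after antipodal folding
#' (directions and their negatives identified), in degrees.
#'
#' @param scheme a [gradient_scheme()] or an N x 3 matrix.
#' @return Angle in degrees.
#' @export
scheme_min_angle <- function(scheme) {
  e <- if (inherits(scheme, "gradient_scheme")) scheme$directions else as.matrix(scheme)
  g <- abs(e %*% t(e))
  acos(min(1, max(g[upper.tri(g)]))) * 180 / pi
}

#' Uniformly distributed 3D rotations
#'
#' Samples `M` rotation matrices whose action on any fixed axis is uniform
#' on the sphere: a uniformly distributed image axis (normalized standard
#' normal 3-vector) combined with a uniform spin angle about it. Seeded
#' and reproducible.
#'
#' @param M number of rotations.
#' @param seed integer RNG seed.
#' @return A 3 x 3 x M array of rotation matrices (orthogonal, det +1).
#' @examples
#' R <- uniform_rotations(4, seed = 1)
#' @export
uniform_rotations <- function(M, seed = 0L) {
  if (M < 1) stop("M must be at least 1")
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * M), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  psi <- stats::runif(M, 0, 2 * pi)
  out <- array(NA_real_, c(3, 3, M))
  for (m in seq_len(M)) {
    a <- u[m, ]
    # any unit vector perpendicular to a
    v1 <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v1 <- v1 - sum(v1 * a) * a
    v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(a[2] * v1[3] - a[3] * v1[2],
            a[3] * v1[1] - a[1] * v1[3],
            a[1] * v1[2] - a[2] * v1[1])
    B <- cbind(v1, v2, a)              # maps z-axis to a, det +1
    Rz <- matrix(c(cos(psi[m]), sin(psi[m]), 0,
                   -sin(psi[m]), cos(psi[m]), 0,
                   0, 0, 1), 3, 3)
    out[, , m] <- B %*% Rz
  }
  out
}

#' Read an FSL-style bvec/bval scheme
#'
#' `bvec` is a 3 x N whitespace table of unit direction components; `bval`
#' is 1 x N in s/mm^2 and is converted to ms/um^2 (x 1e-3) on read.
#'
#' @param bvec_path,bval_path file paths.
#' @param n_reps repetitions per condition.
#' @return A [gradient_scheme()].
#' @export
read_bvec_bval <- function(bvec_path, bval_path, n_reps = 1L) {
  bvec <- as.matrix(utils::read.table(bvec_path))
  bval <- as.numeric(utils::read.table(bval_path))
  if (nrow(bvec) != 3) stop("bvec must have 3 rows")
  if (ncol(bvec) != length(bval)) stop("bvec/bval length mismatch")
  dirs <- t(bvec)
  nz <- sqrt(rowSums(dirs^2)) > 0
  dirs <- unique(round(dirs[nz, , drop = FALSE], 10))
  gradient_scheme(dirs, b_values = bval * 1e-3, n_reps = n_reps)
}

#' Write an FSL-style bvec/bval scheme
#'
#' Writes every (direction, b) combination as one column; b-values are
#' written in s/mm^2 (x 1e3).
#'
#' @param scheme a [gradient_scheme()].
#' @param bvec_path,bval_path output file paths.
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  e <- scheme$directions
  b <- scheme$b_values
  cols <- expand.grid(dir = seq_len(nrow(e)), b = b)
  bvec <- t(e[cols$dir, , drop = FALSE])
  bvec[, cols$b == 0] <- 0
  utils::write.table(format(bvec, digits = 10), bvec_path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(t(cols$b * 1e3), bval_path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a CSV scheme (columns ex, ey, ez, b_ms_per_um2)
#'
#' @param path CSV file path.
#' @param n_reps repetitions per condition.
#' @return A [gradient_scheme()].
#' @export
read_scheme_csv <- function(path, n_reps = 1L) {
  d <- utils::read.csv(path)
  need <- c("ex", "ey", "ez", "b_ms_per_um2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("scheme CSV missing columns: ", paste(miss, collapse = ", "))
  dirs <- unique(as.matrix(d[, c("ex", "ey", "ez")]))
  dirs <- dirs[rowSums(dirs^2) > 0, , drop = FALSE]
  gradient_scheme(dirs, b_values = unique(d$b_ms_per_um2), n_reps = n_reps)
}

#' Write a CSV scheme
#'
#' @param scheme a [gradient_scheme()].
#' @param path output CSV path.
#' @export
write_scheme_csv <- function(scheme, path) {
  cols <- expand.grid(dir = seq_len(nrow(scheme$directions)), b = scheme$b_values)
  d <- data.frame(ex = scheme$directions[cols$dir, 1],
                  ey = scheme$directions[cols$dir, 2],
                  ez = scheme$directions[cols$dir, 3],
                  b_ms_per_um2 = cols$b)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(NULL)
}
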