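# Dataset I/O and the composed analysis pipeline.

#' Write a directional dataset as CSV
#'
#' Long format, one row per (direction, b, repetition): columns
#' `dir_index`, `b_ms_per_um2`, `rep`, `amplitude` and optionally
#' `crlb_pct`.
#'
#' @param data a [directional_dataset()].
#' @param path output CSV path.
#' @export
write_directional_dataset <- function(data, path) {
  d <- dim(data$amplitudes)
  grid <- expand.grid(dir_index = seq_len(d[1]),
                      b_index = seq_len(d[2]),
                      rep = seq_len(d[3]))
  out <- data.frame(dir_index = grid$dir_index,
                    b_ms_per_um2 = data$scheme$b_values[grid$b_index],
                    rep = grid$rep,
                    amplitude = as.numeric(data$amplitudes))
  if (!is.null(data$crlb_pct))
    out$crlb_pct <- as.numeric(data$crlb_pct)[grid$dir_index +
                                                (grid$b_index - 1) * d[1]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(NULL)
}

#' Read a directional dataset from CSV
#'
#' Expects the long format of [write_directional_dataset()]; amplitudes
#' are cross-checked against the scheme (direction count, b-values) and
#' b-values are interpreted in ms/um^2.
#'
#' @param path CSV path.
#' @param scheme the [gradient_scheme()] the data were acquired with.
#' @return A [directional_dataset()].
#' @export
read_directional_dataset <- function(path, scheme) {
  d <- utils::read.csv(path)
  need <- c("dir_index", "b_ms_per_um2", "rep", "amplitude")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("dataset CSV missing columns: ", paste(miss, collapse = ", "))
  if (any(d$b_ms_per_um2 < 0)) stop("negative b-values in dataset")
  n_dir <- nrow(scheme$directions)
  got <- sort(unique(d$dir_index))
  if (!identical(got, seq_len(n_dir)) && !identical(got, as.integer(seq_len(n_dir)))) {
    missing_idx <- setdiff(seq_len(n_dir), got)
    if (length(missing_idx))
      stop("dataset is missing direction index(es): ",
           paste(missing_idx, collapse = ", "))
    stop("dataset direction indices exceed the scheme's ", n_dir, " directions")
  }
  bvals <- sort(unique(d$b_ms_per_um2))
  if (length(bvals) != length(scheme$b_values) ||
      any(abs(bvals - scheme$b_values) > 1e-9))
    stop("dataset b-values do not match the scheme")
  n_rep <- max(d$rep)
  amp <- array(NA_real_, c(n_dir, length(bvals), n_rep))
  bi <- match(d$b_ms_per_um2, bvals)
  amp[cbind(d$dir_index, bi, d$rep)] <- d$amplitude
  if (anyNA(amp)) stop("incomplete dataset: missing (direction, b, rep) cells")
  sc <- scheme
  sc$n_reps <- as.integer(n_rep)
  directional_dataset(sc, amp)
}

#' Run the full powder-averaging analysis pipeline
#'
#' Composes the analysis applied to each acquisition: powder averaging,
#' stick and tensor fits of the averaged decay, per-direction
#' initial-slope (gamma) diffusivities, macroscopic-tensor estimation
#' with its dispersion angle, and the high-b asymptote diagnostic.
#' Deterministic given the input data.
#'
#' @param data a [directional_dataset()].
#' @param out_dir optional directory; if given, writes `summary.json`,
#'   `powder_decay.csv` and `asymptote.csv` there.
#' @return A list of class `pipeline_result`: `decay`, `fit_stick`,
#'   `fit_tensor`, `gamma_fits`, `macro`, `theta_deg`, `asymptote`,
#'   `summary` (flat named list).
#' @examples
#' pre <- scenario_preset("PWM")
#' ds <- generate_dataset(pre, preset_scheme(pre), seed = 1)
#' run_full_pipeline(ds)$summary$theta_deg
#' @export
run_full_pipeline <- function(data, out_dir = NULL) {
  stopifnot(inherits(data, "directional_dataset"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  decay <- stage("powder_average", powder_average(data))
  fit_s <- stage("fit_stick", fit_powder_model(decay, "stick"))
  fit_t <- stage("fit_tensor", fit_powder_model(decay, "tensor"))
  rep_mean <- apply(data$amplitudes, c(1, 2), mean)
  gamma_fits <- stage("directional_adc_gamma",
                      apply(rep_mean, 1, function(y)
                        directional_adc_gamma(data$scheme$b_values, y)))
  D_i <- vapply(gamma_fits, function(f) f$mu, numeric(1))
  macro <- stage("solve_macro_tensor", solve_macro_tensor(D_i, data$scheme))
  theta <- stage("dispersion_angle",
                 dispersion_angle(macro$MD, min(macro$D_L, 3 * macro$MD)))
  asym <- stage("asymptote_check", asymptote_check(decay, fit_s))
  summary <- list(
    stick = list(model = "stick", S0 = fit_s$S0, D_L = fit_s$D_L,
                 D_T = 0, MD = fit_s$MD, uFA = fit_s$uFA,
                 converged = fit_s$converged),
    tensor = list(model = "tensor", S0 = fit_t$S0, D_L = fit_t$D_L,
                  D_T = fit_t$D_T, MD = fit_t$MD, uFA = fit_t$uFA,
                  converged = fit_t$converged),
    macro = list(MD = macro$MD, D_L = macro$D_L, D_T = macro$D_T,
                 FA = macro$FA),
    theta_deg = theta)
  res <- structure(list(decay = decay, fit_stick = fit_s, fit_tensor = fit_t,
                        gamma_fits = gamma_fits, macro = macro,
                        theta_deg = theta, asymptote = asym,
                        summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(decay, file.path(out_dir, "powder_decay.csv"),
                     row.names = FALSE)
    utils::write.csv(asym, file.path(out_dir, "asymptote.csv"),
                     row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$fit_stick)
  print(x$fit_tensor)
  print(x$macro)
  cat(sprintf("dispersion angle theta = %.1f deg\n", x$theta_deg))
  invisible(x)
}
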