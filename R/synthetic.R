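# Synthetic RD29A::LUC luminescence generator. Emulates the observable
# features of reporter assays - a unimodal pulse peaking ~5 h after ABA
# exposure, saturating dose dependence over 0-200 uM, and multiplicative
# replicate noise - without using the ODE model, so that calibration against
# these data is not circular. A second mode wraps simulator output with the
# same noise model for parameter-recovery experiments.

.lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  # meanlog chosen so the noise factor has mean 1 (replicate means converge
  # to the generator mean curve)
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate synthetic RD29A::LUC luminescence time courses
#'
#' The noise-free mean curve is `baseline + A(dose) * g(t)`, where `g` is a
#' log-Gaussian pulse with mode at `peak_time` and `A(dose)` is a saturating
#' Hill function of the ABA dose (half-saturation `dose_K`, exponent
#' `dose_hill`; saturating by 200 uM). Replicates apply independent
#' multiplicative log-normal noise with coefficient of variation `noise_cv`.
#' With `model` supplied, the mean curve is instead the simulated RD29A mRNA
#' trace at `dose`, rescaled to `amplitude` relative luminescence units -
#' use this mode for parameter-recovery tests.
#'
#' @param dose ABA dose in uM (>= 0).
#' @param peak_time Mode of the pulse in hours (default 5).
#' @param n_reps Number of replicates (default 3).
#' @param noise_cv Replicate coefficient of variation (default 0.1).
#' @param seed Optional integer seed for reproducibility.
#' @param times Sampling grid in hours (default 0-24 h every 0.5 h).
#' @param baseline Baseline luminescence in RLU (default 10).
#' @param amplitude Maximal dose amplitude in RLU (default 1000).
#' @param dose_K Half-saturating dose in uM (default 75).
#' @param dose_hill Hill exponent of the dose response (default 1).
#' @param shape_width Log-width of the pulse (default 0.9).
#' @param model Optional `aba_model`; switches to from-model mode.
#' @param ... Passed to [run_aba_protocol()] in from-model mode.
#' @return Tibble (`time_h`, `dose_uM`, `replicate`, `rlu`) of class
#'   `aba_luminescence`, with the generator ground truth in
#'   `attr(x, "truth")`.
#' @export
generate_luminescence <- function(dose, peak_time = 5, n_reps = 3,
                                  noise_cv = 0.1, seed = NULL,
                                  times = seq(0, 24, by = 0.5),
                                  baseline = 10, amplitude = 1000,
                                  dose_K = 75, dose_hill = 1,
                                  shape_width = 0.9, model = NULL, ...) {
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be at least 1", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(model)) {
    pulse <- ifelse(times > 0,
                    exp(-(log(times / peak_time))^2 / (2 * shape_width^2)), 0)
    amp <- if (dose > 0) {
      amplitude * dose^dose_hill / (dose_K^dose_hill + dose^dose_hill)
    } else 0
    mean_curve <- baseline + amp * pulse
    source <- "phenomenological"
  } else {
    traj <- run_aba_protocol(model, dose = dose,
                             post_duration = max(times), t_grid = times, ...)
    y <- traj[[RD29A_SPECIES]]
    mean_curve <- baseline +
      if (max(y) > 0) amplitude * y / max(y) else y
    source <- "from_model"
  }

  out <- tidyr::expand_grid(replicate = seq_len(n_reps), time_h = times) |>
    dplyr::mutate(dose_uM = dose,
                  rlu = rep(mean_curve, times = n_reps) *
                    .lognormal_noise(n_reps * length(times), noise_cv)) |>
    dplyr::select("time_h", "dose_uM", "replicate", "rlu")
  structure(out, class = c("aba_luminescence", class(out)),
            truth = list(source = source, peak_time = peak_time,
                         shape_width = shape_width, dose_K = dose_K,
                         dose_hill = dose_hill, noise_cv = noise_cv,
                         baseline = baseline, amplitude = amplitude,
                         seed = seed))
}

#' Synthetic dose-series readout at a fixed time
#'
#' Emulates end-point reporter assays: one luminescence value per replicate
#' per dose, read at `sample_time` hours after ABA exposure, summarised as
#' mean and standard error.
#'
#' @param doses Non-empty vector of ABA doses in uM.
#' @param sample_time Readout time in hours (default 5); must lie on the
#'   sampling grid of the generated curves.
#' @param seed Optional integer seed.
#' @param ... Passed to [generate_luminescence()].
#' @return Tibble (`dose_uM`, `mean_rlu`, `sem_rlu`, `n`).
#' @export
generate_dose_series <- function(doses, sample_time = 5, seed = NULL, ...) {
  if (length(doses) == 0) stop("doses must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  purrr::map(doses, function(d) {
    ds <- generate_luminescence(dose = d, seed = NULL, ...)
    if (!any(abs(ds$time_h - sample_time) < 1e-9)) {
      stop("sample_time ", sample_time, " h is outside the sampling grid",
           call. = FALSE)
    }
    vals <- ds$rlu[abs(ds$time_h - sample_time) < 1e-9]
    tibble::tibble(dose_uM = d, mean_rlu = mean(vals),
                   sem_rlu = stats::sd(vals) / sqrt(length(vals)),
                   n = length(vals))
  }) |>
    purrr::list_rbind()
}

#' Write / read a luminescence dataset (CSV + truth sidecar)
#'
#' @param data An `aba_luminescence` tibble.
#' @param path CSV path; generator truth goes to `<path>.meta.json`.
#' @return `path` invisibly; the reader returns the dataset.
#' @export
write_luminescence <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  jsonlite::write_json(attr(data, "truth"), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_luminescence
#' @export
read_luminescence <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  truth <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
  structure(out, class = c("aba_luminescence", class(out)), truth = truth)
}
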