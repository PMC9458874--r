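# Bounded grid-search calibration of the three undetermined expression
# parameters (kf26 feedback transcription, kf27 RD29A transcription, kf28
# feedback translation) against a transient-shape criterion and, optionally,
# luminescence time courses. Feasibility is decided by model output alone;
# data only refines the best point within the feasible set.

#' Score the transient shape of an RD29A response
#'
#' A response counts as transient when it peaks between 1 and 12 h after the
#' ABA step, declines to at most 80% of the peak by 24 h, and rises more than
#' 10-fold above the pre-step level. The continuous score (lower is better)
#' combines the distance of the peak time from the observed ~5 h and any
#' decline shortfall, for ranking among feasible parameter sets.
#'
#' @param traj An `aba_trajectory` covering at least 24 h post-step.
#' @param species Readout species.
#' @return One-row tibble: `is_transient`, `score`, plus the
#'   [peak_metrics()] columns.
#' @export
transient_score <- function(traj, species = RD29A_SPECIES) {
  if (max(traj$time_h) < 24) {
    stop("trajectory must cover at least 24 h post-step", call. = FALSE)
  }
  pm <- peak_metrics(traj, species)
  base <- attr(traj, "baseline")
  pre_level <- if (!is.null(base)) unname(base[species]) else traj[[species]][1]
  is_transient <- pm$peak_time >= 1 && pm$peak_time <= 12 &&
    pm$decline_ratio <= 0.8 && pm$peak_value > 10 * pre_level
  score <- abs(pm$peak_time - 5) / 5 + pmax(0, pm$decline_ratio - 0.8) / 0.2
  dplyr::bind_cols(tibble::tibble(is_transient = is_transient, score = score),
                   pm)
}

#' Peak-normalised root-mean-square error between two curves
#'
#' Both curves are rescaled to unit maximum before comparison, since
#' luminescence units are arbitrary relative to mRNA concentration.
#'
#' @param model_curve,data_curve Numeric vectors sampled on a common time
#'   grid, each with a positive maximum.
#' @return Dimensionless RMSE.
#' @export
normalized_rmse <- function(model_curve, data_curve) {
  if (length(model_curve) != length(data_curve)) {
    stop("curves must share a common time grid", call. = FALSE)
  }
  ma <- max(model_curve); mb <- max(data_curve)
  if (ma <= 0 || mb <= 0) stop("curves must have positive maxima",
                               call. = FALSE)
  sqrt(mean((model_curve / ma - data_curve / mb)^2))
}

#' Calibrate the expression parameters by bounded grid search
#'
#' Runs the 100 uM ABA step protocol at every grid point over (kf26, kf27,
#' kf28), marks points whose RD29A response is transient
#' ([transient_score()]), and - when luminescence data are supplied - ranks
#' feasible points by a scale-invariant RMSE against the replicate-mean
#' curve. Without data, feasible points are ranked by the transient score.
#' All other model parameters stay fixed.
#'
#' Because luminescence units are arbitrary, only the curve shape is
#' informative. The default objective (`objective = "scale_fit"`) fits the
#' proportionality constant between model and data by least squares before
#' taking the RMSE, which is robust to replicate noise at the curve maximum;
#' `objective = "peak_norm"` rescales both curves to unit maximum instead
#' (see [normalized_rmse()]). RD29A transcription (kf27) is a pure scale
#' factor of the readout, so no scale-invariant objective can identify it:
#' directions along which the objective is numerically flat are resolved to
#' the grid point nearest the centre of the tied set rather than an
#' arbitrary tie order.
#'
#' @param model An `aba_model`.
#' @param data Optional luminescence dataset from [generate_luminescence()]
#'   (tibble with `time_h`, `dose_uM`, `replicate`, `rlu`).
#' @param bounds Named list of c(lower, upper) for kf26, kf27, kf28 in h^-1.
#'   Defaults span the literature ranges: kf26, kf27 in [1, 20] and kf28 in
#'   [50, 500].
#' @param grid_step Named steps; defaults kf26 = 1, kf27 = 1, kf28 = 25 h^-1.
#' @param dose Calibration dose in uM (default 100).
#' @param post_duration Post-step hours simulated per grid point (default 48;
#'   the transient criterion reads the first 24 h).
#' @param objective Data objective: `"scale_fit"` (default) or
#'   `"peak_norm"`.
#' @param ... Passed to [run_aba_protocol()].
#' @return An `aba_calibration` object: list with `grid` (one row per point:
#'   parameters, feasibility, score, rmse, peak metrics), `best_params`,
#'   `objective_value`, `bounds`, `grid_step`. Use [tidy()] / [glance()].
#' @export
fit_expression_params <- function(model, data = NULL,
                                  bounds = list(kf26 = c(1, 20),
                                                kf27 = c(1, 20),
                                                kf28 = c(50, 500)),
                                  grid_step = c(kf26 = 1, kf27 = 1,
                                                kf28 = 25),
                                  dose = 100, post_duration = 48,
                                  objective = c("scale_fit", "peak_norm"),
                                  ...) {
  objective <- match.arg(objective)
  axes <- lapply(c("kf26", "kf27", "kf28"), function(p) {
    b <- bounds[[p]]
    if (is.null(b) || length(b) != 2 || b[1] > b[2]) {
      stop("bounds must give c(lower, upper) for ", p, call. = FALSE)
    }
    seq(b[1], b[2], by = grid_step[[p]])
  })
  names(axes) <- c("kf26", "kf27", "kf28")
  grid <- tidyr::expand_grid(kf26 = axes$kf26, kf27 = axes$kf27,
                             kf28 = axes$kf28)
  if (nrow(grid) == 0) stop("empty calibration grid", call. = FALSE)

  data_mean <- NULL
  if (!is.null(data)) {
    sub <- data[data$dose_uM == dose, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("data contain no rows at the calibration dose ", dose, " uM",
           call. = FALSE)
    }
    data_mean <- sub |>
      dplyr::group_by(.data$time_h) |>
      dplyr::summarise(rlu = mean(.data$rlu), .groups = "drop") |>
      dplyr::arrange(.data$time_h)
    data_mean <- data_mean[data_mean$time_h <= 24, , drop = FALSE]
  }
  t_grid <- unique(c(seq(0, 24, by = 0.1),
                     seq(24, post_duration, by = 0.5)))

  rows <- purrr::pmap(grid, function(kf26, kf27, kf28) {
    m <- set_parameters(model, c(kf26 = kf26, kf27 = kf27, kf28 = kf28))
    traj <- run_aba_protocol(m, dose = dose, post_duration = post_duration,
                             t_grid = t_grid, ...)
    ts <- transient_score(traj)
    rmse <- NA_real_
    if (!is.null(data_mean)) {
      y <- stats::approx(traj$time_h, traj[[RD29A_SPECIES]],
                         xout = data_mean$time_h)$y
      rmse <- if (max(y) <= 0) {
        Inf
      } else if (objective == "peak_norm") {
        normalized_rmse(y, data_mean$rlu)
      } else {
        a <- sum(y * data_mean$rlu) / sum(y * y)
        sqrt(mean((a * y - data_mean$rlu)^2)) / max(data_mean$rlu)
      }
    }
    dplyr::bind_cols(tibble::tibble(kf26 = kf26, kf27 = kf27, kf28 = kf28,
                                    rmse = rmse), ts)
  })
  grid_out <- purrr::list_rbind(rows)

  feas <- grid_out[grid_out$is_transient, , drop = FALSE]
  pool <- if (nrow(feas) > 0) feas else grid_out
  obj <- if (!is.null(data_mean)) pool$rmse else pool$score
  # collapse numerically flat directions to the centre of the tied set
  omin <- min(obj)
  tied <- which(obj <= omin + 1e-6 * (abs(omin) + 1e-12))
  if (length(tied) > 1) {
    pts <- as.matrix(pool[tied, c("kf26", "kf27", "kf28")])
    units <- c(grid_step[["kf26"]], grid_step[["kf27"]], grid_step[["kf28"]])
    ctr <- colMeans(pts)
    dist <- rowSums(sweep(sweep(pts, 2, ctr), 2, units, "/")^2)
    ibest <- tied[which.min(dist)]
  } else {
    ibest <- tied[1]
  }
  best <- pool[ibest, c("kf26", "kf27", "kf28")]
  structure(
    list(grid = grid_out,
         best_params = unlist(best),
         objective_value = obj[ibest],
         feasible_set = feas[, c("kf26", "kf27", "kf28")],
         bounds = bounds, grid_step = grid_step, dose = dose,
         used_data = !is.null(data_mean)),
    class = "aba_calibration")
}

#' @export
print.aba_calibration <- function(x, ...) {
  cat("<aba_calibration> ", nrow(x$grid), " grid points, ",
      nrow(x$feasible_set), " transient-feasible\n", sep = "")
  cat("  best:", paste(names(x$best_params), signif(x$best_params, 4),
                       sep = " = ", collapse = ", "), "\n")
  cat("  objective (", if (x$used_data) "normalised RMSE" else
    "transient score", "): ", signif(x$objective_value, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the calibration grid
#'
#' @param x An `aba_calibration`.
#' @param ... Unused.
#' @return The per-grid-point tibble.
#' @method tidy aba_calibration
#' @export
tidy.aba_calibration <- function(x, ...) x$grid

#' One-row calibration summary
#'
#' @param x An `aba_calibration`.
#' @param ... Unused.
#' @return Tibble with grid size, feasible count, best parameters and
#'   objective value.
#' @method glance aba_calibration
#' @export
glance.aba_calibration <- function(x, ...) {
  tibble::tibble(n_grid = nrow(x$grid), n_feasible = nrow(x$feasible_set),
                 kf26 = x$best_params[["kf26"]],
                 kf27 = x$best_params[["kf27"]],
                 kf28 = x$best_params[["kf28"]],
                 objective = x$objective_value,
                 used_data = x$used_data)
}

#' Write a calibration result to CSV plus a summary text file
#'
#' @param fit An `aba_calibration`.
#' @param path CSV path for the grid; the summary goes to `<path>.summary.txt`.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(fit, path) {
  readr::write_csv(fit$grid, path)
  summary_lines <- c(
    sprintf("grid points: %d", nrow(fit$grid)),
    sprintf("feasible (transient) points: %d", nrow(fit$feasible_set)),
    sprintf("best: kf26 = %g, kf27 = %g, kf28 = %g h^-1",
            fit$best_params[["kf26"]], fit$best_params[["kf27"]],
            fit$best_params[["kf28"]]),
    sprintf("objective: %g (%s)", fit$objective_value,
            if (fit$used_data) "normalised RMSE" else "transient score"))
  writeLines(summary_lines, paste0(path, ".summary.txt"))
  invisible(path)
}
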