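# In-silico experiment battery: peak metrics, dose-response, knockouts,
# feedback ablation, and local sensitivity analysis. The readout species for
# all experiments is the accumulated RD29A mRNA pool.

RD29A_SPECIES <- "mRNA_RD29A"

#' Summarise the peak behaviour of one species
#'
#' @param traj An `aba_trajectory`.
#' @param species Species name (default the RD29A mRNA readout).
#' @return One-row tibble: `species`, `peak_value` (uM), `peak_time` (h),
#'   `value_at_5h`, `value_at_24h`, `decline_ratio` (value at 24 h divided by
#'   the peak; 1 for an all-zero trace).
#' @export
peak_metrics <- function(traj, species = RD29A_SPECIES) {
  if (!species %in% names(traj)) {
    stop("species not in trajectory: ", species, call. = FALSE)
  }
  y <- traj[[species]]
  tt <- traj$time_h
  at <- function(h) {
    if (h < min(tt) || h > max(tt)) return(NA_real_)
    stats::approx(tt, y, xout = h)$y
  }
  ipk <- which.max(y)
  peak <- y[ipk]
  tibble::tibble(
    species = species,
    peak_value = peak,
    peak_time = tt[ipk],
    value_at_5h = at(5),
    value_at_24h = at(24),
    decline_ratio = if (peak > 0) at(24) / peak else 1
  )
}

#' ABA dose-response scan
#'
#' Runs the full step protocol once per dose and summarises the RD29A mRNA
#' response. The model saturates over a narrower range (0-50 uM) than real
#' plants (0-200 uM).
#'
#' @param model An `aba_model`.
#' @param doses ABA doses in uM; default `c(0, 1, 5, 10, 25, 50, 100, 200)`.
#' @param species Readout species.
#' @param ... Passed to [run_aba_protocol()].
#' @return Tibble with one row per dose: the dose plus the [peak_metrics()]
#'   columns, ordered by dose.
#' @export
dose_response <- function(model, doses = c(0, 1, 5, 10, 25, 50, 100, 200),
                          species = RD29A_SPECIES, ...) {
  if (length(doses) == 0) stop("doses must be non-empty", call. = FALSE)
  if (anyDuplicated(doses)) stop("doses must be unique", call. = FALSE)
  doses <- sort(doses)
  purrr::map(doses, function(d) {
    pm <- peak_metrics(run_aba_protocol(model, dose = d, ...), species)
    dplyr::bind_cols(tibble::tibble(dose = d), pm)
  }) |>
    purrr::list_rbind()
}

# Expression channels per gene, as reaction ids.
.channel_ids <- function(gene, channel = c("constitutive", "feedback")) {
  channel <- match.arg(channel)
  switch(channel,
         constitutive = paste0("translation_", gene),
         feedback = paste0("fb_translation_", gene))
}

.disable_reactions <- function(model, ids) {
  missing <- setdiff(ids, model$reactions$id)
  if (length(missing) > 0) {
    stop("unknown reaction(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  model$reactions$scale[model$reactions$id %in% ids] <- 0
  .recompile(model)
}

#' Simulate a gene knockout
#'
#' Mimics a null mutant by zeroing the gene's constitutive translation
#' channel (the kf30 reaction), and additionally its feedback translation
#' channel (kf28) for the feedback-regulated genes ABF and PP2C.
#'
#' @param model An `aba_model`.
#' @param target One of `"PYR"`, `"PP2C"`, `"SnRK2"`, `"ABF"`.
#' @return A modified `aba_model`.
#' @export
knockout <- function(model, target) {
  target <- match.arg(target, c("PYR", "PP2C", "SnRK2", "ABF"))
  ids <- .channel_ids(target, "constitutive")
  if (target %in% c("ABF", "PP2C")) {
    ids <- c(ids, .channel_ids(target, "feedback"))
  }
  .disable_reactions(model, ids)
}

#' Ablate one ABRE feedback loop
#'
#' Removes only the ABRE-driven transcription channel (the kf26 reaction) of
#' the given feedback gene; constitutive expression is untouched. Removing
#' the PP2C loop converts the transient RD29A response into sustained
#' (logarithmic) accumulation about two orders of magnitude higher.
#'
#' @param model An `aba_model`.
#' @param gene One of `"ABF"`, `"DREB2A"`, `"PP2C"`.
#' @return A modified `aba_model`.
#' @export
feedback_ablation <- function(model, gene) {
  gene <- match.arg(gene, c("ABF", "DREB2A", "PP2C"))
  .disable_reactions(model, paste0("fb_transcription_", gene))
}

#' Peak fold change between two trajectories
#'
#' @param traj_a,traj_b Trajectories sharing `species`.
#' @param species Species name.
#' @return peak(traj_a) / peak(traj_b).
#' @export
fold_change <- function(traj_a, traj_b, species = RD29A_SPECIES) {
  pa <- peak_metrics(traj_a, species)$peak_value
  pb <- peak_metrics(traj_b, species)$peak_value
  if (pb == 0) stop("denominator trajectory has zero peak", call. = FALSE)
  pa / pb
}

# The fourteen binding / enzymatic / degradation parameters scanned by
# default: complex dissociation rates, the catalytic steps for SnRK2
# phosphorylation and ABF-P dephosphorylation, and PYR turnover.
SENSITIVITY_PARAMS <- c("kr1", "kr2", "kr3", "kr4", "kr5", "kr7", "kr9",
                        "kr10", "kr11", "kr14", "kr16", "kf15", "kf17",
                        "kf21")

#' Local sensitivity analysis of the RD29A response
#'
#' Normalised (log-log) local sensitivity of the RD29A mRNA trajectory to
#' each parameter, by central finite differences of two full protocol runs
#' per parameter: the index is the time integral over 0-24 h of
#' |d ln RD29A(t) / d ln p|.
#'
#' @param model An `aba_model`.
#' @param parameter_names Parameters to scan (default the fourteen
#'   binding/enzymatic/degradation constants in `SENSITIVITY_PARAMS`).
#' @param perturbation Relative perturbation for the central difference
#'   (default 0.01).
#' @param dose ABA dose in uM (default 100).
#' @param window Integration window in hours (default 24).
#' @param ... Passed to [run_aba_protocol()].
#' @return Tibble `parameter`, `sensitivity`, `rank` (1 = most sensitive),
#'   sorted by rank.
#' @export
local_sensitivity <- function(model, parameter_names = SENSITIVITY_PARAMS,
                              perturbation = 0.01, dose = 100, window = 24,
                              ...) {
  if (perturbation <= 0) stop("perturbation must be positive", call. = FALSE)
  base_vals <- param_value(model$parameters, parameter_names)
  t_grid <- seq(0, window, by = 0.25)
  run <- function(overrides) {
    traj <- run_aba_protocol(set_parameters(model, overrides), dose = dose,
                             post_duration = window, t_grid = t_grid, ...)
    traj[[RD29A_SPECIES]]
  }
  floor_ <- 1e-300
  idx <- purrr::map_dbl(seq_along(parameter_names), function(i) {
    p <- parameter_names[i]; v <- base_vals[i]
    up <- run(stats::setNames(v * (1 + perturbation), p))
    dn <- run(stats::setNames(v * (1 - perturbation), p))
    dlny <- abs(log(pmax(up, floor_)) - log(pmax(dn, floor_)))
    s <- dlny / (2 * perturbation)
    s[up <= 0 & dn <= 0] <- 0
    # trapezoidal time integral over the window
    sum(diff(t_grid) * (utils::head(s, -1) + utils::tail(s, -1)) / 2)
  })
  out <- tibble::tibble(parameter = parameter_names, sensitivity = idx)
  out$rank <- rank(-out$sensitivity, ties.method = "first")
  dplyr::arrange(out, .data$rank)
}
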