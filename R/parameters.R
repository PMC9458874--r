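# Rate-constant registry for the ABA -> RD29A model.
#
# Internal unit system: hours and micromolar. Literature values quoted in
# s^-1 or uM^-1 s^-1 are converted on construction (x 3600). Expression and
# turnover rates are already per hour.

SECONDS_PER_HOUR <- 3600

# Curated rate constants in their source units. `per_s` entries are converted
# to h^-1 (first order) or uM^-1 h^-1 (second order) by build_parameter_table().
.param_defs <- function() {
  row <- function(name, value, unit, fixed, desc) {
    tibble::tibble(name = name, value = value, unit = unit, fixed = fixed,
                   description = desc)
  }
  second_order <- function(name, desc, value = 1000, fixed = TRUE) {
    row(name, value, "uM^-1 s^-1", fixed, desc)
  }
  first_order <- function(name, value, desc, fixed = TRUE) {
    row(name, value, "s^-1", fixed, desc)
  }
  per_hour <- function(name, value, desc, fixed = TRUE) {
    row(name, value, "h^-1", fixed, desc)
  }

  dplyr::bind_rows(
    second_order("kf1", "ABA + PYR association"),
    first_order("kr1", 69000, "ABA.PYR dissociation (KD ~ 69 uM)"),
    second_order("kf2", "PP2C + SnRK2 association"),
    first_order("kr2", 0.1, "PP2C.SnRK2 dissociation (KD 100 pM)"),
    second_order("kf3", "PP2C + SnRK2-P association"),
    first_order("kr3", 97, "PP2C.SnRK2-P dissociation (KM 0.097 uM)"),
    second_order("kf4", "SnRK2 + MAP3K association"),
    first_order("kr4", 23000, "SnRK2.MAP3K dissociation (KM 23 uM)"),
    second_order("kf5", "SnRK2-P + ABF association"),
    first_order("kr5", 19300, "SnRK2-P.ABF dissociation (KM 19.3 uM)"),
    second_order("kf6", "ABA + 26S proteasome association (assumed)"),
    first_order("kr6", 50, "ABA.proteasome dissociation (assumed)"),
    second_order("kf7", "ABA.PYR + PP2C association"),
    first_order("kr7", 30, "ABA.PYR.PP2C dissociation (KD 30 nM)"),
    second_order("kf8", "ABA.PYR + PP2C.SnRK2 association"),
    first_order("kr8", 30, "ABA.PYR.PP2C.SnRK2 dissociation (KD 30 nM)"),
    second_order("kf9", "ABF-P + PP2C association"),
    first_order("kr9", 11150, "ABF-P.PP2C dissociation (KM 11.15 uM)"),
    second_order("kf10", "ABF-P + ABRE association, feedback genes"),
    first_order("kr10", 2, "ABF-P/ABRE dissociation, feedback genes (KD 2 nM)"),
    second_order("kf11", "DREB2A + DRE association, free RD29A promoter"),
    first_order("kr11", 2, "DREB2A/DRE dissociation (KD 2 nM)"),
    second_order("kf12", "ABF-P + ABRE association, free RD29A promoter"),
    first_order("kr12", 2, "ABF-P/ABRE dissociation, free RD29A promoter"),
    second_order("kf13", "DREB2A + DRE association, ABRE-occupied RD29A promoter"),
    first_order("kr13", 2, "DREB2A/DRE dissociation, ABRE-occupied promoter"),
    second_order("kf14", "ABF-P + ABRE association, DRE-occupied RD29A promoter"),
    first_order("kr14", 2, "ABF-P/ABRE dissociation, RD29A promoter (KD 2 nM)"),
    first_order("kf15", 14, "SnRK2 phosphorylation by MAP3K (kcat)"),
    second_order("kf16", "DREB2A + 26S proteasome association (assumed)",
                 value = 5),
    first_order("kr16", 50, "DREB2A.proteasome dissociation (assumed)"),
    first_order("kcat16", 10, "DREB2A proteolysis by bound proteasome"),
    first_order("kf17", 1.04, "ABF-P dephosphorylation by PP2C (kcat)"),
    first_order("kf18", 10, "SnRK2 release from ABA.PYR.PP2C.SnRK2"),
    first_order("kf19", 0.924, "SnRK2-P dephosphorylation by PP2C (kcat)"),
    first_order("kf20", 0.04, "ABF phosphorylation by SnRK2-P (kcat)"),
    per_hour("kf26", 10, "ABRE-driven (feedback) transcription", fixed = FALSE),
    per_hour("kf27", 10, "RD29A transcription from doubly occupied promoter",
             fixed = FALSE),
    per_hour("kf28", 200, "Translation of ABRE-driven feedback mRNA",
             fixed = FALSE),
    per_hour("kf29", 1, "Constitutive transcription"),
    per_hour("kf30", 4.5, "Constitutive translation"),
    per_hour(sprintf("kf%d", c(21:25, 31:45, 49)), 0.05,
             "Protein / protein-complex degradation"),
    per_hour(sprintf("kf%d", 46:48), 0.06, "mRNA degradation")
  )
}

#' Build the model parameter table
#'
#' Assembles the full rate-constant table of the ABA signaling model in the
#' internal unit system (hours, micromolar). Association rate constants are
#' \eqn{1000\ \mu M^{-1} s^{-1}} throughout; dissociation and catalytic rates
#' come from in-vitro literature values; expression and turnover rates are
#' per-hour averages for eukaryotic cells. The only non-fixed entries are the
#' three undetermined expression parameters \code{kf26} (feedback
#' transcription), \code{kf27} (RD29A transcription) and \code{kf28} (feedback
#' translation), which [fit_expression_params()] calibrates.
#'
#' @param overrides Named numeric vector or list of parameter values (internal
#'   units) replacing defaults, e.g. \code{c(kf27 = 0)}. Names must exist in
#'   the default table; values must be non-negative.
#' @return A tibble with columns \code{name}, \code{value} (h^-1 or
#'   uM^-1 h^-1), \code{unit} (internal unit), \code{fixed}, and
#'   \code{description}.
#' @examples
#' pt <- build_parameter_table()
#' param_value(pt, "kr10") / param_value(pt, "kf10") # ABF-P/ABRE KD, 2e-3 uM
#' @export
build_parameter_table <- function(overrides = NULL) {
  defs <- .param_defs()
  tbl <- defs |>
    dplyr::mutate(
      value = dplyr::case_when(
        .data$unit == "s^-1" ~ .data$value * SECONDS_PER_HOUR,
        .data$unit == "uM^-1 s^-1" ~ .data$value * SECONDS_PER_HOUR,
        TRUE ~ .data$value
      ),
      unit = dplyr::case_when(
        .data$unit == "s^-1" ~ "h^-1",
        .data$unit == "uM^-1 s^-1" ~ "uM^-1 h^-1",
        TRUE ~ .data$unit
      )
    )
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), tbl$name)
    if (length(bad) > 0) {
      stop("unknown parameter name(s) in overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(overrides)) || any(overrides < 0)) {
      stop("override values must be finite and non-negative", call. = FALSE)
    }
    idx <- match(names(overrides), tbl$name)
    tbl$value[idx] <- unname(overrides)
  }
  tbl
}

#' Look up a parameter value
#'
#' @param params Parameter table from [build_parameter_table()].
#' @param name Parameter name(s).
#' @return Numeric value(s) in internal units.
#' @export
param_value <- function(params, name) {
  idx <- match(name, params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ", paste(name[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  params$value[idx]
}

#' Write / read a flat parameter config file
#'
#' One parameter per line: \code{name value unit}, whitespace separated,
#' \code{#} comments allowed.
#'
#' @param params Parameter table.
#' @param path File path.
#' @return `read_parameter_config()` returns a parameter table; the writer
#'   returns `path` invisibly.
#' @export
write_parameter_config <- function(params, path) {
  lines <- c("# abasignal parameter table (internal units: h, uM)",
             sprintf("%-8s %.12g %s", params$name, params$value, params$unit))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_parameter_config
#' @export
read_parameter_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  vals <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  names(vals) <- vapply(parts, `[[`, character(1), 1)
  build_parameter_table(overrides = vals)
}
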