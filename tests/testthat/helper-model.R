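# Shared fixtures, built once per test run. The wild-type 100 uM protocol
# trajectory and the feedback-off equilibrium are reused across test files.
.fixtures <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_model()
  .fixtures$model
}

wt_trajectory <- function() {
  if (is.null(.fixtures$wt)) {
    .fixtures$wt <- run_aba_protocol(default_model(), dose = 100)
  }
  .fixtures$wt
}

feedback_off_equilibrium <- function() {
  if (is.null(.fixtures$eq0)) {
    m0 <- set_parameters(default_model(), c(kf26 = 0))
    .fixtures$eq0 <- equilibrate(m0)
  }
  .fixtures$eq0
}

# Minimal hand-built model: one reversible binding A + B <-> C plus optional
# first-order decay of D, compiled with the package's own machinery. Used to
# check the integrator against closed-form equilibria and exponential decay.
toy_binding_model <- function(kf = 10, kr = 2, kdecay = 0.05,
                              a0 = 0.1, b0 = 0.1, d0 = 1) {
  species <- tibble::tibble(
    name = c("A", "B", "C", "D"),
    role = "protein",
    clamped = FALSE,
    initial_concentration = c(a0, b0, 0, d0))
  reactions <- tibble::tibble(
    id = c("binding", "decay"),
    kind = c("reversible_binding", "degradation"),
    reactants = list(c(A = 1, B = 1), c(D = 1)),
    products = list(c(C = 1), stats::setNames(numeric(0), character(0))),
    forward_param = c("kf", "kdecay"),
    reverse_param = c("kr", NA),
    gene = NA_character_, scale = 1)
  parameters <- tibble::tibble(
    name = c("kf", "kr", "kdecay"),
    value = c(kf, kr, kdecay),
    unit = c("uM^-1 h^-1", "h^-1", "h^-1"),
    fixed = TRUE, description = "toy")
  model <- structure(
    list(species = species, reactions = reactions, parameters = parameters,
         cell_volume = 50, gene_copies = 2),
    class = "aba_model")
  model$compiled <- abasignal:::.compile_model(model)
  model
}

# Closed-form equilibrium of A + B <-> C from initial (a0, b0, 0):
# kf (a0 - c)(b0 - c) = kr c, smaller root of the quadratic.
toy_binding_equilibrium <- function(kf, kr, a0, b0) {
  k <- kr / kf
  disc <- (a0 + b0 + k)^2 - 4 * a0 * b0
  ((a0 + b0 + k) - sqrt(disc)) / 2
}

# Wrap a plain time/value table as a trajectory for peak-metric tests.
as_toy_trajectory <- function(time_h, value, species = "mRNA_RD29A") {
  out <- tibble::tibble(time_h = time_h)
  out[[species]] <- value
  structure(out, class = c("aba_trajectory", class(out)))
}
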