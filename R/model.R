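# Reaction network of the ABA -> RD29A gene-expression model.
#
# Species fall into six roles: free proteins, protein complexes, mRNA pools,
# promoter states (gene loci), the clamped ABA ligand, and constitutive gene
# loci. All rate laws are elementary mass action; enzymatic steps are
# binding + catalytic pairs so that KM = (kr + kcat)/kf.

AVOGADRO <- 6.02214076e23

.CORE_GENES <- c("PYR", "PP2C", "SnRK2", "ABF", "DREB2A", "MAP3K", "PROT26S")
.FEEDBACK_GENES <- c("PP2C", "ABF", "DREB2A")

# Table 1 degradation-parameter allocation: one name per protein or complex
# (DNA-bound transcription-factor states are exempt to conserve gene loci).
.PROTEIN_DEG <- c(
  SnRK2 = "kf21", PYR = "kf22", PP2C = "kf23", ABF = "kf24", DREB2A = "kf25",
  SnRK2_P = "kf31", ABF_P = "kf32", MAP3K = "kf33", PROT26S = "kf34",
  ABA_PYR = "kf35", PP2C_SnRK2 = "kf36", PP2C_SnRK2_P = "kf37",
  SnRK2_MAP3K = "kf38", SnRK2_P_ABF = "kf39", ABA_PROT26S = "kf40",
  ABA_PYR_PP2C = "kf41", ABA_PYR_PP2C_SnRK2 = "kf42", ABF_P_PP2C = "kf43",
  DREB2A_PROT26S = "kf44")

#' Convert molecule copy number to concentration
#'
#' @param copies Number of molecules (>= 0).
#' @param volume Cell volume in cubic micrometers (> 0); default 50.
#' @return Concentration in micromolar.
#' @examples
#' molecules_to_concentration(2, 50) # two gene copies in a 50 um^3 cell
#' @export
molecules_to_concentration <- function(copies, volume = 50) {
  if (any(volume <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(copies < 0)) stop("copies must be non-negative", call. = FALSE)
  copies / (AVOGADRO * volume * 1e-15) * 1e6
}

.species_table <- function(locus_conc) {
  sp <- function(name, role, clamped = FALSE, init = 0) {
    tibble::tibble(name = name, role = role, clamped = clamped,
                   initial_concentration = init)
  }
  dplyr::bind_rows(
    sp("ABA", "ligand", clamped = TRUE),
    sp(.CORE_GENES, "protein"),
    sp(c("SnRK2_P", "ABF_P"), "protein"),
    sp(c("ABA_PYR", "PP2C_SnRK2", "PP2C_SnRK2_P", "SnRK2_MAP3K",
         "SnRK2_P_ABF", "ABA_PROT26S", "ABA_PYR_PP2C", "ABA_PYR_PP2C_SnRK2",
         "ABF_P_PP2C", "DREB2A_PROT26S"), "protein_complex"),
    sp(paste0("gene_", .CORE_GENES), "gene_locus", init = locus_conc),
    sp(paste0("ABRE_", .FEEDBACK_GENES, "_free"), "promoter_state",
       init = locus_conc),
    sp(paste0("ABRE_", .FEEDBACK_GENES, "_bound"), "promoter_state"),
    sp("RD29Aprom_free", "promoter_state", init = locus_conc),
    sp(c("RD29Aprom_ABRE", "RD29Aprom_DRE", "RD29Aprom_both"),
       "promoter_state"),
    sp(paste0("mRNA_", .CORE_GENES), "mrna"),
    sp(paste0("fb_mRNA_", .FEEDBACK_GENES), "mrna"),
    sp("mRNA_RD29A", "mrna")
  )
}

.reaction_table <- function() {
  rxn <- function(id, kind, reactants, products, fwd, rev = NA_character_,
                  gene = NA_character_) {
    tibble::tibble(id = id, kind = kind,
                   reactants = list(reactants), products = list(products),
                   forward_param = fwd, reverse_param = rev,
                   gene = gene, scale = 1)
  }
  stoich <- function(x) stats::setNames(rep(1, length(x)), x)
  bind <- function(id, a, b, ab, kf, kr) {
    rxn(id, "reversible_binding", stoich(c(a, b)), stoich(ab), kf, kr)
  }
  cat_ <- function(id, from, to, k) {
    rxn(id, "catalytic", stoich(from), stoich(to), k)
  }

  rows <- list(
    # -- signal transduction ------------------------------------------------
    bind("ABA_PYR_binding", "ABA", "PYR", "ABA_PYR", "kf1", "kr1"),
    bind("PP2C_SnRK2_binding", "PP2C", "SnRK2", "PP2C_SnRK2", "kf2", "kr2"),
    bind("PP2C_SnRK2P_binding", "PP2C", "SnRK2_P", "PP2C_SnRK2_P",
         "kf3", "kr3"),
    cat_("SnRK2P_dephosphorylation", "PP2C_SnRK2_P", c("PP2C", "SnRK2"),
         "kf19"),
    bind("SnRK2_MAP3K_binding", "SnRK2", "MAP3K", "SnRK2_MAP3K",
         "kf4", "kr4"),
    cat_("SnRK2_phosphorylation", "SnRK2_MAP3K", c("SnRK2_P", "MAP3K"),
         "kf15"),
    bind("SnRK2P_ABF_binding", "SnRK2_P", "ABF", "SnRK2_P_ABF",
         "kf5", "kr5"),
    cat_("ABF_phosphorylation", "SnRK2_P_ABF", c("SnRK2_P", "ABF_P"),
         "kf20"),
    bind("ABA_PROT26S_binding", "ABA", "PROT26S", "ABA_PROT26S",
         "kf6", "kr6"),
    bind("ABAPYR_PP2C_binding", "ABA_PYR", "PP2C", "ABA_PYR_PP2C",
         "kf7", "kr7"),
    bind("ABAPYR_PP2CSnRK2_binding", "ABA_PYR", "PP2C_SnRK2",
         "ABA_PYR_PP2C_SnRK2", "kf8", "kr8"),
    cat_("SnRK2_release", "ABA_PYR_PP2C_SnRK2", c("ABA_PYR_PP2C", "SnRK2"),
         "kf18"),
    bind("ABFP_PP2C_binding", "ABF_P", "PP2C", "ABF_P_PP2C", "kf9", "kr9"),
    cat_("ABFP_dephosphorylation", "ABF_P_PP2C", c("ABF", "PP2C"), "kf17"),
    bind("DREB2A_PROT26S_binding", "DREB2A", "PROT26S", "DREB2A_PROT26S",
         "kf16", "kr16"),
    cat_("DREB2A_proteolysis", "DREB2A_PROT26S", "PROT26S", "kcat16")
  )

  # -- promoter occupancy ---------------------------------------------------
  for (g in .FEEDBACK_GENES) {
    rows <- c(rows, list(
      bind(paste0("ABRE_", g, "_binding"), "ABF_P",
           paste0("ABRE_", g, "_free"), paste0("ABRE_", g, "_bound"),
           "kf10", "kr10")))
  }
  rows <- c(rows, list(
    bind("RD29A_ABRE_binding", "ABF_P", "RD29Aprom_free", "RD29Aprom_ABRE",
         "kf12", "kr12"),
    bind("RD29A_DRE_binding", "DREB2A", "RD29Aprom_free", "RD29Aprom_DRE",
         "kf11", "kr11"),
    bind("RD29A_ABRE_on_DRE", "ABF_P", "RD29Aprom_DRE", "RD29Aprom_both",
         "kf14", "kr14"),
    bind("RD29A_DRE_on_ABRE", "DREB2A", "RD29Aprom_ABRE", "RD29Aprom_both",
         "kf13", "kr13")
  ))

  # -- gene expression ------------------------------------------------------
  for (g in .CORE_GENES) {
    gene <- paste0("gene_", g)
    mrna <- paste0("mRNA_", g)
    rows <- c(rows, list(
      rxn(paste0("transcription_", g), "synthesis",
          stats::setNames(1, gene), stats::setNames(c(1, 1), c(gene, mrna)),
          "kf29", gene = g),
      rxn(paste0("translation_", g), "synthesis",
          stats::setNames(1, mrna), stats::setNames(c(1, 1), c(mrna, g)),
          "kf30", gene = g)))
  }
  for (g in .FEEDBACK_GENES) {
    abre <- paste0("ABRE_", g, "_bound")
    mrna <- paste0("fb_mRNA_", g)
    rows <- c(rows, list(
      rxn(paste0("fb_transcription_", g), "synthesis",
          stats::setNames(1, abre), stats::setNames(c(1, 1), c(abre, mrna)),
          "kf26", gene = g),
      rxn(paste0("fb_translation_", g), "synthesis",
          stats::setNames(1, mrna), stats::setNames(c(1, 1), c(mrna, g)),
          "kf28", gene = g)))
  }
  rows <- c(rows, list(
    rxn("transcription_RD29A", "synthesis",
        c(RD29Aprom_both = 1), c(RD29Aprom_both = 1, mRNA_RD29A = 1),
        "kf27", gene = "RD29A")))

  # -- turnover -------------------------------------------------------------
  for (s in names(.PROTEIN_DEG)) {
    rows <- c(rows, list(
      rxn(paste0("degradation_", s), "degradation",
          stats::setNames(1, s), stats::setNames(numeric(0), character(0)),
          .PROTEIN_DEG[[s]])))
  }
  mrna_deg <- c(stats::setNames("kf46", "mRNA_RD29A"),
                stats::setNames(rep("kf47", 3),
                                paste0("fb_mRNA_", .FEEDBACK_GENES)),
                stats::setNames(rep("kf48", 7), paste0("mRNA_", .CORE_GENES)))
  for (s in names(mrna_deg)) {
    rows <- c(rows, list(
      rxn(paste0("degradation_", s), "degradation",
          stats::setNames(1, s), stats::setNames(numeric(0), character(0)),
          mrna_deg[[s]])))
  }
  dplyr::bind_rows(rows)
}

# Flatten reversible reactions into elementary fluxes and index them against
# the species vector. Mass action is at most second order, so each flux is
# k * x[i1] * x[i2] with a sentinel index (n+1, value 1) for first-order terms.
.compile_model <- function(model) {
  sp <- model$species
  n <- nrow(sp)
  idx <- stats::setNames(seq_len(n), sp$name)
  sentinel <- n + 1L

  k <- numeric(0); i1 <- integer(0); i2 <- integer(0)
  stoich_cols <- list()
  add_flux <- function(param, reactants, products, scale) {
    kval <- param_value(model$parameters, param) * scale
    r_idx <- idx[names(reactants)]
    if (anyNA(r_idx)) stop("unknown reactant species", call. = FALSE)
    if (sum(reactants) > 2) stop("mass action is at most second order",
                                 call. = FALSE)
    ii <- rep(r_idx, times = reactants)
    col <- numeric(n)
    col[r_idx] <- col[r_idx] - reactants
    if (length(products) > 0) {
      p_idx <- idx[names(products)]
      if (anyNA(p_idx)) stop("unknown product species", call. = FALSE)
      col[p_idx] <- col[p_idx] + products
    }
    k <<- c(k, kval)
    i1 <<- c(i1, ii[1])
    i2 <<- c(i2, if (length(ii) > 1) ii[2] else sentinel)
    stoich_cols[[length(stoich_cols) + 1L]] <<- col
  }

  for (r in seq_len(nrow(model$reactions))) {
    rx <- model$reactions[r, ]
    add_flux(rx$forward_param, rx$reactants[[1]], rx$products[[1]], rx$scale)
    if (!is.na(rx$reverse_param)) {
      add_flux(rx$reverse_param, rx$products[[1]], rx$reactants[[1]], rx$scale)
    }
  }
  N <- do.call(cbind, stoich_cols)
  clamped <- which(sp$clamped)
  N[clamped, ] <- 0
  list(n = n, k = k, i1 = i1, i2 = i2, N = N, clamped = clamped,
       species = sp$name)
}

#' Build the ABA -> RD29A reaction network
#'
#' Constructs the full mass-action model: ABA receptor binding, PP2C
#' inhibition of SnRK2, MAP3K-mediated SnRK2 phosphorylation, ABF
#' phosphorylation, DREB2A proteolysis by the 26S proteasome (suppressed when
#' ABA sequesters the proteasome), ABRE/DRE occupancy of the four-state RD29A
#' promoter, constitutive expression of the seven pathway proteins, and
#' ABRE-driven feedback expression of PP2C, ABF and DREB2A. Transcription of
#' RD29A requires the doubly occupied promoter.
#'
#' @param parameters Parameter table from [build_parameter_table()].
#' @param cell_volume Cell volume in cubic micrometers (default 50).
#' @param gene_copies Gene copies per locus (default 2, one per homologous
#'   chromosome).
#' @return An object of class `aba_model`: a list with tibbles `species`,
#'   `reactions`, the `parameters` table, and a compiled flux representation
#'   used by the integrator.
#' @examples
#' m <- build_model()
#' nrow(m$species)
#' @export
build_model <- function(parameters = build_parameter_table(),
                        cell_volume = 50, gene_copies = 2) {
  locus_conc <- molecules_to_concentration(gene_copies, cell_volume)
  model <- structure(
    list(species = .species_table(locus_conc),
         reactions = .reaction_table(),
         parameters = parameters,
         cell_volume = cell_volume,
         gene_copies = gene_copies),
    class = "aba_model")
  model$compiled <- .compile_model(model)
  model
}

# Re-derive the compiled fluxes after editing parameters or reaction scales.
.recompile <- function(model) {
  model$compiled <- .compile_model(model)
  model
}

#' Update model parameters
#'
#' @param model An `aba_model`.
#' @param overrides Named numeric vector of parameter values (internal units).
#' @return The model with the new parameter values, recompiled.
#' @export
set_parameters <- function(model, overrides) {
  overrides <- unlist(overrides)
  idx <- match(names(overrides), model$parameters$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(overrides)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  model$parameters$value[idx] <- unname(overrides)
  .recompile(model)
}

#' Initial state of a model
#'
#' @param model An `aba_model`.
#' @return Named numeric vector of initial concentrations (uM).
#' @export
initial_state <- function(model) {
  stats::setNames(model$species$initial_concentration, model$species$name)
}

#' Mass-action right-hand side
#'
#' Time derivative of every species concentration under the law of mass
#' action: each elementary flux is \eqn{k [A] [B]} (second order) or
#' \eqn{k [C]} (first order), and the derivative is the stoichiometry matrix
#' times the flux vector. Clamped species (ABA) have derivative zero.
#'
#' @param model An `aba_model`.
#' @param state Named or unnamed concentration vector matching the species
#'   table order (uM).
#' @param t Time in hours (unused; the system is autonomous).
#' @return Named derivative vector in uM/h.
#' @export
mass_action_rhs <- function(model, state, t = 0) {
  cm <- model$compiled
  if (length(state) != cm$n) {
    stop("state length ", length(state), " does not match ", cm$n,
         " species", call. = FALSE)
  }
  bad <- which(!is.finite(state) | state < -1e-9)
  if (length(bad) > 0) {
    stop("invalid state for species: ",
         paste(cm$species[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(.rhs_raw(cm, as.numeric(state)), cm$species)
}

.rhs_raw <- function(cm, x) {
  xe <- c(x, 1)
  v <- cm$k * xe[cm$i1] * xe[cm$i2]
  as.vector(cm$N %*% v)
}

# Analytic Jacobian of the mass-action system (dense). For flux
# v = k x_a x_b, dv/dx_a = k x_b and dv/dx_b = k x_a.
.jac_raw <- function(cm, x) {
  xe <- c(x, 1)
  nf <- length(cm$k)
  dV <- matrix(0, nf, cm$n)
  f <- seq_len(nf)
  a <- cm$i1; b <- cm$i2
  da <- cm$k * xe[b]
  in_a <- a <= cm$n
  dV[cbind(f[in_a], a[in_a])] <- da[in_a]
  in_b <- b <= cm$n
  db <- cm$k * xe[a]
  # same-species squared terms (a == b) accumulate: 2 k x
  same <- in_b & (a == b)
  dV[cbind(f[in_b], b[in_b])] <- dV[cbind(f[in_b], b[in_b])] + db[in_b] * 1
  if (any(same)) {
    dV[cbind(f[same], a[same])] <- 2 * cm$k[same] * xe[a[same]]
  }
  cm$N %*% dV
}

#' @export
print.aba_model <- function(x, ...) {
  cat("<aba_model> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions, ",
      nrow(x$parameters), " parameters\n", sep = "")
  cat("  cell volume ", x$cell_volume, " um^3, ", x$gene_copies,
      " gene copies per locus\n", sep = "")
  disabled <- x$reactions$id[x$reactions$scale == 0]
  if (length(disabled) > 0) {
    cat("  disabled reactions: ", paste(disabled, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

# Which species carry each protein identity (free form, complexes, and
# DNA-bound states), for conservation accounting.
.PROTEIN_COMPOSITION <- list(
  PYR = c("PYR", "ABA_PYR", "ABA_PYR_PP2C", "ABA_PYR_PP2C_SnRK2"),
  PP2C = c("PP2C", "PP2C_SnRK2", "PP2C_SnRK2_P", "ABA_PYR_PP2C",
           "ABA_PYR_PP2C_SnRK2", "ABF_P_PP2C"),
  SnRK2 = c("SnRK2", "SnRK2_P", "PP2C_SnRK2", "PP2C_SnRK2_P", "SnRK2_MAP3K",
            "SnRK2_P_ABF", "ABA_PYR_PP2C_SnRK2"),
  ABF = c("ABF", "ABF_P", "SnRK2_P_ABF", "ABF_P_PP2C", "ABRE_PP2C_bound",
          "ABRE_ABF_bound", "ABRE_DREB2A_bound", "RD29Aprom_ABRE",
          "RD29Aprom_both"),
  DREB2A = c("DREB2A", "DREB2A_PROT26S", "RD29Aprom_DRE", "RD29Aprom_both"),
  MAP3K = c("MAP3K", "SnRK2_MAP3K"),
  PROT26S = c("PROT26S", "ABA_PROT26S", "DREB2A_PROT26S"))

#' Total abundance of a protein identity
#'
#' Sums a protein over its free form, all complexes containing it, and
#' DNA-bound states, e.g. total PP2C includes PP2C.SnRK2 and the receptor
#' complexes.
#'
#' @param state Named state vector (e.g. from [equilibrate()]).
#' @param protein One of PYR, PP2C, SnRK2, ABF, DREB2A, MAP3K, PROT26S.
#' @return Total concentration in uM.
#' @export
protein_total <- function(state, protein) {
  protein <- match.arg(protein, names(.PROTEIN_COMPOSITION))
  sum(state[.PROTEIN_COMPOSITION[[protein]]])
}
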