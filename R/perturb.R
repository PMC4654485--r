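#' Declare a virtual perturbation
#'
#' A declarative description of an in-silico treatment, applied at the
#' start of a protocol:
#' \describe{
#'   \item{`sirna_silencing`}{introduces an siRNA species that reversibly
#'     sequesters the target mRNA into a translation-incompetent duplex
#'     (default Kd 1e-3 uM, i.e. 1 nM); `dose` is the siRNA concentration.}
#'   \item{`mrna_overexpression`}{adds `dose` (uM) to the target mRNA's
#'     initial concentration.}
#'   \item{`mir_mimic`}{adds `dose` (uM) to the corresponding precursor
#'     miR pool (mimics behave as pre-miRs and still require Dicer).}
#'   \item{`mir_antagonist`}{introduces a species that binds the target
#'     miRISC into a non-functional complex; `dose` is the antagonist
#'     concentration.}
#'   \item{`cocl2`}{adds `dose` (uM) of CoCl2, which sequesters the
#'     hydroxylation-competent PHD2/FIH holoenzymes.}
#'   \item{`parameter_override`}{multiplies the target parameter by
#'     `dose` at treatment time (the protocol run only; steady-state
#'     pre-equilibration is unaffected -- see
#'     [scan_with_reequilibration()] for the re-equilibrated variant).}
#' }
#'
#' @param kind Perturbation kind (see Details).
#' @param target Species id (or parameter id for `parameter_override`).
#' @param dose Dose in uM (multiplier for `parameter_override`);
#'   non-negative.
#' @param kd_uM Dissociation constant for siRNA binding (uM).
#' @param applied_at Application time in minutes (only 0 is supported; all
#'   treatments in the study design are applied at experiment start).
#' @return A `hifmir_perturbation` object.
#' @export
perturbation <- function(kind, target, dose,
                         kd_uM = 1e-3, applied_at = 0) {
  kinds <- c("sirna_silencing", "mrna_overexpression", "mir_mimic",
             "mir_antagonist", "cocl2", "parameter_override")
  kind <- match.arg(kind, kinds)
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("perturbation dose must be a single non-negative number",
         call. = FALSE)
  }
  if (applied_at != 0) {
    stop("all treatments are applied at t = 0 in this protocol layer",
         call. = FALSE)
  }
  structure(list(kind = kind, target = target, dose = dose,
                 kd_uM = kd_uM, applied_at = applied_at),
            class = "hifmir_perturbation")
}

#' @export
print.hifmir_perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s(%s, dose = %g%s)\n", x$kind, x$target,
              x$dose,
              if (x$kind == "sirna_silencing")
                sprintf(", Kd = %g uM", x$kd_uM) else ""))
  invisible(x)
}

## Built-in perturbant machinery of the canonical model: maps a target to
## the dormant perturbant species already wired into the network.
.builtin_perturbants <- list(
  sirna_silencing = list(
    TTP_mRNA  = list(agent = "siRNA_TTP",  kf = "kf_si_ttp",
                     kr = "kr_si_ttp"),
    AGO1_mRNA = list(agent = "siRNA_AGO1", kf = "kf_si_ago1",
                     kr = "kr_si_ago1")),
  mir_antagonist = list(
    let7_AGO1   = list(agent = "anti_let7",   kf = "kf_anti_let7",
                       kr = "kr_anti_let7"),
    miR15a_AGO1 = list(agent = "anti_miR15a", kf = "kf_anti_mir15a",
                       kr = "kr_anti_mir15a")))

#' Apply virtual perturbations to a model
#'
#' Returns a new model with perturbant doses added to the relevant initial
#' concentrations, siRNA dissociation constants honoured, and -- for
#' targets without a pre-wired perturbant pair in the canonical registry --
#' new perturbant species and binding reactions appended.  The input model
#' is left unmodified.  A dose of zero is an exact no-op for the dynamics:
#' perturbant binding fluxes vanish at zero perturbant concentration.
#'
#' @param model A `hifmir_model`.
#' @param perturbations A list of [perturbation()] objects (a single
#'   perturbation is accepted).
#' @return The perturbed `hifmir_model`.  Attribute `bumps` records the
#'   initial-condition increments (named uM vector) and attribute
#'   `param_multipliers` any parameter overrides, so that protocol code can
#'   re-apply doses on top of a pre-equilibrated state.
#' @export
apply_perturbations <- function(model, perturbations) {
  if (inherits(perturbations, "hifmir_perturbation")) {
    perturbations <- list(perturbations)
  }
  bumps <- numeric(0)
  pmult <- numeric(0)
  bump <- function(sp, amount) {
    bumps[sp] <<- (if (sp %in% names(bumps)) bumps[[sp]] else 0) + amount
  }
  for (pt in perturbations) {
    stopifnot(inherits(pt, "hifmir_perturbation"))
    switch(pt$kind,
      mrna_overexpression = {
        role <- model$species$role[match(pt$target, model$species$id)]
        if (is.na(role)) stop("unknown overexpression target '",
                              pt$target, "'", call. = FALSE)
        bump(pt$target, pt$dose)
      },
      mir_mimic = {
        pre <- switch(pt$target,
                      let7 = "pre_let7", pre_let7 = "pre_let7",
                      miR15a = "pre_miR15a", pre_miR15a = "pre_miR15a",
                      stop("unknown miR mimic target '", pt$target, "'",
                           call. = FALSE))
        bump(pre, pt$dose)
      },
      cocl2 = {
        if (!("CoCl2" %in% model$species$id)) {
          stop("model lacks a CoCl2 perturbant species", call. = FALSE)
        }
        bump("CoCl2", pt$dose)
      },
      parameter_override = {
        if (!(pt$target %in% model$parameters$id)) {
          stop("unknown parameter '", pt$target, "'", call. = FALSE)
        }
        pmult[pt$target] <- pt$dose
      },
      sirna_silencing = ,
      mir_antagonist = {
        if (!(pt$target %in% model$species$id)) {
          stop("unknown ", pt$kind, " target '", pt$target, "'",
               call. = FALSE)
        }
        builtin <- .builtin_perturbants[[pt$kind]][[pt$target]]
        if (!is.null(builtin) && builtin$agent %in% model$species$id) {
          bump(builtin$agent, pt$dose)
          if (pt$kind == "sirna_silencing") {
            ## honour the requested Kd by adjusting the off-rate
            kf <- model$parameters$value[
              match(builtin$kf, model$parameters$id)]
            model <- set_params(
              model, stats::setNames(pt$kd_uM * kf, builtin$kr))
          }
        } else {
          model <- .add_perturbant_pair(model, pt)
          bump(paste0("agent_", pt$target), pt$dose)
        }
      })
  }
  model <- set_initial(model, vapply(names(bumps), function(s) {
    model$species$initial[match(s, model$species$id)] + bumps[[s]]
  }, 0))
  if (length(pmult)) {
    vals <- param_values(model)[names(pmult)] * pmult
    model <- set_params(model, vals)
  }
  attr(model, "bumps") <- bumps
  attr(model, "param_multipliers") <- pmult
  model
}

## Append a perturbant species + complex + reversible binding reaction for
## a target without pre-wired machinery (e.g. silencing Dicer mRNA).
.add_perturbant_pair <- function(model, pt) {
  agent <- paste0("agent_", pt$target)
  cplx <- paste0(agent, "_c")
  kf_id <- paste0("kf_", agent)
  kr_id <- paste0("kr_", agent)
  comp <- model$species$compartment[match(pt$target, model$species$id)]
  model$species <- rbind(
    model$species,
    species_def(agent, comp, "perturbant", 0,
                paste("synthetic agent vs", pt$target)),
    species_def(cplx, comp, "complex", 0,
                paste("agent complex with", pt$target)))
  kf <- 10
  kr <- if (pt$kind == "sirna_silencing") pt$kd_uM * kf else 1e-4
  model$parameters <- rbind(
    model$parameters,
    data.frame(id = c(kf_id, kr_id), value = c(kf, kr),
               units = c("1/(uM*min)", "1/min"),
               provenance = "user", stringsAsFactors = FALSE))
  rlaw <- rate_law("mass_action_rev", c(kf = kf_id, kr = kr_id),
                   species = c(agent, pt$target), reverse_species = cplx)
  rx <- reaction(paste0("v_", agent),
                 reactants = stats::setNames(c(1, 1), c(agent, pt$target)),
                 products = stats::setNames(1, cplx),
                 rate = rlaw,
                 description = paste("virtual agent binding of", pt$target),
                 group = "perturbation")
  model$reactions <- c(model$reactions, list(rx))
  model
}
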