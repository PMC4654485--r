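#' hifmir: kinetic modelling of microRNA control of the HIF-VEGF pathway
#'
#' A two-compartment ODE model of hypoxia signalling in endothelial cells:
#' oxygen sensing by PHD2/FIH, HIF-1 stabilisation and nuclear transcription,
#' let-7 biogenesis and AGO1/RISC dynamics, and miR-15a repression of VEGF.
#' The package couples a generic compartmental reaction-network engine with a
#' protocol layer (normoxia/hypoxia switching, virtual gene perturbations),
#' least-squares calibration, local sensitivity analysis and in-silico
#' therapy screens.
#'
#' Units are fixed package-wide: concentrations in micromolar (uM) and time
#' in minutes.  First-order rate constants are min^-1, second-order constants
#' uM^-1 min^-1, Vmax values uM min^-1, and all K constants uM.
#'
#' @keywords internal
#' @aliases hifmir-package
"_PACKAGE"

## Concentrations more negative than this (in uM) are treated as an
## integrator failure rather than round-off.
.NEG_TOL <- 1e-9

#' Define a cellular compartment
#'
#' @param id Short unique identifier (e.g. `"cytoplasm"`).
#' @param label Human-readable name.
#' @return A one-row data frame with columns `id` and `label`.
#' @export
compartment <- function(id, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  data.frame(id = id, label = label, stringsAsFactors = FALSE)
}

#' Define a model species
#'
#' @param id Unique species identifier.
#' @param compartment Compartment id the species lives in.  Nuclear species
#'   carry an `_N` suffix in their labels by convention.
#' @param role One of `"mRNA"`, `"miR_precursor"`, `"miR_mature"`,
#'   `"protein"`, `"complex"`, `"small_molecule"`, `"perturbant"`.
#' @param initial Initial concentration in uM (non-negative).
#' @param label Human-readable name; defaults to `id`.
#' @return A one-row data frame describing the species.
#' @export
species_def <- function(id, compartment, role, initial = 0, label = id) {
  roles <- c("mRNA", "miR_precursor", "miR_mature", "protein", "complex",
             "small_molecule", "perturbant")
  role <- match.arg(role, roles)
  if (!is.numeric(initial) || length(initial) != 1L || is.na(initial) ||
      initial < 0) {
    stop("species '", id, "': initial concentration must be a single ",
         "non-negative number (uM)", call. = FALSE)
  }
  data.frame(id = id, compartment = compartment, role = role,
             initial = initial, label = label, stringsAsFactors = FALSE)
}

#' Construct a rate law
#'
#' Supported kinds:
#' \describe{
#'   \item{`mass_action_1`}{`flux = k * [A]` for the single referenced
#'     species, or `flux = k` (zero-order synthesis) when no species is
#'     referenced.  Translation steps reference the template mRNA as a
#'     modifier so the mRNA is read but not consumed.}
#'   \item{`mass_action_2`}{`flux = k * [A] * [B]`.}
#'   \item{`mass_action_rev`}{net flux `kf * prod(forward species) -
#'     kr * prod(reverse species)`; used for reversible binding and
#'     transport steps, which count as a single reaction.}
#'   \item{`michaelis_menten`}{`flux = Vm * [S] / (Km + [S])`.  With an
#'     `enzyme` species the limiting velocity becomes `kcat * [E]`; with an
#'     `activator` species it becomes `Vm + kact * [A]` (a linear velocity
#'     multiplier, used for the nuclear let-7:AGO1 stimulation of pri-let-7
#'     processing).}
#'   \item{`hill_activation`}{`flux = k0 + Vm * [X]^n / (K^n + [X]^n)`
#'     with basal rate `k0 = 0` unless supplied; `[X]` is the transcriptional
#'     activator.}
#'   \item{`hill_inhibition`}{`flux = Vm * K^n / (K^n + [X]^n)`.}
#' }
#'
#' @param kind Rate-law kind (see Details).
#' @param params Named character vector mapping rate-law roles (`k`, `kf`,
#'   `kr`, `Vm`, `kcat`, `Km`, `n`, `k0`, `kact`) to parameter ids declared
#'   in the model's parameter set.
#' @param species Character vector of species the law reads, in role order
#'   (mass action: the colliding species; MM: substrate; Hill: activator).
#' @param reverse_species For `mass_action_rev`, the species whose product
#'   forms the reverse flux.
#' @param enzyme,activator Optional species ids for the extended MM forms.
#' @return A `hifmir_rate_law` list.
#' @export
rate_law <- function(kind, params, species = character(),
                     reverse_species = character(),
                     enzyme = NULL, activator = NULL) {
  kinds <- c("mass_action_1", "mass_action_2", "mass_action_rev",
             "michaelis_menten", "hill_activation", "hill_inhibition")
  kind <- match.arg(kind, kinds)
  stopifnot(is.character(params), !is.null(names(params)))
  need <- switch(kind,
    mass_action_1 = "k", mass_action_2 = "k",
    mass_action_rev = c("kf", "kr"),
    michaelis_menten = "Km",
    hill_activation = c("Vm", "K", "n"),
    hill_inhibition = c("Vm", "K", "n"))
  if (!all(need %in% names(params))) {
    stop("rate law '", kind, "' requires parameter roles: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (kind == "michaelis_menten" &&
      !any(c("Vm", "kcat") %in% names(params))) {
    stop("michaelis_menten needs either 'Vm' or 'kcat' (with enzyme)",
         call. = FALSE)
  }
  if (kind == "mass_action_2" && length(species) != 2L) {
    stop("mass_action_2 reads exactly two species", call. = FALSE)
  }
  structure(list(kind = kind, params = params, species = species,
                 reverse_species = reverse_species,
                 enzyme = enzyme, activator = activator),
            class = "hifmir_rate_law")
}

#' Construct a reaction
#'
#' @param id Reaction identifier (the canonical model uses `v1` ... `v57`).
#' @param reactants,products Named numeric vectors of stoichiometric
#'   coefficients (positive integers), e.g. `c(A = 1, B = 1)`.  Degradation
#'   reactions have empty products; zero-order synthesis has empty reactants.
#' @param modifiers Species that appear in the rate but are not consumed
#'   (catalysts, templates).
#' @param rate A [rate_law()].
#' @param description Free-text description.
#' @param group Functional sub-network tag: one of `"oxygen_sensing"`,
#'   `"hif_transcription"`, `"let7_arm"`, `"mir15a_vegf_arm"`, `"turnover"`,
#'   `"perturbation"`.
#' @return A `hifmir_reaction` object.
#' @export
reaction <- function(id, reactants = numeric(), products = numeric(),
                     modifiers = character(), rate, description = "",
                     group = "turnover") {
  groups <- c("oxygen_sensing", "hif_transcription", "let7_arm",
              "mir15a_vegf_arm", "turnover", "perturbation")
  group <- match.arg(group, groups)
  stopifnot(inherits(rate, "hifmir_rate_law"))
  as_stoich <- function(x, what) {
    if (length(x) == 0L) {
      return(data.frame(species = character(), coef = numeric(),
                        stringsAsFactors = FALSE))
    }
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("reaction '", id, "': ", what, " must be a named vector",
           call. = FALSE)
    }
    if (any(x <= 0) || any(x != round(x))) {
      stop("reaction '", id, "': stoichiometric coefficients must be ",
           "positive integers", call. = FALSE)
    }
    data.frame(species = names(x), coef = as.numeric(x),
               stringsAsFactors = FALSE)
  }
  structure(list(id = id,
                 reactants = as_stoich(reactants, "reactants"),
                 products = as_stoich(products, "products"),
                 modifiers = modifiers, rate = rate,
                 description = description, group = group),
            class = "hifmir_reaction")
}

#' Assemble a model definition
#'
#' @param compartments Data frame of compartments (rows from
#'   [compartment()]).
#' @param species Data frame of species (rows from [species_def()]).
#' @param reactions List of [reaction()] objects.
#' @param parameters Data frame with columns `id`, `value`, `units`,
#'   `provenance` (`"reference"`, `"fitted"`, `"default_median"`, `"user"`).
#' @param clamped Species held constant during integration (boundary
#'   species); the canonical model clamps `O2`.
#' @param name Model name used in printing and provenance.
#' @return A `hifmir_model` object.
#' @export
hifmir_model <- function(compartments, species, reactions, parameters,
                         clamped = character(), name = "model") {
  stopifnot(is.data.frame(compartments), is.data.frame(species),
            is.list(reactions), is.data.frame(parameters))
  m <- structure(list(name = name, compartments = compartments,
                      species = species, reactions = reactions,
                      parameters = parameters, clamped = clamped),
                 class = "hifmir_model")
  viol <- validate_model(m)
  ref <- viol[viol$severity == "error" & viol$check == "reference", ]
  if (nrow(ref) > 0L) {
    stop("model definition has dangling references:\n  ",
         paste(ref$message, collapse = "\n  "), call. = FALSE)
  }
  m
}

#' Named vector of parameter values
#'
#' @param model A `hifmir_model`.
#' @return Named numeric vector in registry order.
#' @export
param_values <- function(model) {
  stats::setNames(model$parameters$value, model$parameters$id)
}

#' Update parameter values in a model
#'
#' @param model A `hifmir_model`.
#' @param values Named numeric vector of new values; names must be declared
#'   parameter ids.
#' @param provenance Provenance tag recorded for the updated entries.
#' @return The modified model.
#' @export
set_params <- function(model, values, provenance = "user") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  idx <- match(names(values), model$parameters$id)
  if (anyNA(idx)) {
    stop("unknown parameter id(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  model$parameters$value[idx] <- as.numeric(values)
  model$parameters$provenance[idx] <- provenance
  model
}

#' Update initial concentrations
#'
#' @param model A `hifmir_model`.
#' @param values Named numeric vector of initial concentrations (uM).
#' @return The modified model.
#' @export
set_initial <- function(model, values) {
  idx <- match(names(values), model$species$id)
  if (anyNA(idx)) {
    stop("unknown species id(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (any(values < 0)) stop("initial concentrations must be >= 0",
                            call. = FALSE)
  model$species$initial[idx] <- as.numeric(values)
  model
}

#' Initial state vector of a model
#'
#' @param model A `hifmir_model`.
#' @return Named numeric vector of initial concentrations (uM).
#' @export
initial_state <- function(model) {
  stats::setNames(model$species$initial, model$species$id)
}

## Resolve a rate-law parameter role to its numeric value.
.law_par <- function(law, role, pv, default = NA_real_) {
  pid <- law$params[role]
  if (is.na(pid)) return(default)
  v <- pv[[pid]]
  if (is.null(v)) stop("parameter '", pid, "' not in parameter set",
                       call. = FALSE)
  v
}

#' Evaluate the flux of one reaction
#'
#' Computes the instantaneous flux (uM/min) of a single reaction given a
#' state.  Mass-action kinds return `k`, `k*[A]` or `k*[A]*[B]`;
#' Michaelis-Menten returns `Vm*[S]/(Km+[S])` (equal to `Vm/2` at
#' `[S] = Km`); Hill activation returns `Vm*[X]^n/(K^n+[X]^n)` (half-maximal
#' at `[X] = K` for any `n`); Hill inhibition returns
#' `Vm*K^n/(K^n+[X]^n)`.  All fluxes are non-negative except for
#' `mass_action_rev`, whose net flux may take either sign.
#'
#' @param rxn A [reaction()].
#' @param state Named numeric vector of concentrations (uM).
#' @param params Named numeric vector of parameter values, or a
#'   `hifmir_model` whose parameters are used.
#' @return Flux in uM/min.
#' @export
reaction_rate <- function(rxn, state, params) {
  stopifnot(inherits(rxn, "hifmir_reaction"))
  if (inherits(params, "hifmir_model")) params <- param_values(params)
  pv <- as.list(params)
  law <- rxn$rate
  conc <- function(ids) {
    if (length(ids) == 0L) return(1)
    miss <- setdiff(ids, names(state))
    if (length(miss) > 0L) {
      stop("reaction '", rxn$id, "': species not in state: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    x <- state[ids]
    if (any(Re(x) < -.NEG_TOL)) {
      stop("reaction '", rxn$id, "': negative concentration beyond ",
           "tolerance in state", call. = FALSE)
    }
    prod(x)
  }
  switch(law$kind,
    mass_action_1 = .law_par(law, "k", pv) * conc(law$species),
    mass_action_2 = .law_par(law, "k", pv) * conc(law$species),
    mass_action_rev =
      .law_par(law, "kf", pv) * conc(law$species) -
      .law_par(law, "kr", pv) * conc(law$reverse_species),
    michaelis_menten = {
      s <- conc(law$species[1])
      vmax <- if (!is.null(law$enzyme)) {
        .law_par(law, "kcat", pv) * conc(law$enzyme)
      } else {
        .law_par(law, "Vm", pv)
      }
      if (!is.null(law$activator)) {
        vmax <- vmax + .law_par(law, "kact", pv) * conc(law$activator)
      }
      n <- .law_par(law, "n", pv, default = 1)
      Km <- .law_par(law, "Km", pv)
      vmax * s^n / (Km^n + s^n)
    },
    hill_activation = {
      x <- conc(law$species[1])
      n <- .law_par(law, "n", pv)
      K <- .law_par(law, "K", pv)
      .law_par(law, "k0", pv, default = 0) +
        .law_par(law, "Vm", pv) * x^n / (K^n + x^n)
    },
    hill_inhibition = {
      x <- conc(law$species[1])
      n <- .law_par(law, "n", pv)
      K <- .law_par(law, "K", pv)
      .law_par(law, "Vm", pv) * K^n / (K^n + x^n)
    })
}

#' Stoichiometry matrix
#'
#' @param model A `hifmir_model`.
#' @return Numeric matrix (species x reactions) of net stoichiometric
#'   coefficients; modifiers contribute nothing.
#' @export
stoichiometry_matrix <- function(model) {
  sp <- model$species$id
  S <- matrix(0, nrow = length(sp), ncol = length(model$reactions),
              dimnames = list(sp, vapply(model$reactions, `[[`, "", "id")))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (i in seq_len(nrow(r$reactants))) {
      S[r$reactants$species[i], j] <- S[r$reactants$species[i], j] -
        r$reactants$coef[i]
    }
    for (i in seq_len(nrow(r$products))) {
      S[r$products$species[i], j] <- S[r$products$species[i], j] +
        r$products$coef[i]
    }
  }
  S
}

## Compile the model into fast index tables used by the RHS closure.
## Species indices point into c(y, 1): index n_sp + 1 is the constant 1,
## so absent factors multiply by one without branching.
.compile_model <- function(model) {
  sp <- model$species$id
  np <- model$parameters$id
  n <- length(sp)
  unit <- n + 1L
  sidx <- function(id) {
    if (is.null(id) || length(id) == 0L) return(unit)
    i <- match(id, sp)
    if (anyNA(i)) stop("unknown species: ", paste(id[is.na(i)],
                       collapse = ", "), call. = FALSE)
    i
  }
  pidx <- function(law, role) {
    pid <- law$params[role]
    if (is.na(pid)) return(NA_integer_)
    i <- match(pid, np)
    if (is.na(i)) stop("unknown parameter: ", pid, call. = FALSE)
    i
  }
  pad2 <- function(i) c(i, rep(unit, 2L - length(i)))[1:2]
  nr <- length(model$reactions)
  tab <- list(kind = character(nr),
              k = integer(nr), kf = integer(nr), kr = integer(nr),
              f1 = integer(nr), f2 = integer(nr),
              r1 = integer(nr), r2 = integer(nr),
              Vm = integer(nr), kcat = integer(nr), Km = integer(nr),
              nH = integer(nr), k0 = integer(nr), kact = integer(nr),
              sub = integer(nr), enz = integer(nr), act = integer(nr),
              X = integer(nr))
  for (j in seq_len(nr)) {
    law <- model$reactions[[j]]$rate
    tab$kind[j] <- law$kind
    switch(law$kind,
      mass_action_1 = , mass_action_2 = {
        tab$k[j] <- pidx(law, "k")
        fs <- pad2(sidx(law$species))
        tab$f1[j] <- fs[1]; tab$f2[j] <- fs[2]
      },
      mass_action_rev = {
        tab$kf[j] <- pidx(law, "kf"); tab$kr[j] <- pidx(law, "kr")
        fs <- pad2(sidx(law$species))
        rs <- pad2(sidx(law$reverse_species))
        tab$f1[j] <- fs[1]; tab$f2[j] <- fs[2]
        tab$r1[j] <- rs[1]; tab$r2[j] <- rs[2]
      },
      michaelis_menten = {
        tab$Vm[j] <- pidx(law, "Vm"); tab$kcat[j] <- pidx(law, "kcat")
        tab$Km[j] <- pidx(law, "Km"); tab$kact[j] <- pidx(law, "kact")
        tab$nH[j] <- pidx(law, "n")
        tab$sub[j] <- sidx(law$species[1])
        tab$enz[j] <- if (is.null(law$enzyme)) 0L else sidx(law$enzyme)
        tab$act[j] <- if (is.null(law$activator)) 0L else
          sidx(law$activator)
      },
      hill_activation = , hill_inhibition = {
        tab$Vm[j] <- pidx(law, "Vm"); tab$Km[j] <- pidx(law, "K")
        tab$nH[j] <- pidx(law, "n"); tab$k0[j] <- pidx(law, "k0")
        tab$X[j] <- sidx(law$species[1])
      })
  }
  list(S = stoichiometry_matrix(model), tab = tab, n = n, unit = unit,
       clamped = match(model$clamped, sp),
       ma = which(tab$kind %in% c("mass_action_1", "mass_action_2")),
       rev = which(tab$kind == "mass_action_rev"),
       mm = which(tab$kind == "michaelis_menten"),
       ha = which(tab$kind == "hill_activation"),
       hi = which(tab$kind == "hill_inhibition"))
}

#' Build the ODE right-hand side of a model
#'
#' Returns a derivative function in the form deSolve expects:
#' `function(t, y, parms)` returning `list(dy)`, where `parms` is the named
#' parameter vector (defaults to the model's registry values).  The
#' derivative of each species is the stoichiometry-weighted sum of reaction
#' fluxes; modifiers enter rates but not stoichiometry; clamped species
#' (e.g. `O2`) have zero derivative.  The closure evaluates correctly for
#' complex-valued states and parameters, which the complex-step sensitivity
#' path relies on.
#'
#' @param model A `hifmir_model`.
#' @return A function `(t, y, parms)` -> `list(dy)` with an attribute
#'   `flux` function `(y, parms)` returning the per-reaction flux vector.
#' @export
assemble_rhs <- function(model) {
  cm <- .compile_model(model)
  tab <- cm$tab
  S <- cm$S
  ma <- cm$ma; rv <- cm$rev; mm <- cm$mm; ha <- cm$ha; hi <- cm$hi
  nr <- length(tab$kind)
  flux_fn <- function(y, p) {
    yx <- c(y, 1)
    v <- vector(mode = if (is.complex(yx) || is.complex(p)) "complex"
                else "numeric", length = nr)
    if (length(ma)) {
      v[ma] <- p[tab$k[ma]] * yx[tab$f1[ma]] * yx[tab$f2[ma]]
    }
    if (length(rv)) {
      v[rv] <- p[tab$kf[rv]] * yx[tab$f1[rv]] * yx[tab$f2[rv]] -
        p[tab$kr[rv]] * yx[tab$r1[rv]] * yx[tab$r2[rv]]
    }
    for (j in mm) {
      s <- yx[tab$sub[j]]
      vmax <- if (tab$enz[j] > 0L) p[tab$kcat[j]] * yx[tab$enz[j]]
              else p[tab$Vm[j]]
      if (tab$act[j] > 0L) vmax <- vmax + p[tab$kact[j]] * yx[tab$act[j]]
      Km <- p[tab$Km[j]]
      if (!is.na(tab$nH[j])) {
        n <- p[tab$nH[j]]
        v[j] <- vmax * s^n / (Km^n + s^n)
      } else {
        v[j] <- vmax * s / (Km + s)
      }
    }
    for (j in ha) {
      x <- yx[tab$X[j]]
      n <- p[tab$nH[j]]; K <- p[tab$Km[j]]
      b <- if (!is.na(tab$k0[j]) && tab$k0[j] > 0L) p[tab$k0[j]] else 0
      v[j] <- b + p[tab$Vm[j]] * x^n / (K^n + x^n)
    }
    for (j in hi) {
      x <- yx[tab$X[j]]
      n <- p[tab$nH[j]]; K <- p[tab$Km[j]]
      v[j] <- p[tab$Vm[j]] * K^n / (K^n + x^n)
    }
    v
  }
  default_p <- param_values(model)
  f <- function(t, y, parms = default_p) {
    dy <- as.vector(S %*% flux_fn(y, parms))
    if (length(cm$clamped)) dy[cm$clamped] <- 0
    list(dy)
  }
  attr(f, "flux") <- flux_fn
  attr(f, "species") <- model$species$id
  f
}

## NA-safe integer index guard used by flux_fn for optional k0.
## (k0 indices are stored as NA_integer_ when the law has no basal term.)

#' Validate a model definition
#'
#' Checks the structural invariants of a model -- unique identifiers,
#' resolvable species/parameter references, positive rate constants, Hill
#' coefficients at least 1, non-negative initial concentrations -- and
#' reports the species/reaction/parameter counts.  Violations are reported,
#' never raised.
#'
#' @param model A `hifmir_model` (or an unclassed list with the same
#'   fields).
#' @return A data frame of violations (zero rows when the model is valid)
#'   with attribute `counts`, a named vector
#'   `c(species=, reactions=, parameters=)`.
#' @export
validate_model <- function(model) {
  v <- list()
  add <- function(check, message, severity = "error") {
    v[[length(v) + 1L]] <<- data.frame(check = check, message = message,
                                       severity = severity,
                                       stringsAsFactors = FALSE)
  }
  sp <- model$species; pars <- model$parameters
  if (anyDuplicated(model$compartments$id)) {
    add("unique", "duplicate compartment ids")
  }
  if (anyDuplicated(sp$id)) add("unique", "duplicate species ids")
  if (anyDuplicated(pars$id)) add("unique", "duplicate parameter ids")
  bad <- sp$id[!(sp$compartment %in% model$compartments$id)]
  for (b in bad) add("reference", paste0("species '", b,
                     "' in undeclared compartment"))
  if (any(sp$initial < 0)) {
    add("positivity", "negative initial concentration(s)")
  }
  if (any(!is.finite(pars$value) | pars$value <= 0)) {
    for (b in pars$id[!is.finite(pars$value) | pars$value <= 0]) {
      add("positivity", paste0("parameter '", b, "' is not positive"))
    }
  }
  rids <- vapply(model$reactions, function(r) r$id, "")
  if (anyDuplicated(rids)) add("unique", "duplicate reaction ids")
  for (r in model$reactions) {
    refs <- unique(c(r$reactants$species, r$products$species, r$modifiers,
                     r$rate$species, r$rate$reverse_species,
                     r$rate$enzyme, r$rate$activator))
    miss <- setdiff(refs, sp$id)
    for (m in miss) add("reference", paste0("reaction '", r$id,
                        "' references undeclared species '", m, "'"))
    pmiss <- setdiff(unname(r$rate$params), pars$id)
    for (m in pmiss) add("reference", paste0("reaction '", r$id,
                         "' references undeclared parameter '", m, "'"))
    if ("n" %in% names(r$rate$params)) {
      pid <- r$rate$params[["n"]]
      val <- pars$value[match(pid, pars$id)]
      if (!is.na(val) && val < 1) {
        add("hill", paste0("reaction '", r$id, "': Hill coefficient '",
                           pid, "' < 1"))
      }
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(check = character(), message = character(),
               severity = character(), stringsAsFactors = FALSE)
  attr(out, "counts") <- c(species = nrow(sp),
                           reactions = length(model$reactions),
                           parameters = nrow(pars))
  out
}

#' @export
print.hifmir_model <- function(x, ...) {
  cnt <- attr(validate_model(x), "counts")
  cat("<hifmir_model> ", x$name, "\n", sep = "")
  cat("  compartments: ", paste(x$compartments$id, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  species: %d | reactions: %d | parameters: %d\n",
              cnt["species"], cnt["reactions"], cnt["parameters"]))
  if (length(x$clamped)) {
    cat("  clamped: ", paste(x$clamped, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.hifmir_model <- function(object, ...) {
  viol <- validate_model(object)
  groups <- table(vapply(object$reactions, function(r) r$group, ""))
  kinds <- table(vapply(object$reactions, function(r) r$rate$kind, ""))
  out <- list(name = object$name, counts = attr(viol, "counts"),
              violations = viol, reaction_groups = groups,
              rate_law_kinds = kinds,
              provenance = table(object$parameters$provenance))
  class(out) <- "summary.hifmir_model"
  out
}

#' @export
print.summary.hifmir_model <- function(x, ...) {
  cat("Model:", x$name, "\n")
  print(x$counts)
  cat("\nReaction groups:\n"); print(x$reaction_groups)
  cat("\nRate-law kinds:\n"); print(x$rate_law_kinds)
  cat("\nParameter provenance:\n"); print(x$provenance)
  if (nrow(x$violations)) {
    cat("\nViolations:\n"); print(x$violations)
  } else cat("\nNo violations.\n")
  invisible(x)
}
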