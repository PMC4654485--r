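## Protocol layer: steady-state pre-equilibration, hypoxia switching and
## stiff time-course integration (deSolve::lsoda).

## Steady states are memoised per (parameters, initials, O2) so repeated
## protocol runs and screens do not re-equilibrate needlessly.
.ss_cache <- new.env(parent = emptyenv())

.ss_key <- function(model, o2_uM) {
  paste(c(sprintf("%.17g", param_values(model)),
          sprintf("%.17g", initial_state(model)),
          sprintf("%.17g", o2_uM), model$clamped), collapse = "|")
}

#' Define a simulation protocol
#'
#' @param o2_percent Ambient O2 percentage in `[0, 21]` applied from t = 0.
#' @param duration_min Simulated span in minutes (> 0).
#' @param perturbations List of [perturbation()]s applied at t = 0.
#' @param output_every_min Output grid spacing in minutes (the solver
#'   output is stored at least this densely; readout integrals use it).
#' @param rtol,atol Relative/absolute solver tolerances (atol in uM).
#' @return A `hifmir_protocol` list.
#' @export
protocol <- function(o2_percent, duration_min,
                     perturbations = list(),
                     output_every_min = 1,
                     rtol = 1e-8, atol = 1e-12) {
  if (duration_min <= 0) stop("protocol duration must be > 0",
                              call. = FALSE)
  if (inherits(perturbations, "hifmir_perturbation")) {
    perturbations <- list(perturbations)
  }
  structure(list(o2_percent = o2_percent, duration_min = duration_min,
                 perturbations = perturbations,
                 output_every_min = output_every_min,
                 rtol = rtol, atol = atol),
            class = "hifmir_protocol")
}

.check_negative <- function(y, where) {
  bad <- min(Re(y))
  if (bad < -.NEG_TOL) {
    stop(sprintf(
      "integrator produced concentration %.3g uM below tolerance (%s)",
      bad, where), call. = FALSE)
  }
}

#' Find the normoxic steady state of a model
#'
#' Integrates the model with O2 clamped at the requested tension (default
#' 21%, i.e. 209 uM) until every species satisfies
#' `|d[X]/dt| / max([X], floor) < tol`.  This is the pre-equilibration
#' step every protocol starts from: hypoxia simulations begin at the
#' normoxic steady state.
#'
#' @param model A `hifmir_model`.
#' @param o2_percent Ambient O2 percentage used for equilibration.
#' @param tol Convergence tolerance on the relative residual (min^-1).
#' @param floor Concentration floor (uM) in the residual denominator.
#' @param max_time Time cap (minutes) after which non-convergence is an
#'   error.
#' @param rtol,atol Solver tolerances.
#' @return Named state vector (uM) with attributes `residual` (achieved
#'   relative residual) and `o2_percent`.
#' @export
find_normoxic_steady_state <- function(model, o2_percent = 21,
                                       tol = 1e-8, floor = 1e-9,
                                       max_time = 4e8,
                                       rtol = 1e-8, atol = 1e-13) {
  o2 <- o2_percent_to_concentration(o2_percent)
  key <- .ss_key(model, o2)
  hit <- .ss_cache[[key]]
  if (!is.null(hit)) return(hit)
  rhs <- assemble_rhs(model)
  p <- param_values(model)
  y <- initial_state(model)
  if ("O2" %in% names(y)) y[["O2"]] <- o2
  t_chunk <- 2e5
  t_done <- 0
  residual <- function(y) {
    dy <- rhs(0, y, p)[[1]]
    max(abs(dy) / pmax(abs(y), floor))
  }
  ## Newton polish on the integrated end state; the pseudo-inverse keeps
  ## the step well-defined despite conserved-pool null directions.
  polish <- function(y) {
    for (it in 1:8) {
      f0 <- rhs(0, y, p)[[1]]
      n <- length(y)
      J <- matrix(0, n, n)
      hshift <- pmax(abs(y), 1e-9) * 1e-7
      for (j in seq_len(n)) {
        yj <- y
        yj[j] <- yj[j] + hshift[j]
        J[, j] <- (rhs(0, yj, p)[[1]] - f0) / hshift[j]
      }
      step <- tryCatch(as.numeric(MASS::ginv(J) %*% f0),
                       error = function(e) NULL)
      if (is.null(step)) break
      cand <- pmax(y - step, 0)
      if (residual(cand) < residual(y)) y <- cand else break
    }
    y
  }
  repeat {
    ## a chunk that runs out of steps simply ends early; the residual
    ## check below is the convergence authority, so the solver's
    ## "returning early" warnings carry no information here
    sol <- suppressWarnings(
      deSolve::lsoda(y, times = c(0, t_chunk), func = rhs, parms = p,
                     rtol = rtol, atol = atol, maxsteps = 5e5))
    y <- sol[nrow(sol), -1]
    .check_negative(y, "steady-state search")
    y <- pmax(y, 0)
    t_done <- t_done + t_chunk
    res <- residual(y)
    if (res >= tol && res < 1e5 * tol) {
      y <- polish(y)
      res <- residual(y)
    }
    if (res < tol) break
    if (t_done >= max_time) {
      stop(sprintf(
        "no steady state within %g min (relative residual %.3g > %.3g)",
        max_time, res, tol), call. = FALSE)
    }
    t_chunk <- min(t_chunk * 4, max_time - t_done)
  }
  out <- stats::setNames(as.numeric(y), model$species$id)
  attr(out, "residual") <- residual(y)
  attr(out, "o2_percent") <- o2_percent
  .ss_cache[[key]] <- out
  out
}

#' Run a simulation protocol
#'
#' Pre-equilibrates the untreated model at normoxia (21% O2), applies the
#' protocol's perturbations at t = 0 (dose bumps on top of the steady
#' state, plus any perturbant machinery), switches O2 to the protocol
#' tension, and integrates the stiff ODE system over the requested span.
#' Deterministic given (model, protocol, tolerances).
#'
#' @param model A `hifmir_model`.
#' @param prot A [protocol()].
#' @param init Optional named initial state (uM) overriding the normoxic
#'   steady state (perturbation bumps still apply on top).
#' @return A `hifmir_timecourse`: list with `time` (minutes), `conc`
#'   (time x species matrix, uM), `model` (the perturbed model), `protocol`
#'   and `baseline` (the pre-equilibrated state).
#' @export
run_protocol <- function(model, prot, init = NULL) {
  stopifnot(inherits(prot, "hifmir_protocol"))
  base <- if (is.null(init)) find_normoxic_steady_state(model) else init
  pm <- apply_perturbations(model, prot$perturbations)
  bumps <- attr(pm, "bumps")
  y0 <- stats::setNames(numeric(nrow(pm$species)), pm$species$id)
  shared <- intersect(names(y0), names(base))
  y0[shared] <- base[shared]
  if (length(bumps)) y0[names(bumps)] <- y0[names(bumps)] + bumps
  if ("O2" %in% names(y0)) {
    y0[["O2"]] <- o2_percent_to_concentration(prot$o2_percent)
  }
  times <- unique(sort(c(
    seq(0, prot$duration_min, by = min(prot$output_every_min,
                                       prot$duration_min)),
    prot$duration_min)))
  rhs <- assemble_rhs(pm)
  p <- param_values(pm)
  sol <- deSolve::lsoda(y0, times = times, func = rhs, parms = p,
                        rtol = prot$rtol, atol = prot$atol,
                        maxsteps = 5e5)
  if (attr(sol, "istate")[1] < 0) {
    stop("stiff integration failed: ",
         paste(attr(sol, "istate"), collapse = " "), call. = FALSE)
  }
  conc <- sol[, -1, drop = FALSE]
  .check_negative(conc, "protocol run")
  structure(list(time = sol[, 1], conc = conc, model = pm,
                 protocol = prot, baseline = y0),
            class = "hifmir_timecourse")
}

#' @export
print.hifmir_timecourse <- function(x, ...) {
  cat(sprintf(
    "<hifmir_timecourse> %d species, %d time points, %.4g-%.4g min, %s%% O2\n",
    ncol(x$conc), length(x$time), min(x$time), max(x$time),
    format(x$protocol$o2_percent)))
  if (length(x$protocol$perturbations)) {
    cat("  perturbations:",
        paste(vapply(x$protocol$perturbations, function(p)
          sprintf("%s(%s, %g)", p$kind, p$target, p$dose), ""),
          collapse = "; "), "\n")
  }
  invisible(x)
}

#' Extract species traces from a time course
#'
#' @param tc A `hifmir_timecourse`.
#' @param species Character vector of species ids.
#' @return Matrix (time x species), negative round-off clipped to zero.
#' @export
species_trace <- function(tc, species) {
  miss <- setdiff(species, colnames(tc$conc))
  if (length(miss)) stop("species not in time course: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pmax(tc$conc[, species, drop = FALSE], 0)
}

#' Plot a time course
#'
#' @param x A `hifmir_timecourse`.
#' @param species Species ids to draw (default: the six pathway signature
#'   readouts).
#' @param log Plot on a log10 concentration axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hifmir_timecourse <- function(x, species = NULL, log = FALSE, ...) {
  if (is.null(species)) {
    species <- intersect(c("HIF1A", "HIF1", "TTP", "let7_AGO1", "AGO1",
                           "VEGF"), colnames(x$conc))
  }
  y <- species_trace(x, species)
  graphics::matplot(x$time / 60, y, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "concentration (uM)",
                    log = if (log) "y" else "", ...)
  graphics::legend("topright", legend = species, lty = 1,
                   col = seq_along(species), cex = 0.8, bty = "n")
  invisible(x)
}
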