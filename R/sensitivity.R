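## Local sensitivity analysis: time-dependent derivatives of a species
## with respect to a parameter (complex-step through a complex-valued
## stiff integration, or central differences), the non-dimensionalised /
## time-integrated / sum-normalised share pipeline, and the
## re-equilibration multiplier-scan workflow.

#' Time-dependent local sensitivity of a species to a parameter
#'
#' `complex_step` integrates the system with the parameter perturbed to
#' `p * (1 + i*h)` using a complex-valued stiff solver (deSolve::zvode)
#' and returns `Im([A](t)) / (p*h)`; no subtractive cancellation occurs,
#' so `h` can be small.  `central_difference` uses
#' `([A](t; p(1+h)) - [A](t; p(1-h))) / (2*p*h)` with a relative step of
#' 1e-4.  If the complex path fails, the function falls back to central
#' differences and records it (`attr(x, "method")`), never silently.
#'
#' The simulation starts from the model's normoxic steady state (the
#' parameter change applies to the protocol run, not the
#' pre-equilibration; see [scan_with_reequilibration()] for the
#' re-equilibrated analysis).
#'
#' @param model A `hifmir_model`.
#' @param prot A [protocol()].
#' @param species Species id whose trajectory is differentiated.
#' @param parameter Parameter id.
#' @param method `"complex_step"` or `"central_difference"`.
#' @param h Relative step (default 1e-7 for complex step, 1e-4 for
#'   central differences).
#' @param init Optional named initial state (uM); defaults to the
#'   normoxic steady state.
#' @return Numeric vector `d[species](t)/dp` on the protocol output grid,
#'   with attributes `time` and `method` (the method actually used).
#' @export
local_sensitivity <- function(model, prot, species, parameter,
                              method = c("complex_step",
                                         "central_difference"),
                              h = NULL, init = NULL) {
  method <- match.arg(method)
  if (!(parameter %in% model$parameters$id)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  y0 <- if (is.null(init)) find_normoxic_steady_state(model) else init
  if ("O2" %in% names(y0)) {
    y0[["O2"]] <- o2_percent_to_concentration(prot$o2_percent)
  }
  times <- unique(sort(c(seq(0, prot$duration_min,
                             by = prot$output_every_min),
                         prot$duration_min)))
  p <- param_values(model)
  rhs <- assemble_rhs(model)
  idx <- match(species, model$species$id)
  if (is.na(idx)) stop("unknown species '", species, "'", call. = FALSE)

  if (method == "complex_step") {
    hh <- if (is.null(h)) 1e-7 else h
    sens <- tryCatch({
      pc <- p * (1 + 0i)
      pc[parameter] <- p[[parameter]] * complex(real = 1, imaginary = hh)
      sol <- deSolve::zvode(as.complex(y0), times = times, func = rhs,
                            parms = pc, rtol = prot$rtol,
                            atol = prot$atol * 1e-4, maxsteps = 5e5)
      if (attr(sol, "istate")[1] < 0) stop("zvode failed")
      Im(sol[, idx + 1]) / (p[[parameter]] * hh)
    }, error = function(e) NULL)
    if (!is.null(sens)) {
      attr(sens, "time") <- times
      attr(sens, "method") <- "complex_step"
      return(sens)
    }
    warning("complex-step path unavailable; falling back to central ",
            "differences", call. = FALSE)
    method <- "central_difference"
  }
  hh <- if (is.null(h) || method == "central_difference") 1e-4 else h
  run <- function(fac) {
    pp <- p
    pp[parameter] <- p[[parameter]] * fac
    sol <- deSolve::lsoda(y0, times = times, func = rhs, parms = pp,
                          rtol = prot$rtol, atol = prot$atol,
                          maxsteps = 5e5)
    sol[, idx + 1]
  }
  sens <- (run(1 + hh) - run(1 - hh)) / (2 * p[[parameter]] * hh)
  attr(sens, "time") <- times
  attr(sens, "method") <- "central_difference"
  sens
}

## Parameters of the reactions that directly produce or degrade a species
## (the species is a reactant or product, rather than acting upstream).
.direct_params <- function(model, species) {
  out <- character()
  for (r in model$reactions) {
    prod_ids <- r$products$species
    reac_ids <- r$reactants$species
    if (species %in% c(prod_ids, reac_ids)) {
      out <- c(out, unname(r$rate$params))
    }
  }
  unique(out)
}

#' Normalised sensitivity shares of a readout species
#'
#' The share pipeline: each raw sensitivity is non-dimensionalised
#' as `(p/[A](t)) * d[A](t)/dp` (relative sensitivity), its absolute value
#' integrated over the simulation span, and the integrals normalised to
#' sum to one, yielding the pie-chart shares.  A floor of 1e-12 uM guards
#' the `[A](t)` denominator.  Direct production/degradation parameters of
#' the readout species can be excluded (`exclude_direct`), as their
#' dominance is uninformative.
#'
#' @param model A `hifmir_model`.
#' @param prot A [protocol()] (the default analysis uses 48 h at 2% O2).
#' @param species Readout species id.
#' @param parameters Parameter ids to rank (non-empty).
#' @param method Passed to [local_sensitivity()].
#' @param exclude_direct Drop direct production/degradation parameters of
#'   `species` before computing shares.
#' @return A `hifmir_sensitivity` data frame (`parameter`, `integral`,
#'   `share`, `rank`) with attributes `method` and `span_min`.
#' @export
sensitivity_shares <- function(model,
                               prot = protocol(2, 2880,
                                               output_every_min = 30),
                               species, parameters,
                               method = "complex_step",
                               exclude_direct = FALSE) {
  if (length(parameters) == 0L) stop("no parameters given", call. = FALSE)
  if (exclude_direct) {
    drop <- .direct_params(model, species)
    parameters <- setdiff(parameters, drop)
    if (length(parameters) == 0L) {
      stop("all requested parameters are direct production/degradation ",
           "rates of '", species, "'", call. = FALSE)
    }
  }
  tc <- run_protocol(model, protocol(prot$o2_percent, prot$duration_min,
                                     output_every_min =
                                       prot$output_every_min,
                                     rtol = prot$rtol, atol = prot$atol))
  a <- stats::approx(tc$time, species_trace(tc, species)[, 1],
                     xout = seq(0, prot$duration_min,
                                by = prot$output_every_min))$y
  if (all(a <= 1e-12)) {
    stop("readout species '", species, "' is identically ~0 on the span",
         call. = FALSE)
  }
  p <- param_values(model)
  uniq <- unique(parameters)
  used_method <- character(length(uniq))
  uintegrals <- vapply(seq_along(uniq), function(j) {
    pid <- uniq[j]
    s <- local_sensitivity(model, prot, species, pid, method = method)
    used_method[j] <<- attr(s, "method")
    tt <- attr(s, "time")
    rel <- abs(p[[pid]] * s / pmax(a[seq_along(s)], 1e-12))
    sum(diff(tt) * (rel[-1] + rel[-length(rel)]) / 2)
  }, 0)
  ## shares are computed over unique parameters; copies of a duplicated
  ## id split that parameter's combined share evenly
  tot <- sum(uintegrals)
  ushare <- if (tot <= 0) rep(1 / length(uintegrals), length(uintegrals))
            else uintegrals / tot
  ncopy <- table(parameters)[uniq]
  ui <- match(parameters, uniq)
  integrals <- uintegrals[ui]
  share <- (ushare / as.numeric(ncopy))[ui]
  out <- data.frame(parameter = parameters, integral = integrals,
                    share = share, rank = rank(-share,
                                               ties.method = "min"),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- unique(used_method)
  attr(out, "span_min") <- prot$duration_min
  class(out) <- c("hifmir_sensitivity", "data.frame")
  out
}

#' @export
print.hifmir_sensitivity <- function(x, ...) {
  cat("<hifmir_sensitivity> method:",
      paste(attr(x, "method"), collapse = "+"),
      "| span:", attr(x, "span_min"), "min\n")
  print.data.frame(x[order(x$rank), ], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Parameter scan with normoxic re-equilibration
#'
#' For each multiplier `m`: scale the parameter to `m * p0`, find the new
#' normoxic steady state, take it as the t = 0 state, run the hypoxia
#' protocol, and record relative-expression traces of the declared
#' readouts (normalised to the new t = 0).  Multiplier 1 reproduces the
#' baseline.  Steady-state failures are recorded per multiplier and the
#' scan continues.
#'
#' @param model A `hifmir_model`.
#' @param parameter Parameter id to scan.
#' @param multipliers Positive multipliers (e.g. `c(0.1, 0.5, 2, 5)`).
#' @param prot Hypoxia [protocol()].
#' @param readouts Character vector of canonical readout names or list of
#'   [readout_definition()]s.
#' @return A `hifmir_scan`: list with `parameter`, `multipliers`, `time`,
#'   `traces` (list: per multiplier, a matrix time x readouts), `states`
#'   (re-equilibrated initial states), `errors`.
#' @export
scan_with_reequilibration <- function(model, parameter, multipliers,
                                      prot = protocol(
                                        2, 2880, output_every_min = 10),
                                      readouts = c("total_hif1a",
                                                   "total_ago1")) {
  stopifnot(all(multipliers > 0))
  if (!(parameter %in% model$parameters$id)) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  p0 <- param_values(model)[[parameter]]
  ros <- lapply(readouts, function(r)
    if (is.character(r)) canonical_readout(r) else r)
  traces <- list(); states <- list(); errors <- list()
  tgrid <- NULL
  for (m in multipliers) {
    key <- format(m)
    res <- tryCatch({
      mm <- set_params(model, stats::setNames(m * p0, parameter))
      ss <- find_normoxic_steady_state(mm)
      tc <- run_protocol(mm, prot, init = ss)
      tr <- vapply(ros, function(ro) relative_expression(tc, ro),
                   numeric(length(tc$time)))
      colnames(tr) <- vapply(ros, function(ro) ro$name, "")
      list(tc = tc, tr = tr, ss = ss)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      tgrid <- res$tc$time
      traces[[key]] <- res$tr
      states[[key]] <- res$ss
    }
  }
  structure(list(parameter = parameter, multipliers = multipliers,
                 time = tgrid, traces = traces, states = states,
                 errors = errors),
            class = "hifmir_scan")
}

#' @export
print.hifmir_scan <- function(x, ...) {
  cat(sprintf("<hifmir_scan> %s x {%s}\n", x$parameter,
              paste(x$multipliers, collapse = ", ")))
  if (length(x$errors)) {
    cat("  errors at multipliers:",
        paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
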