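## In-silico therapy screens: tumour (VEGF suppression) and peripheral
## arterial disease (VEGF enhancement), quantified as total VEGF produced
## over 24 h relative to same-O2 untreated controls.

#' Canonical therapy strategies
#'
#' Tumour (anti-angiogenic) strategies: direct let-7 antagonism, AGO1 mRNA
#' overexpression, AGO1 + Dicer mRNA overexpression, miR-15a mimics, and
#' TTP mRNA overexpression.  PAD (pro-angiogenic) strategies: let-7
#' mimics, miR-15a antagonism, and their combination.
#'
#' @param set `"tumor"` or `"pad"`.
#' @return Named list of strategy constructors; each maps a dose (uM) to a
#'   list of [perturbation()]s.
#' @export
therapy_strategies <- function(set = c("tumor", "pad")) {
  set <- match.arg(set)
  if (set == "tumor") {
    list(
      let7_antagonist = function(dose)
        list(perturbation("mir_antagonist", "let7_AGO1", dose)),
      AGO1_overexpression = function(dose)
        list(perturbation("mrna_overexpression", "AGO1_mRNA", dose)),
      AGO1_plus_Dicer_overexpression = function(dose)
        list(perturbation("mrna_overexpression", "AGO1_mRNA", dose),
             perturbation("mrna_overexpression", "Dicer_mRNA", dose)),
      miR15a_mimic = function(dose)
        list(perturbation("mir_mimic", "miR15a", dose)),
      TTP_overexpression = function(dose)
        list(perturbation("mrna_overexpression", "TTP_mRNA", dose)))
  } else {
    list(
      let7_mimic = function(dose)
        list(perturbation("mir_mimic", "let7", dose)),
      miR15a_antagonist = function(dose)
        list(perturbation("mir_antagonist", "miR15a_AGO1", dose)),
      combined = function(dose)
        list(perturbation("mir_mimic", "let7", dose),
             perturbation("mir_antagonist", "miR15a_AGO1", dose)))
  }
}

#' Saturating dose for a strategy
#'
#' Operational definition: antagonists and siRNAs are dosed at 10 times
#' the normoxic steady-state concentration of their binding partner (the
#' matched RISC pool for antagonists, the matched mRNA pool for siRNA);
#' mRNA overexpression and miR mimics are dosed at the top of the printed
#' transfection dose scale, 0.08 uM (the overexpression experiments use
#' 0.01-0.08 uM initial-condition bumps).
#'
#' @param model A `hifmir_model`.
#' @param strategy Strategy name from [therapy_strategies()].
#' @return Dose in uM.
#' @export
saturating_dose <- function(model, strategy) {
  oe_dose <- 0.08
  if (strategy %in% c("AGO1_overexpression",
                      "AGO1_plus_Dicer_overexpression",
                      "TTP_overexpression", "miR15a_mimic", "let7_mimic")) {
    return(oe_dose)
  }
  ss <- find_normoxic_steady_state(model)
  pool <- switch(strategy,
    let7_antagonist = ss[["let7_AGO1"]] + ss[["let7_AGO1_N"]],
    miR15a_antagonist = ,
    combined = ss[["miR15a_AGO1"]],
    stop("unknown strategy '", strategy, "'", call. = FALSE))
  10 * pool
}

## One screen cell: apply a perturbation bundle at t = 0 of the test
## condition (the untreated model is pre-equilibrated in normoxia) and
## integrate total VEGF production over the span.
.screen_cell <- function(model, perts, o2, span_min, rtol, atol) {
  pr <- protocol(o2, span_min, perturbations = perts,
                 rtol = rtol, atol = atol)
  tc <- run_protocol(model, pr)
  total_vegf_produced(tc, span_min)
}

#' Run a therapy screen
#'
#' For every (strategy, dose, O2) cell: apply the strategy's perturbation
#' bundle at t = 0 on top of the untreated normoxic steady state, simulate
#' the span, and record the total VEGF produced and its fold relative to
#' the same-O2 untreated control.  Control rows (dose 0) are included with
#' fold exactly 1.  Failed cells are recorded with `NA` and the screen
#' continues.
#'
#' @param model A `hifmir_model`.
#' @param strategies Named list from [therapy_strategies()], or a subset.
#' @param dose_grid Numeric vector of doses (uM), or `"auto"` for
#'   `saturating_dose()` times `c(0.1, 0.5, 1)`.
#' @param o2_levels Ambient O2 percentages.
#' @param span_min Production span (default 24 h).
#' @param rtol,atol Solver tolerances.
#' @return A `hifmir_screen` data frame with columns `strategy`, `dose`,
#'   `o2_percent`, `vegf_produced`, `fold`.
#' @export
run_screen <- function(model, strategies = therapy_strategies("tumor"),
                       dose_grid = "auto", o2_levels = c(0.5, 1, 2, 21),
                       span_min = 1440, rtol = 1e-8, atol = 1e-12) {
  rows <- list()
  for (o2 in o2_levels) {
    ctrl <- .screen_cell(model, list(), o2, span_min, rtol, atol)
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = "control", dose = 0, o2_percent = o2,
      vegf_produced = as.numeric(ctrl), fold = 1,
      stringsAsFactors = FALSE)
    for (nm in names(strategies)) {
      doses <- if (identical(dose_grid, "auto")) {
        saturating_dose(model, nm) * c(0.1, 0.5, 1)
      } else dose_grid
      for (d in doses) {
        val <- tryCatch(
          .screen_cell(model, strategies[[nm]](d), o2, span_min,
                       rtol, atol),
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = nm, dose = d, o2_percent = o2,
          vegf_produced = as.numeric(val),
          fold = as.numeric(val) / as.numeric(ctrl),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("hifmir_screen", "data.frame")
  out
}

#' @export
print.hifmir_screen <- function(x, ...) {
  cat("<hifmir_screen> total VEGF produced per (strategy, dose, O2)\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Peripheral-arterial-disease variant of the model
#'
#' PAD is modelled as impaired HIF-driven let-7 induction: the let-7
#' transcription constant `kp21` (the HIF-1 half-saturation of pri-let-7
#' transcription, uM) is set to 0.464 uM; nothing else changes.
#'
#' @param model A `hifmir_model` containing `kp21`.
#' @param kp21 Override value (uM).
#' @return The PAD model.
#' @export
pad_model <- function(model, kp21 = 0.464) {
  if (!("kp21" %in% model$parameters$id)) {
    stop("model has no 'kp21' parameter", call. = FALSE)
  }
  set_params(model, c(kp21 = kp21), provenance = "user")
}

#' Run the PAD therapy screen
#'
#' [run_screen()] on [pad_model()] with the pro-angiogenic strategy set;
#' folds are computed against PAD untreated controls.
#'
#' @inheritParams run_screen
#' @export
pad_screen <- function(model, strategies = therapy_strategies("pad"),
                       dose_grid = "auto", o2_levels = c(0.5, 1, 2),
                       span_min = 1440, rtol = 1e-8, atol = 1e-12) {
  run_screen(pad_model(model), strategies, dose_grid, o2_levels,
             span_min, rtol = rtol, atol = atol)
}

#' TTP overexpression screen
#'
#' Tests TTP mRNA overexpression as an anti-angiogenic treatment: TTP both
#' weakens the HIF-1 signal (HIF-1a mRNA destabilisation) and directly
#' destabilises VEGF mRNA, so VEGF folds fall below 1 in hypoxia and are
#' non-increasing in dose.
#'
#' @param model A `hifmir_model`.
#' @param doses TTP mRNA doses (uM).
#' @param o2_levels Ambient O2 percentages.
#' @param span_min Production span.
#' @export
ttp_overexpression_screen <- function(model, doses = c(0.01, 0.04, 0.08),
                                      o2_levels = c(1, 2),
                                      span_min = 1440) {
  strat <- list(TTP_overexpression = function(dose)
    list(perturbation("mrna_overexpression", "TTP_mRNA", dose)))
  run_screen(model, strat, dose_grid = doses, o2_levels = o2_levels,
             span_min = span_min)
}
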