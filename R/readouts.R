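#' Define a readout
#'
#' A readout is a named sum of species, optionally normalised to its value
#' at t = 0 (the pre-equilibrated normoxic level), matching how relative
#' expression is quantified from Western blots.
#'
#' @param name Readout name.
#' @param members Non-empty character vector of species ids (summed).
#' @param normalization `"relative_to_t0"` or `"absolute"`.
#' @return A `hifmir_readout` object.
#' @export
readout_definition <- function(name, members,
                               normalization = c("relative_to_t0",
                                                 "absolute")) {
  if (length(members) == 0L) stop("readout needs at least one member",
                                  call. = FALSE)
  structure(list(name = name, members = members,
                 normalization = match.arg(normalization)),
            class = "hifmir_readout")
}

#' Canonical readout definitions
#'
#' Total HIF-1a sums the free cytoplasmic and nuclear protein, the
#' hydroxylated form and the HIF-1 transcription-factor complex; total
#' AGO1 sums free AGO1 and every AGO1-containing RISC (including
#' antagonist-inactivated complexes); the remaining readouts are single
#' species.
#'
#' @param name One of `"total_hif1a"`, `"total_ago1"`, `"total_let7"`,
#'   `"total_mir15a"`, `"vegf_protein"`, `"free_vegf_mrna"`,
#'   `"hif1_complex"`.
#' @return A [readout_definition()].
#' @export
canonical_readout <- function(name = c("total_hif1a", "total_ago1",
                                       "total_let7", "total_mir15a",
                                       "vegf_protein", "free_vegf_mrna",
                                       "hif1_complex")) {
  name <- match.arg(name)
  members <- switch(name,
    total_hif1a = c("HIF1A", "HIF1A_OH", "HIF1A_N", "HIF1"),
    total_ago1 = c("AGO1", "let7_AGO1", "let7_AGO1_N", "miR15a_AGO1"),
    total_let7 = c("let7", "let7_AGO1", "let7_AGO1_N", "anti_let7_c"),
    total_mir15a = c("miR15a", "miR15a_AGO1", "anti_miR15a_c"),
    vegf_protein = "VEGF",
    free_vegf_mrna = "VEGF_mRNA",
    hif1_complex = "HIF1")
  readout_definition(name, members)
}

#' Relative expression of a readout over a time course
#'
#' `trace(t) = sum(members at t) / sum(members at t = 0)`; the t = 0
#' value is exactly 1.  With `normalization = "absolute"` the summed
#' concentration (uM) is returned unnormalised.
#'
#' @param tc A `hifmir_timecourse`.
#' @param readout A [readout_definition()] or a name accepted by
#'   [canonical_readout()].
#' @return Numeric vector along `tc$time` with attribute `time`.
#' @export
relative_expression <- function(tc, readout) {
  if (is.character(readout)) readout <- canonical_readout(readout)
  members <- intersect(readout$members, colnames(tc$conc))
  if (length(members) == 0L) {
    stop("no readout member present in the time course", call. = FALSE)
  }
  tot <- rowSums(species_trace(tc, members))
  if (readout$normalization == "relative_to_t0") {
    if (tot[1] <= 0) {
      stop("readout '", readout$name, "' is zero at t = 0; cannot ",
           "normalise", call. = FALSE)
    }
    tot <- tot / tot[1]
    tot[1] <- 1
  }
  attr(tot, "time") <- tc$time
  tot
}

#' Cumulative VEGF production over a span
#'
#' Time integral of the VEGF translation flux `kt_vegf * [free VEGF mRNA]`
#' (trapezoidal rule on the stored solver grid).  This is a production
#' quantity: it is independent of the VEGF degradation rate, unlike the
#' end-point VEGF level (also returned, for cross-checks).
#'
#' @param tc A `hifmir_timecourse` covering the span.
#' @param span_min Integration span in minutes (default 24 h).
#' @return Cumulative VEGF produced (uM) with attribute `endpoint_level`
#'   (VEGF concentration at the end of the span, uM).
#' @export
total_vegf_produced <- function(tc, span_min = 1440) {
  if (span_min > max(tc$time) + 1e-9) {
    stop("requested span exceeds the simulated range", call. = FALSE)
  }
  keep <- tc$time <= span_min + 1e-9
  t <- tc$time[keep]
  kt <- param_values(tc$model)[["kt_vegf"]]
  flux <- kt * species_trace(tc, "VEGF_mRNA")[keep, 1]
  total <- sum(diff(t) * (flux[-1] + flux[-length(flux)]) / 2)
  attr(total, "endpoint_level") <- species_trace(tc, "VEGF")[sum(keep), 1]
  total
}

#' Fraction of VEGF mRNA free for translation
#'
#' `free / (free + RISC-bound + p-body)` at each stored time; values lie
#' in `[0, 1]`.  Times where the total pool is zero yield `NA`.
#'
#' @param tc A `hifmir_timecourse`.
#' @return Numeric vector along `tc$time` with attribute `time`.
#' @export
free_vegf_mrna_fraction <- function(tc) {
  pools <- species_trace(tc, c("VEGF_mRNA", "VEGF_mRNA_RISC",
                               "VEGF_mRNA_PB"))
  tot <- rowSums(pools)
  frac <- ifelse(tot > 0, pools[, "VEGF_mRNA"] / tot, NA_real_)
  attr(frac, "time") <- tc$time
  frac
}

#' Transcriptional onset delay of a rising species
#'
#' Operational delay metric: the first time at which the species' net
#' increase over its t = 0 level reaches 5% of its increase at 120
#' minutes (linear interpolation between stored points).  Returns `NA`
#' when the species shows no net increase by 120 minutes.
#'
#' @param tc A `hifmir_timecourse` spanning at least 120 minutes.
#' @param species Species id.
#' @param frac Threshold fraction of the 120-min rise (default 0.05).
#' @param ref_min Reference time for the rise (default 120 min).
#' @return Delay in minutes, or `NA_real_`.
#' @export
onset_delay <- function(tc, species, frac = 0.05, ref_min = 120) {
  if (max(tc$time) < ref_min) {
    stop("time course must span at least ", ref_min, " minutes",
         call. = FALSE)
  }
  y <- species_trace(tc, species)[, 1]
  inc <- y - y[1]
  ref <- stats::approx(tc$time, inc, xout = ref_min)$y
  if (!is.finite(ref) || ref <= 0) return(NA_real_)
  thr <- frac * ref
  above <- which(inc >= thr)
  if (length(above) == 0L) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(0)
  ## interpolate the crossing inside [t[i-1], t[i]]
  t0 <- tc$time[i - 1]; t1 <- tc$time[i]
  y0 <- inc[i - 1]; y1 <- inc[i]
  t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
}
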