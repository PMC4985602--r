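# Broth-microdilution MIC estimation: two-fold dilution ladders, endpoint
# OD600 readings, the 50%-growth-inhibition MIC definition, and
# fold-resistance ratios relative to the wild type.

#' Construct a dilution series
#'
#' @param concentrations Strictly decreasing two-fold concentration ladder
#'   (nmol/L; total of both peptides at 1:1 for a two-peptide bacteriocin).
#' @param od Endpoint OD600 readings, one per concentration.
#' @param od_blank Blank (no cells) control reading.
#' @param od_growth No-bacteriocin growth control reading.
#' @return A list of class `dilution_series`.
#' @export
dilution_series <- function(concentrations, od, od_blank, od_growth) {
  if (length(concentrations) != length(od)) {
    stop("one OD reading per concentration required")
  }
  if (length(concentrations) >= 2L) {
    ratio <- concentrations[-length(concentrations)] /
      concentrations[-1L]
    if (any(abs(ratio - 2) > 1e-6)) {
      stop("concentrations must decrease two-fold per step")
    }
  }
  if (any(od < 0)) stop("OD readings must be >= 0")
  if (missing(od_blank) || missing(od_growth)) {
    stop("blank and growth controls are required")
  }
  structure(list(concentrations = concentrations, od = od,
                 od_blank = od_blank, od_growth = od_growth),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("Dilution series:", length(x$concentrations), "wells,",
      signif(max(x$concentrations), 3), "down to",
      signif(min(x$concentrations), 3), "nmol/L\n")
  invisible(x)
}

#' Per-well growth-inhibition fractions
#'
#' `1 - (OD - blank)/(growth control - blank)`, clamped to `[0, 1]`.
#'
#' @param series A [dilution_series()].
#' @return Numeric vector of inhibition fractions per concentration.
#' @export
inhibition_fractions <- function(series) {
  denom <- series$od_growth - series$od_blank
  if (denom <= 0) {
    stop("failed assay: growth control (", series$od_growth,
         ") does not exceed blank (", series$od_blank, ")")
  }
  pmin(1, pmax(0, 1 - (series$od - series$od_blank) / denom))
}

#' Estimate the MIC of a dilution series
#'
#' The MIC is the concentration at which the inhibition curve crosses 50%,
#' interpolated linearly in log2(concentration) between the bracketing
#' wells. When inhibition never reaches 50% the MIC is censored above the
#' top concentration; when even the lowest well is >= 50% inhibited it is
#' censored below the bottom. Non-monotone curves (beyond a small
#' tolerance) are flagged and the first downward crossing from the high
#' end is used.
#'
#' @param series A [dilution_series()] with at least 3 concentrations.
#' @return Object of class `mic_result`: `mic` (nmol/L, NA when censored),
#'   `censored` (`"none"`, `">top"`, `"<bottom"`), `inhibition` (per-well
#'   fractions), `non_monotone` flag.
#' @export
estimate_mic <- function(series) {
  if (length(series$concentrations) < 3L) {
    stop("at least 3 concentrations required")
  }
  conc <- series$concentrations
  inh <- inhibition_fractions(series)
  non_mono <- any(diff(inh) > 0.15)  # inhibition should fall with dilution
  res <- function(mic, censored) {
    structure(list(mic = mic, censored = censored, inhibition = inh,
                   concentrations = conc, non_monotone = non_mono),
              class = "mic_result")
  }
  if (all(inh < 0.5)) return(res(NA_real_, ">top"))
  if (all(inh >= 0.5)) return(res(NA_real_, "<bottom"))
  # first downward 0.5 crossing scanning from the highest concentration
  i <- which(inh[-length(inh)] >= 0.5 & inh[-1L] < 0.5)[1L]
  if (is.na(i)) return(res(NA_real_, ">top"))
  l2 <- log2(conc)
  mic_l2 <- l2[i] + (0.5 - inh[i]) * (l2[i + 1L] - l2[i]) /
    (inh[i + 1L] - inh[i])
  res(2^mic_l2, "none")
}

#' @export
print.mic_result <- function(x, ...) {
  if (x$censored == "none") {
    cat("MIC:", signif(x$mic, 3), "nmol/L\n")
  } else {
    bound <- if (x$censored == ">top") max(x$concentrations) else
      min(x$concentrations)
    cat("MIC censored:", x$censored, "(", signif(bound, 3), "nmol/L )\n")
  }
  invisible(x)
}

#' Fold increase of a mutant MIC over the wild type
#'
#' The resistance ratio mutant MIC / wild-type MIC, with an optional spread
#' reported as the half-range over replicate ratios rounded to one
#' significant figure. Censored MICs never enter the ratio silently: a
#' censored mutant yields a directional bound instead of a number.
#'
#' @param mutant,wildtype [estimate_mic()] results.
#' @param replicates Optional list of `list(mutant =, wildtype =)` MIC
#'   result pairs from replicate plates.
#' @return List of class `fold_increase`: `fold` (NA when censored),
#'   `bound` (character like ">1200" when censored, else NA), `spread`.
#' @export
fold_increase <- function(mutant, wildtype, replicates = NULL) {
  if (wildtype$censored != "none") {
    stop("wild-type MIC is censored (", wildtype$censored,
         "); cannot form a fold ratio")
  }
  if (mutant$censored != "none") {
    bound_conc <- if (mutant$censored == ">top")
      max(mutant$concentrations) else min(mutant$concentrations)
    dir <- substr(mutant$censored, 1L, 1L)
    return(structure(list(fold = NA_real_,
                          bound = paste0(dir, signif(bound_conc /
                                                       wildtype$mic, 2)),
                          spread = NA_real_),
                     class = "fold_increase"))
  }
  fold <- mutant$mic / wildtype$mic
  spread <- NA_real_
  if (!is.null(replicates) && length(replicates) > 0L) {
    ratios <- vapply(replicates, function(r) {
      if (r$mutant$censored != "none" || r$wildtype$censored != "none") {
        return(NA_real_)
      }
      r$mutant$mic / r$wildtype$mic
    }, numeric(1))
    ratios <- ratios[!is.na(ratios)]
    if (length(ratios) >= 2L) {
      spread <- signif((max(ratios) - min(ratios)) / 2, 1)
    }
  }
  structure(list(fold = fold, bound = NA_character_, spread = spread),
            class = "fold_increase")
}

#' @export
print.fold_increase <- function(x, ...) {
  if (is.na(x$fold)) {
    cat("Fold increase:", x$bound, "\n")
  } else if (!is.na(x$spread)) {
    cat("Fold increase:", signif(x$fold, 2), "+/-", x$spread, "\n")
  } else {
    cat("Fold increase:", signif(x$fold, 2), "\n")
  }
  invisible(x)
}
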