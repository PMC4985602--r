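# Transmembrane-helix prediction from Kyte-Doolittle hydropathy and
# localization of mutation consequences against the helix/loop
# architecture.

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Sliding-window hydropathy profile
#'
#' Kyte-Doolittle values averaged over a centered window; near the termini
#' the window shrinks symmetrically to what fits.
#'
#' @param protein Protein sequence (single string, 20 standard residues).
#' @param window Odd window size >= 7 (default 19, the classical
#'   transmembrane setting).
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  if (window %% 2L == 0L || window < 7L) {
    stop("window must be odd and >= 7")
  }
  aa <- seq_chars(protein)
  bad <- which(!aa %in% names(KD_SCALE))
  if (length(bad)) {
    stop("unknown residue '", aa[bad[1L]], "' at position ", bad[1L])
  }
  v <- unname(KD_SCALE[aa])
  n <- length(v)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)  # shrink symmetrically at the ends
  (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
}

#' Construct a topology model
#'
#' @param helices Data frame with columns start and end (residue
#'   intervals, ascending and non-overlapping).
#' @param n_terminus_side Side of the N terminus, `"cytoplasmic"`
#'   (default) or `"extracellular"`.
#' @return List of class `topology_model` with `helices` (helix/start/end/
#'   side columns) and `n_terminus_side`; loop sides alternate between
#'   consecutive helices.
#' @export
topology_model <- function(helices,
                           n_terminus_side = c("cytoplasmic",
                                               "extracellular")) {
  n_terminus_side <- match.arg(n_terminus_side)
  helices <- as.data.frame(helices)[, c("start", "end")]
  helices <- helices[order(helices$start), , drop = FALSE]
  if (nrow(helices) > 1L &&
      any(helices$start[-1L] <= helices$end[-nrow(helices)])) {
    stop("helices overlap")
  }
  helices$helix <- seq_len(nrow(helices))
  structure(list(helices = helices[, c("helix", "start", "end")],
                 n_terminus_side = n_terminus_side),
            class = "topology_model")
}

# Side of the loop after helix k (k = 0 is the N terminus).
loop_side <- function(topo, k) {
  sides <- c("cytoplasmic", "extracellular")
  first <- match(topo$n_terminus_side, sides)
  sides[(first - 1L + k) %% 2L + 1L]
}

#' @export
print.topology_model <- function(x, ...) {
  cat("Topology:", nrow(x$helices), "TM helices, N terminus",
      x$n_terminus_side, "\n")
  invisible(x)
}

#' Predict transmembrane helices from a hydropathy profile
#'
#' Maximal runs of profile values above the threshold, at least `min_run`
#' residues long, become helices; runs longer than 30 residues are split at
#' their internal hydropathy minimum. Sidedness alternates from the
#' N-terminal side.
#'
#' @param profile Numeric hydropathy profile (from
#'   [hydropathy_profile()]).
#' @param threshold Hydropathy cutoff (default 1.6).
#' @param min_run Minimum helix length in residues (default 15).
#' @param n_terminus_side Side of the N terminus.
#' @return A [topology_model()].
#' @export
predict_helices <- function(profile, threshold = 1.6, min_run = 15L,
                            n_terminus_side = "cytoplasmic") {
  if (length(profile) == 0L) stop("empty profile")
  above <- profile > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  split_run <- function(s, e) {
    if (e - s + 1L <= 30L) return(data.frame(start = s, end = e))
    inner <- (s + 5L):(e - 5L)
    cut <- inner[which.min(profile[inner])]
    rbind(split_run(s, cut - 1L), split_run(cut + 1L, e))
  }
  if (nrow(runs) > 0L) {
    runs <- do.call(rbind, mapply(split_run, runs$start, runs$end,
                                  SIMPLIFY = FALSE))
    runs <- runs[runs$end - runs$start + 1L >= min_run, , drop = FALSE]
  }
  topology_model(runs, n_terminus_side)
}

#' Localize a residue or truncation against the topology
#'
#' Every residue maps to exactly one descriptor: inside a helix, in a loop
#' between two helices (with its predicted side), N-terminal of the first
#' helix or C-terminal of the last. For truncations the descriptor refers
#' to the new C terminus -- a truncation point falling exactly on a helix
#' end reads "after TM helix N" -- and the helices removed downstream are
#' reported.
#'
#' @param residue 1-based residue index (for truncations, the last
#'   remaining residue, i.e. `truncation_after`).
#' @param topo A [topology_model()].
#' @param truncation Is `residue` a truncation point? (default FALSE).
#' @return List with `descriptor` (character), `helix` (containing helix or
#'   NA), `side` (loop side or NA), and for truncations `removed_helices`
#'   (count) and `removed` (helix indices).
#' @export
localize <- function(residue, topo, truncation = FALSE) {
  h <- topo$helices
  n_h <- nrow(h)
  inside <- which(residue >= h$start & residue <= h$end)
  removed <- if (truncation) h$helix[h$start > residue] else integer(0)

  if (length(inside) == 1L) {
    if (truncation && residue == h$end[inside]) {
      desc <- paste0("after TM helix ", h$helix[inside])
    } else {
      desc <- paste0("in TM helix ", h$helix[inside])
    }
    out <- list(descriptor = desc, helix = h$helix[inside],
                side = NA_character_)
  } else if (n_h == 0L || residue < h$start[1L]) {
    side <- loop_side(topo, 0L)
    out <- list(descriptor = paste0("N-terminal of helix 1 (", side, ")"),
                helix = NA_integer_, side = side)
  } else if (residue > h$end[n_h]) {
    side <- loop_side(topo, n_h)
    out <- list(descriptor = paste0("C-terminal of helix ", n_h, " (",
                                    side, ")"),
                helix = NA_integer_, side = side)
  } else {
    k <- max(which(h$end < residue))
    side <- loop_side(topo, k)
    out <- list(descriptor = paste0("between TM helix ", k, " and ",
                                    k + 1L, " (", side, ")"),
                helix = NA_integer_, side = side)
  }
  if (truncation) {
    out$removed_helices <- length(removed)
    out$removed <- removed
    out$descriptor <- sub(" \\((cytoplasmic|extracellular)\\)$", "",
                          out$descriptor)
  }
  out
}

#' Localize a consequence call
#'
#' Convenience wrapper: truncating calls (nonsense, frameshift) are
#' localized at their truncation point, substitutions at their codon.
#'
#' @param call A `consequence_call` row (see [classify()]).
#' @param topo A [topology_model()].
#' @return See [localize()].
#' @export
localize_call <- function(call, topo) {
  call <- as.data.frame(call)[1L, ]
  if (!is.na(call$truncation_after)) {
    localize(call$truncation_after, topo, truncation = TRUE)
  } else {
    localize(call$codon_index, topo)
  }
}
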