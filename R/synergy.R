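#' Bliss-independence expected inhibition
#'
#' Under Bliss independence two drugs act as independent probabilistic
#' events, so the expected combined inhibition is `A + B - A*B`. Inputs are
#' clipped into \[0, 1\] first (TGI can exceed 1 for cytotoxic responses, but
#' Bliss arithmetic requires probabilities).
#'
#' @param inh_a,inh_b Single-agent inhibition fractions (recycled).
#' @return Expected combined inhibition in \[0, 1\].
#' @export
bliss_expected <- function(inh_a, inh_b) {
  if (any(!is.finite(inh_a)) || any(!is.finite(inh_b)))
    stop("single-agent inhibitions must be finite")
  a <- pmin(pmax(inh_a, 0), 1)
  b <- pmin(pmax(inh_b, 0), 1)
  a + b - a * b
}

#' ΔBLISS synergy surface over a combination dose matrix
#'
#' Takes the observed TGI matrix of a checkerboard combination experiment,
#' whose first row and first column (zero dose of the other agent) are the
#' single-agent responses, and computes for every cell the Bliss expectation
#' from the measured zero-dose edges and the ΔBLISS excess
#' `observed - expected`, floored at zero. A ΔBLISS of 0 indicates additivity
#' and values approaching 1 indicate synergy; the signed (unfloored) excess
#' is retained in `excess` so antagonism (negative values) stays visible.
#'
#' @param observed Numeric matrix of TGI fractions; rows indexed by
#'   `doses_a` (ascending, first entry 0), columns by `doses_b` (ascending,
#'   first entry 0). Values are clipped to \[0, 1\] before Bliss arithmetic.
#' @param doses_a,doses_b Dose vectors (molar) including the zero-dose edge.
#' @return Object of class `combination_surface`: list with `doses_a`,
#'   `doses_b`, `observed` (clipped), `expected`, `delta` (floored at 0) and
#'   `excess` (signed).
#' @export
delta_bliss_surface <- function(observed, doses_a, doses_b) {
  observed <- as.matrix(observed)
  if (nrow(observed) != length(doses_a) || ncol(observed) != length(doses_b))
    stop("dimensions of 'observed' must match the dose vectors")
  if (doses_a[1] != 0 || doses_b[1] != 0)
    stop(paste0("incomplete matrix: the observed matrix must include the ",
                "zero-dose single-agent edges as its first row and column"))
  if (is.unsorted(doses_a) || is.unsorted(doses_b))
    stop("doses must be in ascending order")
  if (any(!is.finite(observed)))
    stop("observed TGI matrix contains non-finite values")
  obs <- pmin(pmax(observed, 0), 1)
  expected <- outer(obs[, 1], obs[1, ], bliss_expected)
  excess <- obs - expected
  delta <- pmax(excess, 0)
  dimnames(obs) <- dimnames(expected) <- dimnames(excess) <- dimnames(delta) <-
    list(dose_a = signif(doses_a, 4), dose_b = signif(doses_b, 4))
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 observed = obs, expected = expected,
                 delta = delta, excess = excess),
            class = "combination_surface")
}

#' @export
print.combination_surface <- function(x, ...) {
  cat(sprintf("<combination_surface> %d x %d doses | max ΔBLISS %.3f | min excess %.3f\n",
              length(x$doses_a), length(x$doses_b),
              max(x$delta), min(x$excess)))
  invisible(x)
}

#' Maximal-synergy dose window of a ΔBLISS surface
#'
#' Finds the largest upper-right block of the dose grid on which every cell
#' reaches at least `threshold_fraction` of the maximal ΔBLISS, and reports
#' its boundary in the field's ">X nM drug A and >Y nM drug B" style: the
#' returned `min_dose_a`/`min_dose_b` are the highest tested doses *below*
#' the qualifying block (exclusive lower bounds; 0 when the block already
#' starts at the lowest non-zero dose). Among qualifying corners the one
#' covering the most grid cells, then with the lowest drug-A dose, is chosen.
#'
#' @param surface A `combination_surface`.
#' @param threshold_fraction Fraction of the maximum ΔBLISS every window cell
#'   must reach (default 0.9).
#' @return Object of class `synergy_window`: list with `min_dose_a`,
#'   `min_dose_b` (exclusive bounds, molar), `threshold_fraction`,
#'   `max_delta`, and `empty` (TRUE when `max_delta == 0` so no window
#'   exists).
#' @export
max_synergy_window <- function(surface, threshold_fraction = 0.9) {
  stopifnot(inherits(surface, "combination_surface"),
            threshold_fraction > 0, threshold_fraction <= 1)
  delta <- surface$delta
  md <- max(delta)
  if (length(delta) == 0)
    stop("empty delta matrix")
  if (md <= 0) {
    return(structure(list(min_dose_a = NA_real_, min_dose_b = NA_real_,
                          threshold_fraction = threshold_fraction,
                          max_delta = md, empty = TRUE),
                     class = "synergy_window"))
  }
  thr <- threshold_fraction * md
  ok <- delta >= thr
  nr <- nrow(ok); nc <- ncol(ok)
  best <- NULL
  for (i in 2:nr) {       # corners start above the zero-dose edges,
    for (j in 2:nc) {     # where delta is 0 by construction
      if (all(ok[i:nr, j:nc])) {
        size <- (nr - i + 1) * (nc - j + 1)
        if (is.null(best) || size > best$size ||
            (size == best$size && i < best$i))
          best <- list(i = i, j = j, size = size)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(min_dose_a = NA_real_, min_dose_b = NA_real_,
                          threshold_fraction = threshold_fraction,
                          max_delta = md, empty = TRUE),
                     class = "synergy_window"))
  }
  structure(list(
    min_dose_a = surface$doses_a[best$i - 1L],
    min_dose_b = surface$doses_b[best$j - 1L],
    threshold_fraction = threshold_fraction,
    max_delta = md, empty = FALSE
  ), class = "synergy_window")
}

#' @export
print.synergy_window <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("<synergy_window> empty (max ΔBLISS %.3f)\n", x$max_delta))
  } else {
    cat(sprintf("<synergy_window> > %s drug A and > %s drug B (ΔBLISS >= %.2f of max %.3f)\n",
                format_concentration(x$min_dose_a),
                format_concentration(x$min_dose_b),
                x$threshold_fraction, x$max_delta))
  }
  invisible(x)
}
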