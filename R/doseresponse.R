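#' Serial-dilution dose ladder
#'
#' Builds the concentration series used on a viability plate: `n_points`
#' concentrations starting at `top` and decreasing by a constant `fold`
#' ratio, so element `i` equals `top / fold^(i-1)`. The canonical single-agent
#' design is 9 points from 10 µM by 4-fold, bottoming out at ~153 pM.
#'
#' @param top Highest concentration (molar), > 0.
#' @param fold Dilution ratio between consecutive points, > 1 (or exactly 1
#'   only when `n_points == 1`, i.e. no dilution performed).
#' @param n_points Number of concentrations, >= 1.
#' @return An object of class `dose_ladder`: numeric vector of molar
#'   concentrations in decreasing order, with attributes `top`, `fold`.
#' @examples
#' ladder <- build_dilution_ladder(10e-6, 4, 9)
#' format_concentration(min(ladder))  # "153 pM"
#' @export
build_dilution_ladder <- function(top, fold, n_points) {
  if (!is.numeric(top) || length(top) != 1L || !is.finite(top) || top <= 0)
    stop("'top' must be a single positive concentration (molar)")
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1 ||
      n_points != round(n_points))
    stop("'n_points' must be a positive whole number")
  if (!is.numeric(fold) || length(fold) != 1L || !is.finite(fold) ||
      (n_points > 1 && fold <= 1) || fold < 1)
    stop("'fold' must be a dilution ratio > 1")
  conc <- top / fold^(seq_len(n_points) - 1)
  structure(conc, class = "dose_ladder", top = top, fold = fold)
}

#' @export
print.dose_ladder <- function(x, ...) {
  cat(sprintf("<dose_ladder> %d points, top %s, %g-fold\n",
              length(x), format_concentration(attr(x, "top")),
              attr(x, "fold")))
  cat(" ", paste(vapply(unclass(x), format_concentration, ""),
                 collapse = ", "), "\n")
  invisible(x)
}

#' Display a molar concentration with a human unit
#'
#' Reporting helper: rounds to 3 significant figures and picks the unit
#' (M, mM, µM, nM, pM) so e.g. `1.52588e-10` displays as `"153 pM"`.
#'
#' @param x Concentration in molar.
#' @param digits Significant figures for display (default 3).
#' @return Character scalar.
#' @export
format_concentration <- function(x, digits = 3) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  if (x == 0) return("0 M")
  units <- c(M = 1, mM = 1e-3, `µM` = 1e-6, nM = 1e-9, pM = 1e-12)
  i <- which(abs(x) >= units * 0.9995)[1]
  if (is.na(i)) i <- length(units)
  val <- signif(x / units[i], digits)
  paste0(format(val, scientific = FALSE, trim = TRUE), " ", names(units)[i])
}

#' Tumour-cell growth inhibition (TGI) from raw plate counts
#'
#' Counts are first baseline-adjusted by subtracting the mean of the day-1
#' (seeding-time) untreated wells; TGI is then one minus the ratio of
#' adjusted treated to adjusted endpoint-untreated signal:
#' `TGI = 1 - (treated - mean(baseline)) / (mean(untreated) - mean(baseline))`.
#' TGI is 0 for a well indistinguishable from untreated growth, 1 for growth
#' stasis at the seeding level, > 1 for net cell kill and < 0 for growth
#' stimulation.
#'
#' @param raw_treated Numeric vector of raw treated-well counts.
#' @param plate A `plate_readout` (see [read_plate_csv()] or
#'   [simulate_plate()]), or any list with numeric `baseline_wells` and
#'   `untreated_wells`.
#' @return Numeric vector of TGI fractions, same length as `raw_treated`.
#' @export
compute_tgi <- function(raw_treated, plate) {
  b <- plate$baseline_wells
  u <- plate$untreated_wells
  if (length(b) < 1L || length(u) < 1L)
    stop("plate must carry at least one baseline and one untreated well")
  adj <- mean(u) - mean(b)
  if (!is.finite(adj) || adj <= 0)
    stop(sprintf(paste0("degenerate plate: adjusted untreated signal ",
                        "(mean untreated %.3g - mean baseline %.3g = %.3g) ",
                        "is not positive"),
                 mean(u), mean(b), adj))
  1 - (raw_treated - mean(b)) / adj
}

#' Evaluate a four-parameter logistic dose-response curve
#'
#' `TGI(x) = L + (U - L) / (1 + (IC50/x)^h)` with Hill slope `h > 0`, so the
#' response rises with dose and equals `(L + U)/2` exactly at `x = IC50`
#' (relative IC50 = inflection).
#'
#' @param fit A `four_pl_fit`, or a list with numeric `lower`, `upper`,
#'   `ic50`, `hill`.
#' @param dose Positive dose(s), molar.
#' @return Predicted TGI fraction(s).
#' @export
predict_4pl <- function(fit, dose) {
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("'dose' must be positive and finite")
  fit$lower + (fit$upper - fit$lower) / (1 + (fit$ic50 / dose)^fit$hill)
}

# Residual sum of squares for the 4PL on log10-dose scale;
# theta = (L, U, log10(ic50), h)
.rss_4pl <- function(theta, logd, tgi) {
  pred <- theta[1] + (theta[2] - theta[1]) /
    (1 + 10^(theta[4] * (theta[3] - logd)))
  sum((tgi - pred)^2)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `TGI(x) = L + (U-L)/(1 + (IC50/x)^h)` with the IC50
#' optimised on the log10-dose scale under box constraints
#' (`L` in \[-0.5, 1\], `U` in \[0, 1.5\], `h` in (0, 10\],
#' `IC50` in \[lowest dose / 100, top dose x 100\]), from three deterministic
#' starting points. Replicate TGI values at the same dose are averaged before
#' fitting. When the fitted span `U - L` falls below `min_span` (no detectable
#' effect) or the fitted IC50 exceeds the top tested dose, the IC50 is
#' reported as a censored bound equal to the top dose
#' (`censored = "greater_than_top"`), matching the ">1 µM" reporting style
#' used for non-responding lines.
#'
#' @param doses Numeric vector of doses (molar) or a `dose_ladder`.
#' @param tgis Numeric vector of TGI fractions, same length as `doses`.
#' @param min_span Minimum fitted `U - L` before the curve is declared flat
#'   (default 0.2 TGI units).
#' @return Object of class `four_pl_fit`: list with `lower`, `upper`, `ic50`
#'   (molar; the top-dose bound when censored), `hill`, `censored` (`"exact"`
#'   or `"greater_than_top"`), `rss`, `converged`, `n_doses`, `top_dose`.
#' @examples
#' ladder <- build_dilution_ladder(10e-6, 4, 9)
#' truth <- list(lower = 0, upper = 1, ic50 = 10e-9, hill = 1)
#' fit <- fit_4pl(ladder, predict_4pl(truth, ladder))
#' fit$ic50 * 1e9  # ~10 nM
#' @export
fit_4pl <- function(doses, tgis, min_span = 0.2) {
  doses <- as.numeric(doses)
  if (length(doses) != length(tgis))
    stop("'doses' and 'tgis' must have equal length")
  ok <- is.finite(doses) & doses > 0 & is.finite(tgis)
  doses <- doses[ok]; tgis <- as.numeric(tgis)[ok]
  # average replicates
  agg <- tapply(tgis, doses, mean)
  d <- as.numeric(names(agg)); y <- as.numeric(agg)
  o <- order(d); d <- d[o]; y <- y[o]
  if (length(d) < 4L)
    stop(sprintf("insufficient data: %d distinct finite doses, need >= 4",
                 length(d)))
  logd <- log10(d)
  top <- max(d)
  lower_box <- c(-0.5, 0, log10(min(d) / 100), 1e-3)
  upper_box <- c(1, 1.5, log10(top * 100), 10)

  L0 <- min(max(min(y), lower_box[1]), upper_box[1])
  U0 <- min(max(max(y), lower_box[2]), upper_box[2])
  # dose whose response is nearest the half-effect, as an IC50 guess
  half <- (L0 + U0) / 2
  m_half <- logd[which.min(abs(y - half))]
  starts <- list(
    c(L0, U0, m_half, 1),
    c(L0, U0, mean(range(logd)), 1),
    c(L0, U0, max(logd) - 1, 2)
  )
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower_box), upper_box)
    res <- tryCatch(
      stats::optim(s, .rss_4pl, logd = logd, tgi = y,
                   method = "L-BFGS-B",
                   lower = lower_box, upper = upper_box,
                   control = list(factr = 1e4, maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value))
      best <- res
  }
  if (is.null(best)) {
    return(structure(list(lower = NA_real_, upper = NA_real_,
                          ic50 = NA_real_, hill = NA_real_,
                          censored = "fit_failure", rss = NA_real_,
                          converged = FALSE, n_doses = length(d),
                          top_dose = top),
                     class = "four_pl_fit"))
  }
  th <- best$par
  ic50 <- 10^th[3]
  span <- th[2] - th[1]
  censored <- if (span < min_span || ic50 > top) "greater_than_top" else "exact"
  structure(list(
    lower = th[1], upper = th[2],
    ic50 = if (censored == "exact") ic50 else top,
    hill = th[4],
    censored = censored,
    rss = best$value,
    converged = best$convergence == 0,
    n_doses = length(d),
    top_dose = top
  ), class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  if (identical(x$censored, "fit_failure")) {
    cat("<four_pl_fit> fit failure (optimizer did not converge)\n")
    return(invisible(x))
  }
  ic <- if (x$censored == "greater_than_top")
    paste0("> ", format_concentration(x$ic50))
  else format_concentration(x$ic50)
  cat(sprintf("<four_pl_fit> IC50 %s | L %.3f U %.3f h %.2f | RSS %.3g (%d doses)\n",
              ic, x$lower, x$upper, x$hill, x$rss, x$n_doses))
  invisible(x)
}
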