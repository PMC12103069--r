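#' Quantitative 1:1 binding analysis
#'
#' Fraction-bound transformation and dissociation-constant (Kd) fitting for
#' fluorescence titrations in which a labeled receptor (the E3 ligase, held
#' at constant low concentration, 10 nM by default) is titrated with a
#' serially diluted ligand (the E2 enzyme). Because the tightest affinities
#' are within an order of magnitude of the receptor concentration, the exact
#' ligand-depletion-corrected quadratic isotherm is used rather than the
#' hyperbolic approximation.
#'
#' @name binding
NULL

#' Exact fraction of receptor bound under ligand depletion
#'
#' Solves the 1:1 mass-action equilibrium exactly for total concentrations:
#' `f = ((kd + l + r) - sqrt((kd + l + r)^2 - 4 l r)) / (2 r)`, evaluated in
#' the numerically stable form `2 l / (S + sqrt(S^2 - 4 l r))` which avoids
#' catastrophic cancellation as `f -> 0`.
#'
#' @param l_tot total ligand concentration (molar, vectorised).
#' @param r_tot total receptor concentration (molar, > 0).
#' @param kd dissociation constant (molar, > 0).
#' @return fraction of receptor bound, in \[0, 1\].
#' @export
fraction_bound <- function(l_tot, r_tot, kd) {
  if (any(l_tot < 0)) stop("l_tot must be >= 0")
  if (any(r_tot <= 0)) stop("r_tot must be > 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  s <- kd + l_tot + r_tot
  disc <- s * s - 4 * l_tot * r_tot
  disc[disc < 0] <- 0                      # guard rounding at f ~ 1
  2 * l_tot / (s + sqrt(disc))
}

#' Geometric serial-dilution series
#'
#' @param c_max top concentration (molar).
#' @param n number of points (default 16).
#' @param factor dilution factor per step (default 2).
#' @return decreasing concentration vector of length `n`:
#'   `c_max, c_max/factor, ..., c_max/factor^(n-1)`.
#' @export
serial_dilution <- function(c_max, n = 16, factor = 2) {
  stopifnot(c_max > 0, n >= 2)
  if (!is.numeric(factor) || factor <= 1) stop("dilution factor must be > 1")
  c_max / factor^(seq_len(n) - 1)
}

#' Construct a titration series
#'
#' @param ligand_conc total ligand concentrations (molar, positive,
#'   length >= 8).
#' @param signal matched fluorescence readings (arbitrary units).
#' @param receptor_conc total labeled receptor concentration (molar,
#'   default 1e-8 = 10 nM).
#' @param replicate_id label.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(ligand_conc, signal, receptor_conc = 1e-8,
                             replicate_id = "r1") {
  if (length(ligand_conc) != length(signal))
    stop("ligand_conc and signal must have equal length")
  if (length(ligand_conc) < 8L)
    stop("a titration needs at least 8 points")
  if (any(ligand_conc <= 0)) stop("ligand concentrations must be positive")
  o <- order(ligand_conc)
  if (anyDuplicated(ligand_conc))
    stop("ligand concentrations must be strictly ordered after sorting")
  structure(list(ligand_conc = ligand_conc[o], signal = signal[o],
                 receptor_conc = receptor_conc,
                 replicate_id = replicate_id),
            class = "titration_series")
}

#' Read titration series from CSV/TSV
#'
#' Expects columns `replicate_id`, `ligand_conc_molar`, `signal`; the
#' delimiter is sniffed from the header line.
#'
#' @param path file path.
#' @param receptor_conc molar (default 1e-8).
#' @return list of [titration_series], one per replicate.
#' @export
read_titration_csv <- function(path, receptor_conc = 1e-8) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("replicate_id", "ligand_conc_molar", "signal")
  if (!all(need %in% names(tab)))
    stop("titration table must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$replicate_id), function(d) {
    titration_series(d$ligand_conc_molar, d$signal, receptor_conc,
                     replicate_id = d$replicate_id[1])
  })
}

#' Transform a fitted titration to fraction bound
#'
#' `(signal - baseline) / amplitude` per point; values may fall outside
#' \[0, 1\] through noise and are deliberately not clipped.
#'
#' @param series a [titration_series].
#' @param fit an [fit_isotherm()] result (supplies baseline and amplitude).
#' @return numeric vector of fraction-bound values, ordered as
#'   `series$ligand_conc`.
#' @export
to_fraction_bound <- function(series, fit) {
  if (!is.finite(fit$amplitude) || fit$amplitude == 0)
    stop("fitted amplitude is zero; fraction bound undefined")
  (series$signal - fit$baseline) / fit$amplitude
}

# residual sum of squares profiled over (baseline, amplitude) at fixed kd
.isotherm_rss <- function(log10_kd, l, r, y) {
  f <- fraction_bound(l, r, 10^log10_kd)
  fit <- stats::lm.fit(cbind(1, f), y)
  sum(fit$residuals^2)
}

.isotherm_solve <- function(l, r, y, grid) {
  rss <- vapply(grid, .isotherm_rss, numeric(1), l = l, r = r, y = y)
  k <- which.min(rss)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- optimize(.isotherm_rss, c(lo, hi), l = l, r = r, y = y,
                  tol = 1e-10)
  # keep the grid point if refinement did not improve (flat profile guard)
  if (opt$objective <= rss[k]) {
    list(log10_kd = opt$minimum, rss = opt$objective,
         interior = k > 1L && k < length(grid))
  } else {
    list(log10_kd = grid[k], rss = rss[k],
         interior = k > 1L && k < length(grid))
  }
}

#' Fit the depletion-corrected 1:1 isotherm
#'
#' Least-squares fit of `signal = baseline + amplitude * f(l; r, kd)` where
#' `f` is [fraction_bound()]. Baseline and amplitude are profiled out
#' linearly and the Kd is optimised on a log10 scale: a log-spaced grid
#' spanning `[c_min/100, c_max*100]` is scanned and the best bracket is
#' refined by 1-D minimisation, which makes the fit deterministic and immune
#' to bad starting values. Confidence intervals come from a seeded
#' residual-resampling bootstrap (percentile, 2.5/97.5). The fit is flagged
#' unreliable when the signal-to-noise ratio - the response realised over
#' the titrated range, `|amplitude| * span(fraction bound)`, divided by the
#' RMS residual - is below `snr_min` (10, the threshold below which an
#' affinity measurement is not considered reliable).
#'
#' @param series a [titration_series] or a list of them (replicates pooled
#'   into one fit).
#' @param n_boot bootstrap draws (default 1000; 0 disables the CI).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param snr_min reliability threshold on signal-to-noise (default 10).
#' @param grid_points number of log10-Kd grid points (default 61).
#' @param warn_span warn when the data do not bracket the fitted Kd
#'   (default TRUE).
#' @return object of class `isotherm_fit`: `kd`, `amplitude`, `baseline`,
#'   `kd_ci` (molar, NA when `n_boot = 0`), `snr`, `reliable`, `converged`,
#'   `n_points`, `residuals`, `boot_kd`.
#' @export
fit_isotherm <- function(series, n_boot = 1000, seed = 1, snr_min = 10,
                         grid_points = 61, warn_span = TRUE) {
  if (inherits(series, "titration_series")) series <- list(series)
  stopifnot(length(series) >= 1L)
  l <- unlist(lapply(series, `[[`, "ligand_conc"))
  y <- unlist(lapply(series, `[[`, "signal"))
  r <- series[[1]]$receptor_conc
  if (length(l) < 8L) stop("at least 8 points are required")

  grid <- seq(log10(min(l) / 100), log10(max(l) * 100),
              length.out = grid_points)
  sol <- .isotherm_solve(l, r, y, grid)
  kd <- 10^sol$log10_kd
  f <- fraction_bound(l, r, kd)
  ab <- coef(lm(y ~ f))
  baseline <- unname(ab[1])
  amplitude <- unname(ab[2])
  if (is.na(amplitude)) amplitude <- 0   # constant-signal degenerate case
  resid <- y - (baseline + amplitude * f)
  rms <- sqrt(mean(resid^2))
  # S/N compares the response actually realised over the titrated range
  # (amplitude times the spanned fraction bound) with the residual noise;
  # a flat series can fit an arbitrarily large nominal amplitude over a
  # vanishing fraction-bound span and must not count as signal
  response <- abs(amplitude) * (max(f) - min(f))
  snr <- if (rms > 0) response / rms else Inf
  if (warn_span && (kd < min(l) || kd > max(l)))
    warning("fitted Kd lies outside the titrated concentration range; ",
            "the series does not span the transition")

  boot_kd <- numeric(0)
  kd_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    yhat <- y - resid
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    boot_kd <- vapply(seq_len(n_boot), function(b) {
      yb <- yhat + sample(resid, length(resid), replace = TRUE)
      10^.isotherm_solve(l, r, yb, grid)$log10_kd
    }, numeric(1))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    kd_ci <- unname(quantile(boot_kd, c(0.025, 0.975)))
  }

  structure(list(kd = kd, amplitude = amplitude, baseline = baseline,
                 kd_ci = kd_ci, snr = snr, reliable = snr >= snr_min,
                 converged = sol$interior && amplitude != 0,
                 n_points = length(l), residuals = resid,
                 boot_kd = boot_kd, receptor_conc = r),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("isotherm_fit: Kd = %.3g M", x$kd))
  if (!is.na(x$kd_ci[1]))
    cat(sprintf(" (95%% CI %.3g - %.3g)", x$kd_ci[1], x$kd_ci[2]))
  cat(sprintf("\n  amplitude %.3g, baseline %.3g, S/N %.1f (%s), %d points\n",
              x$amplitude, x$baseline, x$snr,
              if (x$reliable) "reliable" else "unreliable", x$n_points))
  invisible(x)
}

#' Kd fold change between two fits
#'
#' Ratio `kd_b / kd_a` (how many times weaker the second interaction is),
#' with a percentile CI from paired bootstrap draws when both fits carry
#' them.
#'
#' @param fit_a,fit_b [fit_isotherm()] results; both must have converged.
#' @return list with `ratio` and `ci` (NA without bootstrap draws).
#' @export
fold_change <- function(fit_a, fit_b) {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("fold_change requires two converged fits")
  ratio <- fit_b$kd / fit_a$kd
  nb <- min(length(fit_a$boot_kd), length(fit_b$boot_kd))
  ci <- if (nb > 0) {
    unname(quantile(fit_b$boot_kd[seq_len(nb)] / fit_a$boot_kd[seq_len(nb)],
                    c(0.025, 0.975)))
  } else c(NA_real_, NA_real_)
  list(ratio = ratio, ci = ci)
}
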