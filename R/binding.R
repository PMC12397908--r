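# Binding models and fitters: the quadratic (ligand-depletion) equation
# for fluorescence titrations and the one-set-of-sites isotherm for ITC.

#' Quadratic binding signal
#'
#' Exact 1:1 binding solution with ligand depletion. The fraction of
#' fluorophore bound at total protein `P` and total fluorophore `L_total` is
#' \deqn{f = \frac{(P + L + K_D) - \sqrt{(P + L + K_D)^2 - 4 P L}}{2L}}
#' and the signal interpolates linearly between `F_free` and `F_bound`.
#' Unlike the hyperbolic isotherm this remains valid when the fluorophore
#' concentration is comparable to the dissociation constant.
#'
#' @param P total protein concentration(s), uM (vectorised).
#' @param L_total total fluorophore concentration, uM.
#' @param Kd dissociation constant, uM.
#' @param F_free,F_bound signal of the free and bound fluorophore (a.u.).
#' @return signal in the same units as `F_free`/`F_bound`.
#' @export
quadratic_signal <- function(P, L_total, Kd, F_free, F_bound) {
  if (any(P <= 0) || L_total <= 0 || Kd <= 0)
    stop("P, L_total and Kd must be > 0")
  s <- P + L_total + Kd
  disc <- s^2 - 4 * P * L_total
  if (any(disc < -1e-8 * s^2))
    stop("negative discriminant; invalid concentrations")
  f <- (s - sqrt(pmax(disc, 0))) / (2 * L_total)
  f <- pmin(pmax(f, 0), 1)
  F_free + (F_bound - F_free) * f
}

# log-spaced Kd starting values for the multi-start fits
kd_starts <- function(lo, hi, k = 5) 10^seq(log10(lo), log10(hi), length.out = k)

#' Fit the quadratic binding equation to a titration
#'
#' Nonlinear least squares over (Kd, F_free, F_bound) via the
#' Levenberg-Marquardt algorithm with a positivity bound on Kd. To avoid
#' local minima the fit is multi-started from five log-spaced Kd values
#' spanning the measured concentration range (unless `start` is given);
#' the converged fit with the smallest residual sum of squares wins.
#'
#' @param curve a [titration_curve()].
#' @param start optional named list/vector with `Kd`, `F_free`, `F_bound`.
#' @param lower_Kd lower bound on Kd (uM).
#' @return object of class `quadratic_fit`: `Kd`, `F_free`, `F_bound`,
#'   per-parameter standard errors `se`, residual sum of squares `rss`,
#'   logical `at_bound` flagging a Kd pinned at its bound.
#' @export
fit_quadratic <- function(curve, start = NULL, lower_Kd = 1e-6) {
  stopifnot(inherits(curve, "titration_curve"))
  P <- curve$P_total; y <- curve$signal; L <- curve$L_total
  if (length(P) < 4) stop("need at least 4 titration points")
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1))
    stop("signal is constant; Kd is unidentifiable")
  starts <- if (!is.null(start)) list(as.list(start)) else {
    lapply(kd_starts(max(min(P) / 5, lower_Kd * 10), max(P) * 5),
           function(k) list(Kd = k, F_free = y[which.min(P)],
                            F_bound = y[which.max(P)]))
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ quadratic_signal(P, L, Kd, F_free, F_bound),
                        start = s0,
                        lower = c(Kd = lower_Kd, F_free = -Inf, F_bound = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("quadratic fit failed to converge from any starting point")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  out <- structure(list(Kd = unname(cf["Kd"]), F_free = unname(cf["F_free"]),
                        F_bound = unname(cf["F_bound"]),
                        se = c(Kd = unname(se["Kd"]), F_free = unname(se["F_free"]),
                               F_bound = unname(se["F_bound"])),
                        rss = best$rss,
                        at_bound = unname(cf["Kd"]) <= lower_Kd * (1 + 1e-6)),
                   class = "quadratic_fit")
  if (out$at_bound) warning("fitted Kd is at its lower bound; unidentifiable")
  out
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("quadratic binding fit: Kd = %.4g +/- %.2g uM (F_free %.4g, F_bound %.4g, rss %.4g)%s\n",
              x$Kd, x$se["Kd"], x$F_free, x$F_bound, x$rss,
              if (x$at_bound) " [Kd AT BOUND]" else ""))
  invisible(x)
}

# post-injection total concentrations in the cell, with the cumulative
# displaced-volume dilution of an overfilled cell: each injection of dv
# dilutes what is already in the cell by (1 - dv/V0)
itc_concentrations <- function(cell_conc, syringe_conc, injections, V0) {
  k <- length(injections)
  M <- numeric(k); X <- numeric(k)
  m <- cell_conc; x <- 0
  for (i in seq_len(k)) {
    f <- 1 - injections[i] / V0
    m <- m * f
    x <- x * f + syringe_conc * injections[i] / V0
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

#' One-set-of-sites ITC heats
#'
#' Per-injection heats of the standard single-class-of-sites isotherm for
#' `n` identical independent sites, with the displaced-volume correction
#' for an overfilled calorimeter cell. Cumulative heat after injection i is
#' \deqn{Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + \frac{X_i}{n M_i} +
#'   \frac{K_D}{n M_i} - \sqrt{\left(1 + \frac{X_i}{n M_i} +
#'   \frac{K_D}{n M_i}\right)^2 - \frac{4 X_i}{n M_i}}\right]}
#' with M, X the dilution-corrected total cell and titrant concentrations,
#' and the observed per-injection heat is
#' \eqn{\Delta Q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2}.
#'
#' @param Kd dissociation constant, uM.
#' @param n stoichiometry (sites per cell macromolecule).
#' @param dH binding enthalpy, kcal/mol.
#' @param cell_conc initial cell concentration, uM.
#' @param syringe_conc syringe concentration, uM.
#' @param injections injection volumes, ul.
#' @param V0 cell volume, ul.
#' @return per-injection heats, ucal.
#' @export
itc_heats <- function(Kd, n, dH, cell_conc, syringe_conc, injections,
                      V0 = 200) {
  if (Kd <= 0 || n <= 0) stop("Kd and n must be > 0")
  if (cell_conc <= 0 || syringe_conc <= 0 || V0 <= 0 || any(injections <= 0))
    stop("concentrations and volumes must be > 0")
  cc <- itc_concentrations(cell_conc, syringe_conc, injections, V0)
  r <- cc$X / (n * cc$M)
  b <- 1 + r + Kd / (n * cc$M)
  disc <- b^2 - 4 * r
  if (any(disc < -1e-10)) stop("negative discriminant in isotherm")
  ## uM * ul * kcal/mol = 1e-3 ucal
  Q <- (n * cc$M * dH * V0 / 2) * (b - sqrt(pmax(disc, 0))) * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  Q - Qprev + (injections / V0) * (Q + Qprev) / 2
}

#' Fit the one-set-of-sites model to an ITC experiment
#'
#' Levenberg-Marquardt least squares over (Kd, n, dH) against the
#' per-injection heats, multi-started from five log-spaced Kd values.
#' The Wiseman c-value (`n * cell_conc / Kd`) is reported and a warning is
#' issued when it falls outside [1, 1000], where Kd is weakly determined.
#'
#' @param exp an [itc_experiment()].
#' @param start optional named list with `Kd`, `n`, `dH`.
#' @param exclude_first drop the first injection (conventional when the
#'   schedule begins with a small test injection), default `FALSE`.
#' @return object of class `itc_fit`: `Kd`, `n`, `dH`, `se`, `rss`,
#'   `c_value`.
#' @export
fit_itc <- function(exp, start = NULL, exclude_first = FALSE) {
  stopifnot(inherits(exp, "itc_experiment"))
  inj <- exp$injections; q <- exp$heats
  keep <- if (exclude_first) -1 else seq_along(q)
  qk <- q[keep]
  if (length(qk) < 8) stop("need at least 8 informative injections")
  if (max(abs(qk)) <= 1e-12) {
    warning("all heats are zero; dH ~ 0 and Kd is unidentifiable")
    return(structure(list(Kd = NA_real_, n = NA_real_, dH = 0,
                          se = c(Kd = NA, n = NA, dH = NA), rss = 0,
                          c_value = NA_real_),
                     class = "itc_fit"))
  }
  ## crude dH scale from total heat assuming full saturation at n = 1
  dH0 <- sum(q) / (exp$cell_conc * exp$V0 * 1e-3)
  starts <- if (!is.null(start)) list(as.list(start)) else {
    lapply(kd_starts(0.01, 100), function(k) list(Kd = k, n = 1, dH = dH0))
  }
  model_fun <- function(Kd, n, dH)
    itc_heats(Kd, n, dH, exp$cell_conc, exp$syringe_conc, inj, exp$V0)[keep]
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(qk ~ model_fun(Kd, n, dH), start = s0,
                        lower = c(Kd = 1e-6, n = 1e-3, dH = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("ITC fit failed to converge from any starting point")
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  cval <- unname(cf["n"]) * exp$cell_conc / unname(cf["Kd"])
  if (cval < 1 || cval > 1000)
    warning(sprintf("c-value %.3g outside [1, 1000]; Kd is weakly determined",
                    cval))
  structure(list(Kd = unname(cf["Kd"]), n = unname(cf["n"]),
                 dH = unname(cf["dH"]),
                 se = c(Kd = unname(se["Kd"]), n = unname(se["n"]),
                        dH = unname(se["dH"])),
                 rss = best$rss, c_value = cval),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("one-set-of-sites ITC fit: Kd = %.4g +/- %.2g uM, n = %.3g +/- %.2g, dH = %.4g kcal/mol (c = %.3g, rss %.4g)\n",
              x$Kd, x$se["Kd"], x$n, x$se["n"], x$dH, x$c_value, x$rss))
  invisible(x)
}
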