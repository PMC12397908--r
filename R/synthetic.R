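# Synthetic data generators: hinge-motion protein pairs, fluorescence
# dilution titrations and ITC injection series. These provide ground-truth
# inputs with the geometric/statistical structure the analyses assume, so
# the whole pipeline is testable without any structure download.

# idealised helix-like CA curve: rise 1.5 A and 100 deg turn per residue
# about a local axis (radius 2.3 A), giving ~3.8 A consecutive CA spacing
helix_curve <- function(n, origin = c(0, 0, 0), axis_start = 0L) {
  i <- axis_start + seq_len(n) - 1L
  t(origin + t(cbind(1.5 * i,
                     2.3 * cos(i * 100 * pi / 180),
                     2.3 * sin(i * 100 * pi / 180))))
}

#' Generate a two-conformation hinge protein
#'
#' Builds an idealised C-alpha chain of `n1 + n2 + tail_len` residues laid
#' out as a helical curve, then creates a second conformation by rigidly
#' rotating the second segment (and tail) by `hinge_angle` about an axis
#' through the hinge C-alpha (residue `n1`), chosen perpendicular both to
#' the local chain direction and to the hinge-to-segment-2-centroid vector
#' so that the constructed rotation equals the measured interdomain angle.
#' An optional C-terminal tail is additionally relocated to a distinct
#' docking site (a second rigid rotation about the segment-2/tail
#' junction), emulating a terminal segment that swaps binding sites
#' between the two states.
#'
#' Conformations producing C-alpha clashes (< 2 A between non-neighbours)
#' are regenerated with small seeded jitter of the rotation axes, at most
#' 10 times.
#'
#' @param n1,n2 residues in the two rigid segments (each >= 10).
#' @param hinge_angle rotation of segment 2 relative to segment 1, degrees
#'   in [0, 180).
#' @param tail_len residues in the relocating C-terminal tail (0 = none).
#' @param seed integer seed for the jitter stream.
#' @return object of class `hinge_pair`: list with `confA`, `confB`
#'   ([ca_trace()]s, identical numbering 1..N), integer `labels`
#'   (1 = segment 1, 2 = segment 2, 3 = tail), `hinge_angle`, `tail`
#'   (residue range or NULL).
#' @export
make_hinge_protein <- function(n1, n2, hinge_angle, tail_len = 0, seed = 1) {
  if (n1 < 10 || n2 < 10) stop("segments need at least 10 residues each")
  if (hinge_angle < 0 || hinge_angle >= 180)
    stop("hinge_angle must be in [0, 180)")
  n <- n1 + n2 + tail_len
  seg1 <- 1:n1
  seg2 <- (n1 + 1):(n1 + n2)
  tail <- if (tail_len > 0) (n1 + n2 + 1):n else integer(0)

  ## conformation A: segment 1 helix along x; segment 2 (and tail) helix
  ## leaving the hinge perpendicular to it (along y), so that rotating
  ## segment 2 away from segment 1 stays clash-free over the whole
  ## [0, 180) range
  xyzA <- matrix(0, n, 3)
  xyzA[seg1, ] <- helix_curve(n1)
  hinge <- xyzA[n1, ]
  i2 <- seq_len(n - n1)
  ## helical phase of the arm (150 deg) keeps hinge-proximal residues of
  ## the two segments apart at every hinge angle in [0, 180)
  ph <- (i2 * 100 + 150) * pi / 180
  arm <- cbind(2.3 * (cos(ph) - cos(150 * pi / 180)),
               1.5 * i2,
               2.3 * (sin(ph) - sin(150 * pi / 180)))
  xyzA[c(seg2, tail), ] <- sweep(arm, 2, hinge, "+")

  build_confB <- function(jitter) {
    xyzB <- xyzA
    if (hinge_angle > 0) {
      v <- unit(colMeans(xyzA[seg2, , drop = FALSE]) - hinge)
      away <- hinge - colMeans(xyzA[seg1, , drop = FALSE])
      # in-plane direction the arm rotates toward: away from segment 1,
      # orthogonalised against v (plus retry jitter)
      w <- unit(away - sum(away * v) * v + jitter)
      w <- unit(w - sum(w * v) * v)
      axis <- cross3(v, w)  # unit, perpendicular to v => exact angle
      R <- rotation_about_axis(axis, hinge_angle)
      idx <- c(seg2, tail)
      xyzB[idx, ] <- sweep(sweep(xyzA[idx, , drop = FALSE], 2, hinge) %*% R,
                           2, hinge, "+")
    }
    if (tail_len > 0) {
      junction <- xyzB[n1 + n2, ]
      tdir <- xyzB[n1 + n2, ] - xyzB[n1 + n2 - 1, ]
      taxis <- unit(cross3(tdir, c(0, 0, 1) + jitter))
      Rt <- rotation_about_axis(taxis, 130)
      xyzB[tail, ] <- sweep(sweep(xyzB[tail, , drop = FALSE], 2, junction) %*% Rt,
                            2, junction, "+")
    }
    xyzB
  }

  xyzB <- with_seed(seed, {
    out <- NULL
    for (attempt in 1:10) {
      jit <- if (attempt == 1) c(0, 0, 0) else stats::rnorm(3, 0, 0.05)
      cand <- build_confB(jit)
      dm <- as.matrix(stats::dist(cand))
      dm[abs(row(dm) - col(dm)) <= 1] <- Inf
      if (min(dm) >= 2.0) { out <- cand; break }
    }
    if (is.null(out))
      stop("could not generate a clash-free conformation in 10 attempts")
    out
  })

  labels <- c(rep(1L, n1), rep(2L, n2), rep(3L, tail_len))
  structure(list(confA = ca_trace("A", 1:n, xyzA),
                 confB = ca_trace("A", 1:n, xyzB),
                 labels = labels, hinge_angle = hinge_angle,
                 tail = if (tail_len > 0) range(tail) else NULL),
            class = "hinge_pair")
}

# 3-vector cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.hinge_pair <- function(x, ...) {
  cat(sprintf("hinge_pair: %d residues, hinge angle %.1f deg%s\n",
              length(x$labels), x$hinge_angle,
              if (!is.null(x$tail)) sprintf(", relocating tail %d-%d",
                                            x$tail[1], x$tail[2]) else ""))
  invisible(x)
}

#' Construct a titration curve
#'
#' Container for a fluorescence dilution titration: signal measured at a
#' series of (varied) protein concentrations with the fluorophore held at
#' a fixed total concentration.
#'
#' @param P_total protein concentrations, uM.
#' @param signal measured signal, arbitrary units.
#' @param L_total fixed fluorophore (ligand) concentration, uM.
#' @param replicate replicate identifier.
#' @export
titration_curve <- function(P_total, signal, L_total, replicate = 1L) {
  if (length(P_total) != length(signal)) stop("length mismatch")
  if (any(P_total <= 0) || L_total <= 0) stop("concentrations must be > 0")
  structure(list(P_total = as.numeric(P_total), signal = as.numeric(signal),
                 L_total = as.numeric(L_total), replicate = replicate),
            class = "titration_curve")
}

#' Simulate a fluorescence dilution titration
#'
#' Signals follow the quadratic (ligand-depletion) binding model
#' ([quadratic_signal()]) with i.i.d. Gaussian noise. With `sigma = 0` the
#' curve is exactly on-model. The default noise, used by demo fixtures, is
#' 1 percent of the signal range.
#'
#' @param Kd dissociation constant, uM.
#' @param L_total fixed fluorophore concentration, uM.
#' @param P_series protein concentration series, uM.
#' @param F_free,F_bound signal of free and fully bound fluorophore (a.u.).
#'   Defaults mimic fluorescence quenching on binding.
#' @param sigma Gaussian noise s.d. (a.u.); `NULL` = 1 percent of range.
#' @param seed integer seed.
#' @return a [titration_curve()].
#' @export
simulate_titration <- function(Kd, L_total, P_series, F_free = 1000,
                               F_bound = 250, sigma = NULL, seed = 1) {
  if (any(P_series <= 0) || L_total <= 0 || Kd <= 0)
    stop("concentrations and Kd must be > 0")
  if (is.null(sigma)) sigma <- 0.01 * abs(F_bound - F_free)
  if (sigma < 0) stop("sigma must be >= 0")
  y <- quadratic_signal(P_series, L_total, Kd, F_free, F_bound)
  if (sigma > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, sigma))
  titration_curve(P_series, y, L_total)
}

#' Construct an ITC experiment
#'
#' @param heats per-injection heats, ucal.
#' @param cell_conc initial cell (macromolecule) concentration, uM.
#' @param syringe_conc syringe (titrant) concentration, uM.
#' @param injections injection volumes, ul.
#' @param V0 calorimeter cell volume, ul.
#' @export
itc_experiment <- function(heats, cell_conc, syringe_conc, injections,
                           V0 = 200) {
  if (length(heats) != length(injections)) stop("length mismatch")
  if (cell_conc <= 0 || syringe_conc <= 0 || V0 <= 0 || any(injections <= 0))
    stop("concentrations and volumes must be > 0")
  structure(list(heats = as.numeric(heats), cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injections = as.numeric(injections), V0 = V0),
            class = "itc_experiment")
}

#' Simulate an ITC injection series
#'
#' Per-injection heats from the one-set-of-sites isotherm ([itc_heats()])
#' with i.i.d. Gaussian noise (default for demo fixtures: 2 percent of the
#' largest absolute heat). The default injection schedule (18 x 2 ul into
#' a 200 ul cell, 70 uM cell / 700 uM syringe) is a standard small-cell
#' titration layout.
#'
#' @param Kd dissociation constant, uM.
#' @param n stoichiometry (sites per macromolecule).
#' @param dH binding enthalpy, kcal/mol.
#' @param cell_conc,syringe_conc,injections,V0 experiment geometry (uM, ul).
#' @param sigma noise s.d., ucal; `NULL` = 2 percent of max |heat|.
#' @param seed integer seed.
#' @return an [itc_experiment()].
#' @export
simulate_itc <- function(Kd, n, dH, cell_conc = 70, syringe_conc = 700,
                         injections = rep(2, 18), V0 = 200, sigma = NULL,
                         seed = 1) {
  q <- itc_heats(Kd, n, dH, cell_conc, syringe_conc, injections, V0)
  if (is.null(sigma)) sigma <- 0.02 * max(abs(q), 1e-12)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma > 0)
    q <- q + with_seed(seed, stats::rnorm(length(q), 0, sigma))
  itc_experiment(q, cell_conc, syringe_conc, injections, V0)
}
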