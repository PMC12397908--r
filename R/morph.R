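# Iterative dual-endpoint biased morphing between two conformations on a
# C-alpha elastic-network backend, plus dual-reference RMSD trajectory
# analysis.
#
# Protocol per iteration: (1) superpose the two current endpoint
# structures and compute the vector between each pair of corresponding
# C-alpha atoms; (2) place a harmonic bias center for every residue at its
# own position advanced a fraction of the way along that vector toward the
# other endpoint; (3) relax both endpoints under their elastic network
# plus the bias by overdamped Langevin dynamics (steepest descent at
# temperature 0); (4) recompute the endpoint-to-endpoint RMSD. Iterate
# until the RMSD drops below the tolerance or the iteration budget is
# spent. Running the bias from BOTH endpoints simultaneously lets the two
# trajectories meet in the middle instead of forcing one conformation
# through the other's strain field.

#' Build a C-alpha elastic network
#'
#' Harmonic springs between all C-alpha pairs within `cutoff`, at their
#' separations in the input conformation (so the input is the energy
#' minimum).
#'
#' @param trace a [ca_trace()].
#' @param cutoff spring cutoff, Angstrom (> 3.8 so that at least the chain
#'   is connected).
#' @param k spring constant, reduced energy/A^2.
#' @return object of class `enm_system`: `xyz`, `resno`, integer pair
#'   matrix `pairs`, rest lengths `r0`, `k`, `cutoff`.
#' @export
build_enm <- function(trace, cutoff = 10, k = 1) {
  stopifnot(inherits(trace, "ca_trace"))
  if (cutoff <= 3.8) stop("cutoff must exceed the 3.8 A chain spacing")
  d <- as.matrix(stats::dist(trace$xyz))
  sel <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("no springs within cutoff")
  deg <- tabulate(c(sel[, 1], sel[, 2]), nbins = nrow(trace$xyz))
  if (any(deg == 0))
    stop("disconnected network: residue(s) with no spring: ",
         paste(utils::head(trace$resno[deg == 0], 5), collapse = ", "))
  structure(list(xyz = trace$xyz, resno = trace$resno,
                 pairs = unname(sel), r0 = d[sel], k = k, cutoff = cutoff),
            class = "enm_system")
}

#' Elastic network energy
#' @param system an `enm_system`.
#' @param xyz coordinates to evaluate (default: the system's own).
#' @return scalar energy, reduced units.
#' @export
enm_energy <- function(system, xyz = system$xyz) {
  dv <- xyz[system$pairs[, 1], , drop = FALSE] -
    xyz[system$pairs[, 2], , drop = FALSE]
  len <- sqrt(rowSums(dv^2))
  0.5 * system$k * sum((len - system$r0)^2)
}

# gradient of ENM + bias energy at xyz; bias E = 0.5 k_bias sum |x - c|^2
enm_bias_gradient <- function(system, xyz, centers = NULL, k_bias = 0) {
  n <- nrow(xyz)
  i <- system$pairs[, 1]; j <- system$pairs[, 2]
  dv <- xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE]
  len <- sqrt(rowSums(dv^2))
  coef <- system$k * (len - system$r0) / pmax(len, 1e-12)
  contrib <- dv * coef
  g <- matrix(0, n, 3)
  for (col in 1:3) {
    g[, col] <- g[, col] +
      unname(tapply(c(contrib[, col], -contrib[, col]), c(i, j), sum)[
        as.character(seq_len(n))])
  }
  g[is.na(g)] <- 0
  if (!is.null(centers) && k_bias > 0) g <- g + k_bias * (xyz - centers)
  g
}

#' Relax an elastic network under a harmonic bias
#'
#' Overdamped Langevin dynamics: `x <- x - h * grad(E) + sqrt(2 T h) * xi`
#' with `E` the elastic-network plus bias energy. At `temperature = 0`
#' this is steepest descent; a sustained energy increase (more than 5
#' consecutive uphill steps) then aborts with advice to reduce the step.
#' The default step size is chosen from the stability bound of the
#' stiffest mode, `1 / (k * max_coordination + k_bias)`.
#'
#' @param system an `enm_system`.
#' @param centers N x 3 bias centers, or `NULL` for unbiased dynamics.
#' @param k_bias bias spring constant, reduced energy/A^2.
#' @param n_steps number of integration steps.
#' @param temperature reduced temperature (0 = deterministic descent).
#' @param seed integer seed for the thermal noise (ignored at T = 0).
#' @param step_size integration step; `NULL` = automatic.
#' @param start starting coordinates (default: the system's own).
#' @return relaxed N x 3 coordinate matrix.
#' @export
relax_step <- function(system, centers = NULL, k_bias = 0, n_steps = 200,
                       temperature = 0, seed = NULL, step_size = NULL,
                       start = NULL) {
  xyz <- if (is.null(start)) system$xyz else as.matrix(start)
  n <- nrow(xyz)
  if (is.null(step_size)) {
    maxdeg <- max(tabulate(c(system$pairs[, 1], system$pairs[, 2]), n))
    step_size <- 1 / (system$k * maxdeg + k_bias)
  }
  run <- function() {
    uphill <- 0
    e_prev <- if (temperature == 0)
      enm_energy(system, xyz) + bias_energy(xyz, centers, k_bias) else NA
    for (s in seq_len(n_steps)) {
      g <- enm_bias_gradient(system, xyz, centers, k_bias)
      xyz <- xyz - step_size * g
      if (temperature > 0)
        xyz <- xyz + sqrt(2 * temperature * step_size) *
          matrix(stats::rnorm(3 * n), n, 3)
      if (temperature == 0) {
        e <- enm_energy(system, xyz) + bias_energy(xyz, centers, k_bias)
        uphill <- if (e > e_prev + 1e-12) uphill + 1 else 0
        if (uphill > 5)
          stop("energy increased for >5 consecutive descent steps; ",
               "reduce step_size")
        e_prev <- e
      }
    }
    xyz
  }
  if (temperature > 0 && !is.null(seed)) with_seed(seed, run()) else run()
}

bias_energy <- function(xyz, centers, k_bias) {
  if (is.null(centers) || k_bias == 0) return(0)
  0.5 * k_bias * sum((xyz - centers)^2)
}

#' Per-residue bias vectors toward a target conformation
#'
#' Superposes the target onto the current structure (Kabsch over shared
#' residues) and returns, for each shared residue, the vector from the
#' current C-alpha to the superposed target C-alpha. Any rigid-body
#' component of the difference is removed by the superposition, so the
#' vectors measure internal deformation only.
#'
#' @param current,target `ca_trace` objects.
#' @return N x 3 matrix of vectors (rows follow `current`'s shared
#'   residues, in `current` order), with attribute `"resno"`.
#' @export
compute_bias_vectors <- function(current, target) {
  s <- shared_residues(current, target)
  if (length(s$resno) < 3) stop("fewer than 3 shared residues")
  sup <- kabsch(target$xyz[s$ib, , drop = FALSE],
                current$xyz[s$ia, , drop = FALSE])
  tsup <- apply_superposition(target$xyz[s$ib, , drop = FALSE], sup)
  v <- tsup - current$xyz[s$ia, , drop = FALSE]
  attr(v, "resno") <- s$resno
  v
}

#' Iterative dual-endpoint biased morph
#'
#' Finds a transition pathway between two conformations of one chain by
#' iterating bias-vector computation, bias-center advancement and
#' elastic-network relaxation from both endpoints until they meet (RMSD
#' below `tol`) or `max_iter` is reached. Non-convergence is reported in
#' the result, not raised.
#'
#' @param endA,endB `ca_trace` endpoint conformations (shared residues
#'   are used; each endpoint keeps its own network topology built from its
#'   starting structure).
#' @param cutoff,k_enm elastic network parameters ([build_enm()]).
#' @param k_bias harmonic bias spring constant.
#' @param advance fraction of each bias vector by which centers are
#'   advanced per iteration, in (0, 1].
#' @param steps_per_iter relaxation steps per iteration.
#' @param tol convergence tolerance on the endpoint C-alpha RMSD, Angstrom.
#' @param max_iter iteration budget.
#' @param temperature reduced temperature of the relaxation dynamics
#'   (default 0: deterministic).
#' @param seed master seed; one stream per endpoint is derived from it.
#' @param step_size relaxation step; `NULL` = automatic.
#' @return object of class `morph_result`: `traj_a`, `traj_b` (lists of
#'   `ca_trace` snapshots, element 1 = the input endpoints), `rmsd`
#'   (endpoint RMSD after each iteration, element 1 = initial), `converged`,
#'   `iterations`.
#' @export
biased_morph <- function(endA, endB, cutoff = 10, k_enm = 1, k_bias = 5,
                         advance = 0.1, steps_per_iter = 200, tol = 1.2,
                         max_iter = 100, temperature = 0, seed = 1,
                         step_size = NULL) {
  if (advance <= 0 || advance > 1) stop("advance must be in (0, 1]")
  s <- shared_residues(endA, endB)
  a <- ca_trace(endA$chain, s$resno, endA$xyz[s$ia, , drop = FALSE],
                resid = endA$resid[s$ia])
  b <- ca_trace(endB$chain, s$resno, endB$xyz[s$ib, , drop = FALSE],
                resid = endB$resid[s$ib])
  sysA <- build_enm(a, cutoff, k_enm)
  sysB <- build_enm(b, cutoff, k_enm)
  snap <- function(tmpl, xyz) ca_trace(tmpl$chain, tmpl$resno, xyz,
                                       resid = tmpl$resid)
  traj_a <- list(a); traj_b <- list(b)
  rmsd <- kabsch(b$xyz, a$xyz)$rmsd
  it <- 0L
  while (rmsd[length(rmsd)] >= tol && it < max_iter) {
    it <- it + 1L
    va <- compute_bias_vectors(a, b)
    vb <- compute_bias_vectors(b, a)
    xa <- relax_step(sysA, centers = a$xyz + advance * va, k_bias = k_bias,
                     n_steps = steps_per_iter, temperature = temperature,
                     seed = if (temperature > 0) seed * 1000L + 2L * it else NULL,
                     step_size = step_size, start = a$xyz)
    xb <- relax_step(sysB, centers = b$xyz + advance * vb, k_bias = k_bias,
                     n_steps = steps_per_iter, temperature = temperature,
                     seed = if (temperature > 0) seed * 1000L + 2L * it + 1L else NULL,
                     step_size = step_size, start = b$xyz)
    a <- snap(a, xa); b <- snap(b, xb)
    traj_a[[it + 1L]] <- a; traj_b[[it + 1L]] <- b
    rmsd <- c(rmsd, kabsch(b$xyz, a$xyz)$rmsd)
  }
  structure(list(traj_a = traj_a, traj_b = traj_b, rmsd = rmsd,
                 converged = rmsd[length(rmsd)] < tol, iterations = it),
            class = "morph_result")
}

#' @export
print.morph_result <- function(x, ...) {
  cat(sprintf("morph_result: %s after %d iteration(s); endpoint RMSD %.3f A (initial %.3f A)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$rmsd[length(x$rmsd)], x$rmsd[1]))
  invisible(x)
}

#' RMSD of a trajectory against two reference conformations
#'
#' The standard diagnostic for transition trajectories: per-frame
#' Kabsch-minimised RMSD to the starting-state reference and to the
#' end-state reference.
#'
#' @param trajectory list of `ca_trace` frames.
#' @param refA,refB reference conformations.
#' @return data.frame with columns `frame`, `rmsd_a`, `rmsd_b`.
#' @export
dual_reference_rmsd <- function(trajectory, refA, refB) {
  ra <- vapply(trajectory, rmsd_after_superposition, numeric(1), b = refA)
  rb <- vapply(trajectory, rmsd_after_superposition, numeric(1), b = refB)
  data.frame(frame = seq_along(trajectory), rmsd_a = ra, rmsd_b = rb)
}
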