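# Solvent-accessible surface area (Shrake-Rupley sphere sampling), buried
# interface area between two chain groups, and contact enumeration.

# element-keyed van der Waals radii (Angstrom); protein/cofactor elements
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               MG = 1.73, NA. = 2.27, K = 2.75, CA = 2.31, MN = 1.80,
               FE = 1.80, ZN = 1.39, SE = 1.90)

atom_radii <- function(elements, default_radius = NULL) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  r <- VDW_RADII[key]
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("no van der Waals radius for element(s): ",
           paste(unique(elements[is.na(r)]), collapse = ", "),
           "; supply default_radius to use a fallback")
    r[is.na(r)] <- default_radius
  }
  unname(r)
}

# quasi-uniform points on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by sampling
#' `n_points` quasi-uniform points on each atom's probe-expanded sphere
#' and counting the fraction not buried inside any neighbour's expanded
#' sphere. Heteroatoms present in the model (cofactors, nucleotides) are
#' included like any other atom.
#'
#' @param model a `structure_model`.
#' @param probe probe radius, Angstrom (water: 1.4).
#' @param n_points sphere sample points per atom (default 960; accuracy
#'   improves roughly with 1/n_points).
#' @param default_radius fallback van der Waals radius for elements not in
#'   the built-in table; `NULL` (default) raises an error instead.
#' @return object of class `sasa_result`: per-atom `areas` (A^2), `total`,
#'   `probe`, `n_points`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960, default_radius = NULL) {
  stopifnot(inherits(model, "structure_model"))
  n <- nrow(model)
  if (n == 0)
    return(structure(list(areas = numeric(0), total = 0, probe = probe,
                          n_points = n_points), class = "sasa_result"))
  xyz <- as.matrix(model[, c("x", "y", "z")])
  R <- atom_radii(model$elesy, default_radius) + probe
  sp <- sphere_points(n_points)
  areas <- numeric(n)
  maxR <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * R[i]^2
      next
    }
    pts <- sweep(sp * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      buried <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2) <
        R[j]^2
      free[free] <- !buried
    }
    areas[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  structure(list(areas = areas, total = sum(areas), probe = probe,
                 n_points = n_points), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$areas), x$probe, x$n_points))
  invisible(x)
}

subset_chains <- function(model, chains) {
  out <- model[model$chain %in% chains, , drop = FALSE]
  class(out) <- class(model)
  out
}

#' Buried interface area between two chain groups
#'
#' Three SASA evaluations -- each group in isolation and the complex --
#' combined as `buried_total = SASA(g1) + SASA(g2) - SASA(complex)`.
#' Both reporting conventions are returned: the total buried area and the
#' halved value (`interface_area`), which is the convention used by
#' interface-analysis servers such as PISA. Contacts at or below
#' `contact_cutoff` are enumerated via [contact_list()].
#'
#' @param model a `structure_model`.
#' @param group1,group2 disjoint, non-empty chain-id sets.
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @param contact_cutoff Angstrom for the contact enumeration.
#' @param default_radius see [sasa()].
#' @return object of class `interface_report`: `buried_total`,
#'   `interface_area` (= buried_total / 2), `sasa1`, `sasa2`,
#'   `sasa_complex` (totals), `contacts` (data.frame).
#' @export
buried_area <- function(model, group1, group2, probe = 1.4, n_points = 960,
                        contact_cutoff = 4.0, default_radius = NULL) {
  if (length(intersect(group1, group2)) > 0)
    stop("chain groups overlap")
  m1 <- subset_chains(model, group1)
  m2 <- subset_chains(model, group2)
  if (nrow(m1) == 0 || nrow(m2) == 0) stop("a chain group is empty")
  m12 <- subset_chains(model, c(group1, group2))
  s1 <- sasa(m1, probe, n_points, default_radius)
  s2 <- sasa(m2, probe, n_points, default_radius)
  s12 <- sasa(m12, probe, n_points, default_radius)
  buried <- max(s1$total + s2$total - s12$total, 0)
  structure(list(buried_total = buried, interface_area = buried / 2,
                 sasa1 = s1$total, sasa2 = s2$total,
                 sasa_complex = s12$total,
                 contacts = contact_list(model, group1, group2,
                                         contact_cutoff)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: buried total %.1f A^2, interface area (buried/2) %.1f A^2, %d contact pair(s) listed\n",
              x$buried_total, x$interface_area, nrow(x$contacts)))
  invisible(x)
}

#' Inter-group atomic contacts
#'
#' All atom pairs with one atom in each chain group and distance at or
#' below `cutoff`, sorted by distance.
#'
#' @param model a `structure_model`.
#' @param group1,group2 chain-id sets.
#' @param cutoff Angstrom.
#' @return data.frame with atom descriptors of both partners and `distance`.
#' @export
contact_list <- function(model, group1, group2, cutoff = 4.0) {
  m1 <- subset_chains(model, group1)
  m2 <- subset_chains(model, group2)
  empty <- data.frame(chain1 = character(0), resno1 = integer(0),
                      resid1 = character(0), atom1 = character(0),
                      chain2 = character(0), resno2 = integer(0),
                      resid2 = character(0), atom2 = character(0),
                      distance = numeric(0))
  if (nrow(m1) == 0 || nrow(m2) == 0) return(empty)
  x1 <- as.matrix(m1[, c("x", "y", "z")])
  x2 <- as.matrix(m2[, c("x", "y", "z")])
  d2 <- outer(rowSums(x1^2), rep(1, nrow(x2))) +
    outer(rep(1, nrow(x1)), rowSums(x2^2)) - 2 * x1 %*% t(x2)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(
    chain1 = m1$chain[hit[, 1]], resno1 = m1$resno[hit[, 1]],
    resid1 = m1$resid[hit[, 1]], atom1 = m1$elety[hit[, 1]],
    chain2 = m2$chain[hit[, 2]], resno2 = m2$resno[hit[, 2]],
    resid2 = m2$resid[hit[, 2]], atom2 = m2$elety[hit[, 2]],
    distance = sqrt(pmax(d2[hit], 0)))
  out[order(out$distance), , drop = FALSE]
}
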