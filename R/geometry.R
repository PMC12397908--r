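# Superposition, RMSD, interdomain rotation angle, atom-pair distances.

#' Least-squares superposition (Kabsch)
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference` in the least-squares sense, computed by singular value
#' decomposition of the covariance matrix with the standard determinant
#' correction (sign flip of the smallest singular vector) to exclude
#' reflections.
#'
#' @param mobile N x 3 coordinate matrix.
#' @param reference N x 3 coordinate matrix, same N.
#' @param weights optional non-negative per-point weights.
#' @return object of class `superposition`: list with `rotation` (3x3,
#'   acting on row vectors as `x %*% rotation`), `translation` (length 3)
#'   and `rmsd` (Angstrom). `apply_superposition()` applies it.
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("coordinate sets differ in length")
  if (n < 3) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm); R <- sweep(reference, 2, cr)
  sv_m <- svd(M)$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1))
    stop("degenerate (collinear) point set; rotation is not determined")
  H <- crossprod(M * w, R)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- M %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - R)^2)))
  structure(list(rotation = rot, translation = cr - as.vector(cm %*% rot),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param coords N x 3 matrix.
#' @param sup a `superposition` from [kabsch()].
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, "+")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A, det(R) = %+.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

# shared-residue index pairs between two traces, by author residue number
shared_residues <- function(a, b, residues = NULL) {
  common <- intersect(a$resno, b$resno)
  if (!is.null(residues)) common <- intersect(common, residues)
  if (length(common) == 0) stop("traces share no residues in the selection")
  list(ia = match(common, a$resno), ib = match(common, b$resno),
       resno = common)
}

#' Minimized C-alpha RMSD between two conformations
#'
#' Residue correspondence is by author residue number; mismatched residue
#' sets use the intersection.
#'
#' @param a,b `ca_trace` objects.
#' @param residues optional residue numbers restricting the superposition.
#' @return RMSD in Angstrom after Kabsch superposition over the selection.
#' @export
rmsd_after_superposition <- function(a, b, residues = NULL) {
  s <- shared_residues(a, b, residues)
  if (length(s$resno) < 3) stop("fewer than 3 shared residues")
  kabsch(b$xyz[s$ib, , drop = FALSE], a$xyz[s$ia, , drop = FALSE])$rmsd
}

#' Interdomain rotation angle between two conformations
#'
#' Superposes conformation B onto conformation A over an anchor domain and
#' reports the angle subtended at a fixed vertex residue (taken from the
#' anchored conformation A) by the tip residue of A and the tip residue of
#' the superposed B. This is the classic three-point measure of how far a
#' mobile domain has rotated relative to an anchor domain.
#'
#' @param confA,confB `ca_trace` objects of the same chain in two states.
#' @param anchor integer residue numbers of the anchor (fixed) domain.
#' @param vertex_res residue number of the vertex C-alpha (on the anchor).
#' @param tip_res residue number of the tip C-alpha (on the mobile domain).
#' @return angle in degrees, in [0, 180].
#' @export
interdomain_angle <- function(confA, confB, anchor, vertex_res, tip_res) {
  s <- shared_residues(confA, confB, anchor)
  if (length(s$resno) < 3) stop("anchor shares fewer than 3 residues")
  sup <- kabsch(confB$xyz[s$ib, , drop = FALSE], confA$xyz[s$ia, , drop = FALSE])
  bsup <- apply_superposition(confB$xyz, sup)
  iv <- match(vertex_res, confA$resno)
  ita <- match(tip_res, confA$resno)
  itb <- match(tip_res, confB$resno)
  if (anyNA(c(iv, ita, itb)))
    stop("vertex or tip residue missing from a conformation")
  v1 <- confA$xyz[ita, ] - confA$xyz[iv, ]
  v2 <- bsup[itb, ] - confA$xyz[iv, ]
  if (vnorm(v1) < 1e-6 || vnorm(v2) < 1e-6)
    stop("vertex coincides with a tip residue")
  vec_angle(v1, v2)
}

#' Distance between two selected atoms
#'
#' @param model a `structure_model`.
#' @param sel1,sel2 [atom_selector()] objects.
#' @return Euclidean distance in Angstrom.
#' @export
atom_pair_distance <- function(model, sel1, sel2) {
  vnorm(resolve_atom(model, sel1) - resolve_atom(model, sel2))
}
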