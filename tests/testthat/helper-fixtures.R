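# Shared fixtures and independent oracles, all built in code.

# structure_model holding only the CA atoms of a trace
trace_to_model <- function(trace, chain = trace$chain) {
  structure_model(data.frame(
    chain = chain, resno = trace$resno, resid = trace$resid,
    elety = "CA", x = trace$xyz[, 1], y = trace$xyz[, 2],
    z = trace$xyz[, 3], elesy = "C", stringsAsFactors = FALSE))
}

# independent superposition oracle: Horn's quaternion eigenvalue method
quaternion_rmsd <- function(mobile, reference) {
  A <- scale(mobile, scale = FALSE)
  B <- scale(reference, scale = FALSE)
  M <- t(A) %*% B
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  sqrt(max(0, sum(A^2) + sum(B^2) - 2 * lam) / nrow(A))
}

# random compact point cloud
random_cloud <- function(n, seed) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 5), n, 3)
}

random_rigid_transform <- function(coords, seed) {
  set.seed(seed)
  ax <- rnorm(3)
  R <- hingeforge:::rotation_about_axis(ax, runif(1, 10, 170))
  sweep(coords %*% R, 2, rnorm(3, sd = 20), "+")
}

# minimal mmCIF text for two CA atoms
minimal_cif_lines <- function() {
  c("data_synthetic", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 4.500 2.000 3.000 1.00 10.00 ? 2 GLY A CA 1")
}

# protein-like fixture: two short CA chains facing each other, plus a
# cofactor-style heteroatom group in one chain
two_chain_model <- function(gap = 5) {
  a <- helix_pts(12, origin = c(0, 0, 0))
  b <- helix_pts(12, origin = c(0, gap, 0))
  structure_model(data.frame(
    chain = rep(c("A", "B"), each = 12),
    resno = rep(1:12, 2), resid = "ALA", elety = "CA",
    x = c(a[, 1], b[, 1]), y = c(a[, 2], b[, 2]), z = c(a[, 3], b[, 3]),
    elesy = "C", het = FALSE, stringsAsFactors = FALSE))
}

helix_pts <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  t(origin + t(cbind(1.5 * i, 2.3 * cos(i * 100 * pi / 180),
                     2.3 * sin(i * 100 * pi / 180))))
}
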