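# Structure input/output and atom selection.
#
# A structure_model is a plain data.frame of atom records (one row per atom)
# with class c("structure_model", "data.frame") and columns:
#   chain, resno, insert, resid, elety (atom name), elesy (element),
#   x, y, z, o (occupancy), alt (alternate location), het (logical).
# Residue numbering is the author (1-based) numbering of the source file.

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "TIP3")

#' Construct a structure model from atom records
#'
#' Low-level constructor used by [read_structure()] and by tests to build
#' fixtures in code. Applies the single-conformer policy (keep the
#' highest-occupancy altloc; ties broken alphabetically) and validates the
#' record set.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z` and optionally `insert`, `elesy`, `o`, `alt`, `het`.
#' @param drop_waters drop water residues (default `TRUE`).
#' @return a `structure_model`.
#' @export
structure_model <- function(atoms, drop_waters = TRUE) {
  req <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$insert)) atoms$insert <- rep("", nrow(atoms))
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$alt)) atoms$alt <- rep("", nrow(atoms))
  atoms$alt[is.na(atoms$alt)] <- ""
  if (is.null(atoms$o)) atoms$o <- rep(1, nrow(atoms))
  atoms$o[is.na(atoms$o)] <- 1
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  atoms$elesy[is.na(atoms$elesy) | atoms$elesy == ""] <-
    guess_element(atoms$elety[is.na(atoms$elesy) | atoms$elesy == ""])
  if (is.null(atoms$het)) atoms$het <- rep(FALSE, nrow(atoms))
  atoms$resno <- as.integer(atoms$resno)

  if (drop_waters) atoms <- atoms[!(atoms$resid %in% WATER_RESIDUES), , drop = FALSE]

  ## single-conformer policy: highest occupancy altloc, ties alphabetical
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                     atoms$elety, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  model <- structure(atoms, class = c("structure_model", "data.frame"))
  validate_structure(model)
  model
}

guess_element <- function(elety) {
  e <- toupper(sub("^[0-9']*", "", elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"), two, one)
}

validate_structure <- function(model) {
  coords <- as.matrix(model[, c("x", "y", "z")])
  if (nrow(model) > 0 && !all(is.finite(coords)))
    stop("structure contains non-finite coordinates")
  key <- paste(model$chain, model$resno, model$insert, model$elety, model$alt,
               sep = "|")
  if (anyDuplicated(key))
    stop("duplicated atom record(s): ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  invisible(model)
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a flat atom table. Heteroatoms (cofactors,
#' nucleotides such as FAD or GppNHp) are retained; waters are dropped by
#' default. Where alternate locations are present only the highest-occupancy
#' conformer is kept so that downstream geometry is single-valued.
#'
#' @param path file path.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param drop_waters logical, default `TRUE`.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           drop_waters = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "cif", mmcif = "cif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  structure_model(data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elesy = if (!is.null(a$elesy)) a$elesy else NA_character_,
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    het = a$type == "HETATM",
    stringsAsFactors = FALSE), drop_waters = drop_waters)
}

#' Write a structure model as a PDB file
#'
#' Fixed-column PDB output (coordinates to 3 decimals). Coordinates outside
#' the representable field range of the format (|x| > 9999.999) raise an
#' error rather than producing a corrupt file.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(model) > 0) {
    coords <- as.matrix(model[, c("x", "y", "z")])
    if (any(abs(coords) > 9999.999))
      stop("coordinate exceeds the PDB fixed-width field range (|x| > 9999.999)")
    rec <- ifelse(model$het, "HETATM", "ATOM  ")
    name <- ifelse(nchar(model$elety) < 4,
                   sprintf(" %-3s", model$elety),
                   sprintf("%-4s", model$elety))
    lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(model)) %% 100000, name,
                     substr(model$alt, 1, 1), model$resid,
                     substr(model$chain, 1, 1), model$resno %% 10000,
                     substr(model$insert, 1, 1),
                     model$x, model$y, model$z, model$o, 0,
                     substr(model$elesy, 1, 2))
    writeLines(lines, con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- unique(x$chain)
  cat("structure_model:", nrow(x), "atoms,", length(ch), "chain(s)\n")
  for (c1 in ch) {
    sub <- x[x$chain == c1, ]
    het <- unique(sub$resid[sub$het])
    cat(sprintf("  chain %s: residues %d..%d%s\n", c1,
                min(sub$resno), max(sub$resno),
                if (length(het)) paste0(" [het: ", paste(het, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

#' Construct a C-alpha trace
#'
#' @param chain chain identifier.
#' @param resno integer residue numbers.
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param resid residue names (recycled if length 1).
#' @param insert insertion codes (default none).
#' @return object of class `ca_trace`.
#' @export
ca_trace <- function(chain, resno, xyz, resid = "ALA", insert = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (n < 2) stop("a ca_trace needs at least 2 residues")
  if (length(resno) != n) stop("resno/xyz length mismatch")
  resid <- rep_len(resid, n)
  insert <- rep_len(insert, n)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  breaks <- any(d < 2.5 | d > 4.5)
  structure(list(chain = chain, resno = as.integer(resno), resid = resid,
                 insert = insert, xyz = xyz, has_breaks = breaks),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace: chain %s, %d residues (%d..%d)%s\n", x$chain,
              nrow(x$xyz), min(x$resno), max(x$resno),
              if (x$has_breaks) ", contains chain break(s)" else ""))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) nrow(x$xyz)

#' Extract the C-alpha trace of one chain
#'
#' One CA per residue, ordered by author residue number (insertion codes
#' preserve author order within a residue number). Residues lacking a CA
#' atom are skipped with a warning; heteroatom "CA" records (e.g. calcium)
#' are never picked up.
#'
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param residues optional integer vector restricting the residue numbers.
#' @return a [ca_trace()].
#' @export
extract_ca_trace <- function(model, chain, residues = NULL) {
  sub <- model[model$chain == chain & !model$het, , drop = FALSE]
  if (nrow(sub) == 0) stop("no polymer atoms in chain '", chain, "'")
  if (!is.null(residues)) sub <- sub[sub$resno %in% residues, , drop = FALSE]
  ca <- sub[sub$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("selection contains no CA atoms")
  all_res <- unique(paste(sub$resno, sub$insert, sep = "|"))
  got_res <- paste(ca$resno, ca$insert, sep = "|")
  missing <- setdiff(all_res, got_res)
  if (length(missing) > 0)
    warning(length(missing), " residue(s) lack a CA atom and were skipped: ",
            paste(utils::head(sub("\\|$", "", missing), 5), collapse = ", "))
  ca <- ca[order(ca$resno, ca$insert), , drop = FALSE]
  if (nrow(ca) < 2) stop("fewer than 2 CA atoms in selection")
  ca_trace(chain, ca$resno, as.matrix(ca[, c("x", "y", "z")]),
           resid = ca$resid, insert = ca$insert)
}

#' Atom selector
#'
#' Identifies exactly one atom in a model: by chain, atom name and either a
#' residue number or a residue-name filter (e.g. `resid = "FAD"` to select
#' the N5 of the single FAD copy in a chain).
#'
#' @param chain chain id.
#' @param atom atom name (PDB atom-name column, e.g. `"NZ"`, `"SG"`, `"N5"`).
#' @param resno residue number (optional when `resid` pins the residue).
#' @param resid residue-name filter, optional.
#' @return object of class `atom_selector`.
#' @export
atom_selector <- function(chain, atom, resno = NULL, resid = NULL) {
  if (is.null(resno) && is.null(resid))
    stop("atom_selector needs a residue number or a residue-name filter")
  structure(list(chain = chain, atom = atom,
                 resno = if (!is.null(resno)) as.integer(resno) else NULL,
                 resid = resid),
            class = "atom_selector")
}

#' Resolve an atom selector to coordinates
#'
#' @param model a `structure_model`.
#' @param sel an [atom_selector()].
#' @return numeric length-3 coordinate vector (Angstrom).
#' @export
resolve_atom <- function(model, sel) {
  stopifnot(inherits(sel, "atom_selector"))
  hit <- model$chain == sel$chain & model$elety == sel$atom
  if (!is.null(sel$resno)) hit <- hit & model$resno == sel$resno
  if (!is.null(sel$resid)) hit <- hit & model$resid == sel$resid
  m <- model[hit, , drop = FALSE]
  if (nrow(m) == 0)
    stop("selector matches no atom (chain ", sel$chain, ", atom ", sel$atom,
         if (!is.null(sel$resno)) paste0(", residue ", sel$resno) else "",
         if (!is.null(sel$resid)) paste0(", resid ", sel$resid) else "", ")")
  if (nrow(m) > 1)
    stop("selector is ambiguous; candidates: ",
         paste(sprintf("%s/%s%d%s/%s[%s]", m$resid, m$chain, m$resno,
                       m$insert, m$elety, m$alt), collapse = ", "))
  c(m$x, m$y, m$z)
}
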