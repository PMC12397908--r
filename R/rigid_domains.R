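# Alignment-independent conformational comparison: C-alpha distance
# matrices, difference matrices and rigid-domain segmentation.
#
# The idea: intra-molecular distance matrices describe a conformation in
# internal coordinates, so two conformations can be compared without any
# superposition. Residues that belong to one rigid body keep all their
# mutual distances, giving near-zero blocks in the absolute difference
# matrix; entries between residues of different rigid bodies change with
# the hinge motion.

#' Pairwise C-alpha distance matrix
#'
#' @param trace a [ca_trace()].
#' @return object of class `distance_matrix`: list with `resno` and the
#'   symmetric N x N `values` matrix (Angstrom).
#' @export
ca_distance_matrix <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  v <- as.matrix(stats::dist(trace$xyz))
  dimnames(v) <- list(trace$resno, trace$resno)
  structure(list(resno = trace$resno, values = v), class = "distance_matrix")
}

#' Absolute difference of two distance matrices
#'
#' Rows/columns are matched by residue number; if the residue sets differ
#' the intersection is used (with a message).
#'
#' @param da,db `distance_matrix` objects for the two conformations.
#' @return object of class `diff_matrix` (same layout as `distance_matrix`).
#' @export
difference_matrix <- function(da, db) {
  common <- intersect(da$resno, db$resno)
  if (length(common) == 0) stop("distance matrices share no residues")
  if (length(common) < length(da$resno) || length(common) < length(db$resno))
    message("difference_matrix: using ", length(common),
            " shared residues (inputs differ)")
  ia <- match(common, da$resno); ib <- match(common, db$resno)
  v <- abs(da$values[ia, ia, drop = FALSE] - db$values[ib, ib, drop = FALSE])
  dimnames(v) <- list(common, common)
  structure(list(resno = common, values = v), class = "diff_matrix")
}

#' Segment a difference matrix into rigid blocks
#'
#' Greedy agglomeration on the graph whose edges connect residue pairs with
#' `|dD| <= threshold`: blocks are grown from contiguous sequence runs (so
#' that sequence-local structure seeds them), blocks whose members are
#' mutually compatible are merged (this admits sequence-discontinuous
#' domains), and finally every residue is re-examined against all blocks
#' and assigned to the compatible block with the smallest mean difference
#' (a residue moves only if strictly better, so ties keep the incumbent).
#' Blocks smaller than `min_size` are relabelled 0 (flexible/unassigned).
#'
#' The emitted partition satisfies, by construction and by a final
#' assertion, that every within-block pair is below the threshold.
#'
#' @param diff a `diff_matrix`.
#' @param threshold Angstrom; maximum within-block distance change.
#' @param min_size minimum residues per reported block.
#' @return object of class `domain_segmentation`: list with `resno`,
#'   integer `labels` (0 = unassigned, 1..k = blocks in sequence order),
#'   `threshold`, `min_size`.
#' @export
segment_rigid_domains <- function(diff, threshold = 2.0, min_size = 15) {
  stopifnot(inherits(diff, "diff_matrix"), threshold > 0, min_size >= 1)
  D <- diff$values
  n <- nrow(D)
  lab <- integer(n)

  ## phase 1: contiguous greedy seeds
  k <- 0L; i <- 1L
  while (i <= n) {
    members <- i
    j <- i + 1L
    while (j <= n && all(D[j, members] <= threshold)) {
      members <- c(members, j); j <- j + 1L
    }
    k <- k + 1L
    lab[members] <- k
    i <- j
  }

  ## phase 2: merge mutually compatible blocks, smallest mean cross-diff
  ## first, until no pair of blocks can be merged
  repeat {
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) < 2) break
    best <- NULL; best_mean <- Inf
    for (ai in seq_along(ids)) for (bi in seq_along(ids)) {
      if (bi <= ai) next
      A <- which(lab == ids[ai]); B <- which(lab == ids[bi])
      cross <- D[A, B, drop = FALSE]
      if (max(cross) <= threshold && mean(cross) < best_mean) {
        best <- c(ids[ai], ids[bi]); best_mean <- mean(cross)
      }
    }
    if (is.null(best)) break
    lab[lab == best[2]] <- best[1]
  }

  ## phase 3: per-residue refinement with the mean-difference tie-break
  for (pass in 1:10) {
    changed <- FALSE
    for (r in seq_len(n)) {
      ids <- sort(unique(lab[lab > 0]))
      cur <- lab[r]
      cur_mean <- Inf
      best_id <- cur; best_mean <- Inf
      for (id in ids) {
        members <- setdiff(which(lab == id), r)
        if (length(members) == 0) next
        if (all(D[r, members] <= threshold)) {
          m <- mean(D[r, members])
          if (id == cur) cur_mean <- m
          if (m < best_mean) { best_mean <- m; best_id <- id }
        }
      }
      if (best_id != cur && best_mean < cur_mean - 1e-9) {
        lab[r] <- best_id
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ## phase 4: drop undersized blocks, relabel in sequence order
  for (id in unique(lab[lab > 0]))
    if (sum(lab == id) < min_size) lab[lab == id] <- 0L
  ids <- unique(lab[lab > 0])  # order of first occurrence
  relab <- integer(n)
  for (i2 in seq_along(ids)) relab[lab == ids[i2]] <- i2
  lab <- relab

  ## the partition must literally satisfy its own invariant
  for (id in unique(lab[lab > 0])) {
    members <- which(lab == id)
    if (length(members) > 1 &&
        max(D[members, members]) > threshold + 1e-12)
      stop("internal error: emitted block violates the threshold")
  }

  structure(list(resno = diff$resno, labels = lab, threshold = threshold,
                 min_size = min_size),
            class = "domain_segmentation")
}

#' @export
print.domain_segmentation <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0]))
  cat(sprintf("domain_segmentation: %d rigid block(s), %d unassigned of %d residues (threshold %.2f A, min size %d)\n",
              length(ids), sum(x$labels == 0), length(x$labels),
              x$threshold, x$min_size))
  for (id in ids) {
    res <- x$resno[x$labels == id]
    runs <- split(res, cumsum(c(1, diff(res) != 1)))
    spans <- vapply(runs, function(r)
      if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)]),
      character(1))
    cat(sprintf("  block %d (%d residues): %s\n", id, length(res),
                paste(spans, collapse = ", ")))
  }
  invisible(x)
}
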