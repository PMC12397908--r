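test_that("distance matrices match brute-force double loops", {
  tr <- ca_trace("A", 1:20, random_cloud(20, seed = 8) * 3)
  dm <- ca_distance_matrix(tr)
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    brute[i, j] <- sqrt(sum((tr$xyz[i, ] - tr$xyz[j, ])^2))
  expect_equal(unname(dm$values), brute)
  expect_true(isSymmetric(dm$values))
  expect_equal(diag(dm$values), setNames(rep(0, 20), 1:20))
})

test_that("distance matrices are isometry-invariant", {
  hp <- make_hinge_protein(15, 15, 0)
  tr <- hp$confA
  moved <- ca_trace("A", tr$resno, random_rigid_transform(tr$xyz, 13))
  expect_equal(ca_distance_matrix(tr)$values,
               ca_distance_matrix(moved)$values, tolerance = 1e-9)
})

test_that("two-point matrix is the textbook example", {
  tr <- ca_trace("A", 1:2, rbind(c(0, 0, 0), c(3.8, 0, 0)))
  expect_equal(unname(ca_distance_matrix(tr)$values),
               matrix(c(0, 3.8, 3.8, 0), 2))
})

test_that("difference matrix vanishes for rigid transforms and splits a hinge", {
  hp <- make_hinge_protein(30, 30, 40)
  da <- ca_distance_matrix(hp$confA)
  expect_equal(max(difference_matrix(da, da)$values), 0)
  moved <- ca_trace("A", hp$confA$resno,
                    random_rigid_transform(hp$confA$xyz, 21))
  expect_lt(max(difference_matrix(da, ca_distance_matrix(moved))$values),
            1e-9)
  dd <- difference_matrix(da, ca_distance_matrix(hp$confB))
  expect_lt(max(dd$values[1:30, 1:30]), 1e-9)        # intra segment 1
  expect_lt(max(dd$values[31:60, 31:60]), 1e-9)      # intra segment 2
  expect_gt(max(dd$values[1:30, 31:60]), 2.0)        # across the hinge
})

test_that("difference matrix uses the residue intersection and refuses disjoint sets", {
  a <- ca_trace("A", 1:10, helix_pts(10))
  b <- ca_trace("A", 6:15, helix_pts(10))
  expect_message(dd <- difference_matrix(ca_distance_matrix(a),
                                         ca_distance_matrix(b)), "shared")
  expect_equal(dd$resno, 6:10)
  c1 <- ca_trace("A", 21:30, helix_pts(10))
  expect_error(difference_matrix(ca_distance_matrix(a),
                                 ca_distance_matrix(c1)), "no residues")
})

test_that("degenerate segmentations behave as documented", {
  n <- 30
  zero <- structure(list(resno = 1:n, values = matrix(0, n, n)),
                    class = "diff_matrix")
  seg <- segment_rigid_domains(zero, threshold = 2, min_size = 15)
  expect_equal(seg$labels, rep(1L, n))
  big <- structure(list(resno = 1:n,
                        values = matrix(20, n, n) - diag(20, n)),
                   class = "diff_matrix")
  seg2 <- segment_rigid_domains(big, threshold = 2, min_size = 2)
  expect_equal(seg2$labels, rep(0L, n))
})

test_that("segmentation recovers the generator's two-block partition exactly", {
  hp <- make_hinge_protein(60, 60, 40)
  dd <- difference_matrix(ca_distance_matrix(hp$confA),
                          ca_distance_matrix(hp$confB))
  seg <- segment_rigid_domains(dd)
  expect_identical(seg$labels, hp$labels)
})

test_that("two-block recovery holds across hinge angles 20-160 degrees", {
  for (th in seq(20, 160, by = 20)) {
    hp <- make_hinge_protein(60, 60, th)
    dd <- difference_matrix(ca_distance_matrix(hp$confA),
                            ca_distance_matrix(hp$confB))
    seg <- segment_rigid_domains(dd)
    expect_identical(seg$labels, hp$labels,
                     label = sprintf("labels at %d degrees", th))
  }
})

test_that("segmentation is invariant to renumbering and to swapping inputs", {
  hp <- make_hinge_protein(40, 40, 60)
  da <- ca_distance_matrix(hp$confA)
  db <- ca_distance_matrix(hp$confB)
  seg <- segment_rigid_domains(difference_matrix(da, db))
  # A/B swap
  seg_swap <- segment_rigid_domains(difference_matrix(db, da))
  expect_identical(seg$labels, seg_swap$labels)
  # renumbering offset
  shift_a <- ca_trace("A", hp$confA$resno + 100, hp$confA$xyz)
  shift_b <- ca_trace("A", hp$confB$resno + 100, hp$confB$xyz)
  seg_off <- segment_rigid_domains(
    difference_matrix(ca_distance_matrix(shift_a),
                      ca_distance_matrix(shift_b)))
  expect_identical(seg$labels, seg_off$labels)
})

test_that("every emitted block satisfies its own threshold invariant", {
  hp <- make_hinge_protein(60, 48, 60, tail_len = 12, seed = 1)
  dd <- difference_matrix(ca_distance_matrix(hp$confA),
                          ca_distance_matrix(hp$confB))
  seg <- segment_rigid_domains(dd)
  for (id in unique(seg$labels[seg$labels > 0])) {
    idx <- which(seg$labels == id)
    expect_lte(max(dd$values[idx, idx]), seg$threshold)
    expect_gte(length(idx), seg$min_size)
  }
  # the 12-residue relocating tail is below min_size, hence unassigned
  expect_equal(which(seg$labels == 0), 109:120)
})
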