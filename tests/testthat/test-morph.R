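test_that("elastic networks have the right springs and a zero-energy rest state", {
  tr <- ca_trace("A", 1:2, rbind(c(0, 0, 0), c(3.8, 0, 0)))
  enm <- build_enm(tr, cutoff = 10)
  expect_equal(nrow(enm$pairs), 1)
  expect_equal(enm$r0, 3.8)
  expect_equal(enm_energy(enm), 0)

  hp <- make_hinge_protein(25, 25, 50)
  sys <- build_enm(hp$confA, cutoff = 9)
  d <- as.matrix(dist(hp$confA$xyz))
  brute <- sum(d[upper.tri(d)] <= 9)
  expect_equal(nrow(sys$pairs), brute)
  expect_equal(enm_energy(sys), 0)
  expect_error(build_enm(hp$confA, cutoff = 3), "3.8")
})

test_that("bias vectors vanish for rigid differences and localise on the moving segment", {
  hp <- make_hinge_protein(30, 30, 60)
  v0 <- compute_bias_vectors(hp$confA, hp$confA)
  expect_lt(max(abs(v0)), 1e-10)
  moved <- ca_trace("A", hp$confA$resno,
                    random_rigid_transform(hp$confA$xyz, 31))
  expect_lt(max(abs(compute_bias_vectors(hp$confA, moved))), 1e-8)
  # with a small moving segment the shared-residue superposition is
  # dominated by the anchor, so the vectors concentrate on the mover
  hp2 <- make_hinge_protein(60, 12, 60)
  v <- compute_bias_vectors(hp2$confA, hp2$confB)
  mag <- sqrt(rowSums(v^2))
  expect_gt(mean(mag[61:72]), 2 * mean(mag[1:60]))
})

test_that("relaxation is stationary at rest, snaps to stiff bias, and is seeded", {
  hp <- make_hinge_protein(20, 20, 50)
  sys <- build_enm(hp$confA)
  expect_lt(max(abs(relax_step(sys, n_steps = 50) - sys$xyz)), 1e-12)
  x <- relax_step(sys, centers = hp$confB$xyz, k_bias = 1e4, n_steps = 200)
  expect_lt(max(sqrt(rowSums((x - hp$confB$xyz)^2))), 0.1)
  a <- relax_step(sys, n_steps = 20, temperature = 0.01, seed = 7)
  b <- relax_step(sys, n_steps = 20, temperature = 0.01, seed = 7)
  expect_identical(a, b)
  expect_error(relax_step(sys, centers = hp$confB$xyz, k_bias = 5,
                          n_steps = 50, step_size = 10), "step_size")
})

test_that("identical or rigidly related endpoints converge immediately", {
  hp <- make_hinge_protein(15, 15, 30)
  mr <- biased_morph(hp$confA, hp$confA)
  expect_true(mr$converged)
  expect_equal(mr$iterations, 0)
  expect_equal(mr$rmsd, 0, tolerance = 1e-10)
  moved <- ca_trace("A", hp$confA$resno,
                    random_rigid_transform(hp$confA$xyz, 17))
  mr2 <- biased_morph(hp$confA, moved)
  expect_true(mr2$converged)
  expect_equal(mr2$iterations, 0)
})

test_that("the stiff midpoint limit converges in a single iteration", {
  hp <- make_hinge_protein(20, 20, 50)
  mr <- biased_morph(hp$confA, hp$confB, advance = 0.5, k_bias = 1e4,
                     steps_per_iter = 300)
  expect_true(mr$converged)
  expect_equal(mr$iterations, 1)
  expect_lt(mr$rmsd[length(mr$rmsd)], 0.01)
})

test_that("the iterative protocol closes a 60-degree hinge with intact geometry", {
  hp <- make_hinge_protein(30, 30, 60, seed = 1)
  mr <- biased_morph(hp$confA, hp$confB, seed = 1)
  expect_true(mr$converged)
  expect_lte(mr$rmsd[length(mr$rmsd)], 1.2)
  expect_lte(mr$iterations, 100)
  expect_true(all(diff(mr$rmsd) < 0))
  # no chain tearing anywhere along either trajectory
  for (traj in list(mr$traj_a, mr$traj_b)) {
    bonds <- unlist(lapply(traj, function(f) {
      x <- f$xyz
      sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
    }))
    expect_true(all(bonds > 2.5 & bonds < 5.0))
  }
  # ENM energies at convergence are finite
  expect_true(is.finite(enm_energy(build_enm(hp$confA),
                                   mr$traj_a[[mr$iterations + 1]]$xyz)))
})

test_that("swapping the endpoints leaves the final RMSD essentially unchanged", {
  hp <- make_hinge_protein(20, 20, 45)
  for (seed in 1:5) {
    f <- biased_morph(hp$confA, hp$confB, seed = seed)
    r <- biased_morph(hp$confB, hp$confA, seed = seed)
    expect_lt(abs(f$rmsd[length(f$rmsd)] - r$rmsd[length(r$rmsd)]) /
                f$rmsd[length(f$rmsd)], 0.1)
  }
})

test_that("dual-reference RMSD series behave like a transition trajectory", {
  hp <- make_hinge_protein(30, 30, 60, seed = 1)
  ab <- rmsd_after_superposition(hp$confA, hp$confB)
  dr0 <- dual_reference_rmsd(list(hp$confA), hp$confA, hp$confB)
  expect_equal(dr0$rmsd_a, 0, tolerance = 1e-10)
  expect_equal(dr0$rmsd_b, ab, tolerance = 1e-10)
  # frames that are rigid transforms of the reference stay at zero
  frames <- lapply(1:4, function(s)
    ca_trace("A", hp$confA$resno, random_rigid_transform(hp$confA$xyz, s)))
  expect_lt(max(dual_reference_rmsd(frames, hp$confA, hp$confB)$rmsd_a), 1e-8)
  # along the morph, distance from the start grows and to the target shrinks
  mr <- biased_morph(hp$confA, hp$confB, seed = 1)
  dr <- dual_reference_rmsd(mr$traj_a, hp$confA, hp$confB)
  expect_gt(cor(dr$frame, dr$rmsd_a, method = "spearman"), 0.9)
  expect_lt(cor(dr$frame, dr$rmsd_b, method = "spearman"), -0.9)
})
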