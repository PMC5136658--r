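lockable_bundle <- function(seed = 1, lock_d = 3.0) {
  build_bundle(bundle_spec(
    features = list(feat_contact(bundle_resno("3.50"), bundle_resno("6.30"),
                                 lock_d, "ARG", "ASP")),
    seed = seed))
}

test_that("ionic lock status tracks the planted charged-group distance", {
  b <- lockable_bundle()
  lock <- ionic_lock_status(b$model, b$map)
  expect_true(lock$present)
  expect_equal(lock$distance_A, 3.0, tolerance = 0.05)
  # separate TM6: lock broken
  sp <- bundle_spec(features = list(
    feat_contact(bundle_resno("3.50"), bundle_resno("6.30"), 3.0, "ARG", "ASP"),
    feat_motion(6, translation = c(12, 0, 0))), seed = 1)
  lock2 <- ionic_lock_status(build_bundle(sp)$model, b$map)
  expect_false(lock2$present)
  expect_gt(lock2$distance_A, 10)
})

test_that("a non-ionizable 6.30 yields not_applicable, missing residues degrade", {
  b <- build_bundle(bundle_spec(seed = 4))   # poly-LEU: no Arg/Asp pair
  lock <- ionic_lock_status(b$model, b$map)
  expect_equal(lock$regime, "not_applicable")
  a <- b$model$atoms[b$model$atoms$resno != bundle_resno("6.30"), ]
  lock2 <- ionic_lock_status(as_tmd_structure(a, "cut", "synthetic"), b$map)
  expect_equal(lock2$regime, "unavailable")
})

test_that("state calls follow the lock/toggle decision table", {
  pair <- make_state_pair(bundle_spec(seed = 6),
                          moves = list(move_end(6, "intracellular",
                                                radial = 8)),
                          tm6_spin_deg = 30, toggle_distance_A = 4.6)
  f_in <- activation_fingerprint(pair$inactive, pair$map)
  expect_equal(f_in$state_call, "inactive_like")
  expect_true(f_in$ionic_lock$present)
  expect_equal(f_in$tyrosine_toggle$regime, "apart")
  f_ac <- activation_fingerprint(pair$active, pair$map)
  expect_equal(f_ac$state_call, "active_like")
  expect_false(f_ac$ionic_lock$present)
  expect_gt(f_ac$ionic_lock$distance_A, 10)
  expect_equal(f_ac$tyrosine_toggle$distance_A, 4.6, tolerance = 0.1)
  expect_equal(f_ac$tyrosine_toggle$regime, "water_mediated_possible")
  # lock absent, toggle apart: indeterminate
  pair2 <- make_state_pair(bundle_spec(seed = 6),
                           moves = list(move_end(6, "intracellular",
                                                 radial = 8)))
  f_ind <- activation_fingerprint(pair2$active, pair2$map)
  expect_false(f_ind$ionic_lock$present)
  expect_equal(f_ind$tyrosine_toggle$regime, "apart")
  expect_equal(f_ind$state_call, "indeterminate")
  # featureless bundle: no lock pair, no toggle pair -> indeterminate
  bare <- build_bundle(bundle_spec(seed = 6))
  expect_equal(activation_fingerprint(bare$model, bare$map)$state_call,
               "indeterminate")
})

test_that("the fingerprint is invariant under global rigid motion", {
  b <- lockable_bundle(seed = 9)
  f1 <- activation_fingerprint(b$model, b$map)
  f2 <- activation_fingerprint(apply_global_rigid(b$model), b$map)
  expect_equal(f1$state_call, f2$state_call)
  expect_equal(f1$ionic_lock$distance_A, f2$ionic_lock$distance_A,
               tolerance = 1e-9)
  expect_equal(f1$tyrosine_toggle$distance_A, f2$tyrosine_toggle$distance_A,
               tolerance = 1e-9)
})

test_that("superposition is exact on self and recovers a planted transform", {
  b <- build_bundle(bundle_spec(seed = 3, residues_per_helix = 14))
  s_self <- superpose_by_bw(b$model, b$model, b$map, b$map)
  expect_lt(s_self$rmsd_A, 1e-12)
  expect_equal(s_self$rotation, diag(3), tolerance = 1e-9)
  R <- gphrtmd:::rot_axis_angle(c(1, 2, 3), 25)
  moved <- apply_global_rigid(b$model, c(1, 2, 3), 25, c(4, -2, 7))
  s <- superpose_by_bw(b$model, moved, b$map, b$map)
  expect_lt(s$rmsd_A, 1e-6)
  expect_equal(abs(det(s$rotation) - 1), 0, tolerance = 1e-6)
  expect_equal(s$rotation, R, tolerance = 1e-6)
  # symmetry of the fit quality
  s_rev <- superpose_by_bw(moved, b$model, b$map, b$map)
  expect_lt(abs(s$rmsd_A - s_rev$rmsd_A), 1e-9)
})

test_that("closed-form superposition matches numerical minimization", {
  b <- build_bundle(bundle_spec(seed = 8, residues_per_helix = 10))
  sp2 <- bundle_spec(seed = 8, residues_per_helix = 10,
                     features = list(feat_motion(4, translation = c(3, 1, -2))))
  b2 <- build_bundle(sp2)
  s <- superpose_by_bw(b$model, b2$model, b$map, b2$map)
  m <- gphrtmd:::matched_ca(b$model, b2$model, b$map, b2$map, 1:7)
  obj <- function(p) {
    R <- gphrtmd:::rot_axis_angle(p[1:3] / sqrt(sum(p[1:3]^2)), p[4])
    moved <- t(R %*% t(m$xyz_a)) + matrix(p[5:7], nrow(m$xyz_a), 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - m$xyz_b)^2)))
  }
  fit <- stats::optim(c(0, 0, 1, 1, 0.4, 0.1, -0.3), obj,
                      method = "BFGS", control = list(maxit = 2000))
  expect_equal(s$rmsd_A, fit$value, tolerance = 1e-3)
  expect_lte(s$rmsd_A, fit$value + 1e-6)   # closed form is the optimum
})

test_that("helix movements vanish for identical and rigidly moved copies", {
  b <- build_bundle(bundle_spec(seed = 5))
  mv <- helix_movements(b$model, b$model, b$map, b$map, b$tm)
  expect_lt(max(mv$magnitude_A), 1e-9)
  moved <- apply_global_rigid(b$model, c(0, 1, 1), 40, c(-6, 2, 9))
  mv2 <- helix_movements(b$model, moved, b$map, b$map, b$tm)
  expect_lt(max(mv2$magnitude_A), 1e-6)
})

test_that("a planted intracellular TM6 swing is recovered with sign and size", {
  pair <- make_state_pair(bundle_spec(seed = 2),
                          moves = list(move_end(6, "intracellular",
                                                radial = 5)))
  mv <- helix_movements(pair$inactive, pair$active, pair$map, pair$map,
                        pair$tm, core_selection = c(2, 4))
  tm6_ic <- mv[mv$helix == 6 & mv$end == "intracellular", ]
  expect_equal(tm6_ic$radial_A, 5, tolerance = 0.5)
  expect_lt(abs(mv$magnitude_A[mv$helix == 2 & mv$end == "intracellular"]),
            0.2)
})

test_that("helix rotation measures planted spin with the stated sign convention", {
  pair <- make_state_pair(bundle_spec(seed = 7), tm6_spin_deg = 30)
  rot <- helix_rotation(pair$inactive, pair$active, pair$map, pair$map,
                        pair$tm)
  expect_equal(rot, 30, tolerance = 2)
  rot_rev <- helix_rotation(pair$active, pair$inactive, pair$map, pair$map,
                            pair$tm)
  expect_equal(rot_rev, -rot, tolerance = 1e-6)
  same <- helix_rotation(pair$inactive, pair$inactive, pair$map, pair$map,
                         pair$tm)
  expect_equal(same, 0, tolerance = 1e-9)
})
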