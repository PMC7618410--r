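# Structure editors: symmetrization, motif replacement and multi-state
# coupling.

random_aug <- function(n, seed = 1, sd = 8) {
  set.seed(seed)
  augmentedStructure(array(rnorm(n * 20 * 3, sd = sd), c(n, 20, 3)))
}

sub_atoms <- function(x, k, l_sub) {
  sparsebb:::flatten_atoms(x@atoms[(k - 1) * l_sub + seq_len(l_sub), , ,
                                   drop = FALSE])
}

test_that("cyclic symmetrization produces exact symmetry and is a projection", {
  spec <- symmetrySpec("cyclic", n_subunits = 4L)
  x <- random_aug(40, seed = 2)
  sym <- symmetrize(x, spec)
  rotz <- sparsebb:::rot_z(-90)
  for (k in 2:4) {
    mapped <- t(rotz %*% t(matrix(t(sub_atoms(sym, k, 10)), ncol = 3,
                                  byrow = TRUE)))
  }
  # subunit k maps onto subunit 0 under the inverse action
  s0 <- matrix(t(sub_atoms(sym, 1, 10)), ncol = 3, byrow = TRUE)
  for (k in 2:4) {
    sk <- matrix(t(sub_atoms(sym, k, 10)), ncol = 3, byrow = TRUE)
    inv <- sparsebb:::sym_inverse(sk, spec, k - 1L)
    expect_lt(sqrt(mean(rowSums((inv - s0)^2))), 1e-6)
  }
  # idempotence
  sym2 <- symmetrize(sym, spec)
  expect_lt(max(abs(sym2@atoms - sym@atoms)), 1e-6)
  expect_error(symmetrize(random_aug(41), spec), "divisible")
})

test_that("an already-symmetric input is a fixed point of averaging", {
  spec <- symmetrySpec("cyclic", n_subunits = 3L)
  x <- random_aug(30, seed = 3)
  sym <- symmetrize(x, spec)
  again <- symmetrize(sym, spec)
  expect_lt(max(abs(again@atoms - sym@atoms)), 1e-6)
})

test_that("symmetrization commutes with rotations about the symmetry axis", {
  spec <- symmetrySpec("cyclic", n_subunits = 3L)
  x <- random_aug(30, seed = 4)
  theta <- 37
  Q <- sparsebb:::rot_z(theta)
  xr <- transformStructure(x, Q, c(0, 0, 0))
  a <- transformStructure(symmetrize(x, spec), Q, c(0, 0, 0))
  b <- symmetrize(xr, spec)
  expect_lt(max(abs(a@atoms - b@atoms)), 1e-6)
})

test_that("the radius projection places subunit centroids at R", {
  spec <- symmetrySpec("cyclic", n_subunits = 5L, radius = 14)
  sym <- symmetrize(random_aug(50, seed = 5), spec)
  for (k in 1:5) {
    com <- colMeans(matrix(t(sub_atoms(sym, k, 10)), ncol = 3, byrow = TRUE))
    expect_equal(sqrt(com[1]^2 + com[2]^2), 14, tolerance = 1e-6)
  }
})

test_that("screw symmetry spaces consecutive subunits by the translation", {
  spec <- symmetrySpec("screw", n_subunits = 3L, angle = 30, translation = 12)
  sym <- symmetrize(random_aug(30, seed = 6), spec)
  coms <- sapply(1:3, function(k)
    colMeans(matrix(t(sub_atoms(sym, k, 10)), ncol = 3, byrow = TRUE)))
  expect_equal(coms[3, 2] - coms[3, 1], 12, tolerance = 1e-9)
  expect_equal(coms[3, 3] - coms[3, 2], 12, tolerance = 1e-9)
  # xy centroids rotate by 30 degrees between subunits
  r1 <- sqrt(sum(coms[1:2, 1]^2)); r2 <- sqrt(sum(coms[1:2, 2]^2))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("motif replacement is rigid and respects group structure", {
  m <- toy_test_model()
  scaffold <- random_aug(30, seed = 7)
  motif <- makeFixture("helix", length = 6, seed = 8)
  pl <- motifPlacement(motif, 10:15)
  edited <- motifReplace(scaffold, list(pl))
  # motif-internal pairwise distances are preserved exactly
  motif_pts <- matrix(aperm(motif@coords, c(2, 1, 3)), ncol = 3)
  new_pts <- matrix(aperm(edited@atoms[10:15, 1:4, ], c(2, 1, 3)), ncol = 3)
  expect_lt(max(abs(dist(motif_pts) - dist(new_pts))), 1e-6)
  # pseudoatom slots untouched
  expect_identical(edited@atoms[, 6:20, ], scaffold@atoms[, 6:20, ])
  expect_identical(edited@atoms[1:9, 1:4, ], scaffold@atoms[1:9, 1:4, ])

  # a structure already containing the motif is unchanged
  exact <- motifReplace(edited, list(pl))
  expect_lt(max(abs(exact@atoms[, 1:4, ] - edited@atoms[, 1:4, ])), 1e-6)

  # shared group id preserves relative geometry between motif parts;
  # separate ids fit independently
  m1 <- makeFixture("helix", length = 4, seed = 9)
  m2 <- transformStructure(m1, diag(3), c(20, 0, 0))
  same_group <- motifReplace(scaffold, list(
    motifPlacement(m1, 1:4, group_id = 1),
    motifPlacement(m2, 20:23, group_id = 1)))
  p1 <- matrix(aperm(same_group@atoms[1:4, 1:4, ], c(2, 1, 3)), ncol = 3)
  p2 <- matrix(aperm(same_group@atoms[20:23, 1:4, ], c(2, 1, 3)), ncol = 3)
  cross_dist <- as.vector(sqrt(outer(rowSums(p1^2), rowSums(p2^2), "+") -
                                 2 * p1 %*% t(p2)))
  m1p <- matrix(aperm(m1@coords, c(2, 1, 3)), ncol = 3)
  m2p <- matrix(aperm(m2@coords, c(2, 1, 3)), ncol = 3)
  ref_dist <- as.vector(sqrt(outer(rowSums(m1p^2), rowSums(m2p^2), "+") -
                               2 * m1p %*% t(m2p)))
  expect_lt(max(abs(cross_dist - ref_dist)), 1e-5)

  expect_error(motifReplace(scaffold, list(
    motifPlacement(m1, 1:4), motifPlacement(m1, 3:6))), "overlap")
})

test_that("state coupling makes shared substructures agree exactly", {
  states <- list(random_aug(20, seed = 10), random_aug(20, seed = 11),
                 random_aug(20, seed = 12))
  shared <- list(list(1:6, 3:8, 10:15))
  out <- coupleStates(states, shared)
  pts <- lapply(1:3, function(s)
    matrix(aperm(out[[s]]@atoms[shared[[1]][[s]], 1:4, ], c(2, 1, 3)),
           ncol = 3))
  expect_lt(superpose(pts[[2]], pts[[1]])$rmsd, 1e-6)
  expect_lt(superpose(pts[[3]], pts[[1]])$rmsd, 1e-6)
  # applying the coupling again changes nothing (already agreeing)
  out2 <- coupleStates(out, shared)
  for (s in 1:3)
    expect_lt(max(abs(out2[[s]]@atoms - out[[s]]@atoms)), 1e-6)

  # copy_first inherits the first state's internal distances exactly
  out_cp <- coupleStates(states, shared, mode = "copy_first")
  d1 <- dist(matrix(aperm(states[[1]]@atoms[1:6, 1:4, ], c(2, 1, 3)), ncol = 3))
  d2 <- dist(matrix(aperm(out_cp[[2]]@atoms[3:8, 1:4, ], c(2, 1, 3)), ncol = 3))
  expect_lt(max(abs(d1 - d2)), 1e-6)

  expect_error(coupleStates(states[1], shared), ">= 2 states")
  expect_error(coupleStates(states, list(list(1:2, 1:2, 1:2))),
               "underdetermined")
})
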