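# Loss stack: clipped denoising losses, rotation loss, neighbour-restricted
# FAPE against a dense oracle, violation loss, cross-entropies and the
# weighted combinations.

test_that("trajectory loss: hand-computed clip case and single-block rule", {
  # 1 residue, 1 block, one atom displaced 20 A: clip(20)^2 / 20 slots = 5
  gt <- matrix(0, 1, 60)
  pred <- gt
  pred[1, 1] <- 20
  res <- denoisingLosses(list(pred), gt)
  expect_equal(res$per_block[1], 100 / 20)
  # Eq-8 arithmetic with n = 1: 2*L + L = 3*L
  expect_equal(res$l_traj, 3 * res$per_block[1])

  perfect <- denoisingLosses(list(gt, gt), gt)
  expect_equal(perfect$l_traj, 0)
})

test_that("trajectory combination weights the final block by 2", {
  gt <- matrix(0, 2, 60)
  b1 <- gt + 1   # distance sqrt(3) per atom
  b2 <- gt + 2   # distance 2*sqrt(3)
  res <- denoisingLosses(list(b1, b2), gt)
  l1 <- 3; l2 <- 12  # squared clipped distances
  expect_equal(res$per_block, c(l1, l2))
  expect_equal(res$l_traj, 2 * l2 + (l1 + l2) / 2)
})

test_that("rotation loss: closed-form 180-degree case and invariance", {
  bb <- makeFixture("helix", length = 6, seed = 1)
  fr <- buildFrames(bb)
  expect_equal(rotationLosses(list(fr), fr), 0)

  # rotate every frame 180 degrees about its local z: R^T Rgt = diag(-1,-1,1)
  rot <- fr@rotations
  flip <- diag(c(-1, -1, 1))
  for (i in 1:6) rot[i, , ] <- rot[i, , ] %*% flip
  fr2 <- new("FrameSet", rotations = rot, translations = fr@translations)
  # per-residue term ||diag(-2,-2,0)||^2 = 8; single block -> 3x weighting
  expect_equal(rotationLosses(list(fr2), fr), 3 * 8, tolerance = 1e-9)

  # global rotation applied to both predicted and gt cancels
  Q <- random_proper_rotation(2)
  rotQ <- fr@rotations; rot2Q <- rot
  for (i in 1:6) {
    rotQ[i, , ] <- Q %*% rotQ[i, , ]
    rot2Q[i, , ] <- Q %*% rot2Q[i, , ]
  }
  frQ <- new("FrameSet", rotations = rotQ, translations = fr@translations)
  fr2Q <- new("FrameSet", rotations = rot2Q, translations = fr@translations)
  expect_equal(rotationLosses(list(fr2Q), frQ), 3 * 8, tolerance = 1e-9)
})

test_that("FAPE: zero at perfection, rigid-invariant, equals dense oracle", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 20, seed = 3)
  aug <- encodeStructure(m, bb)
  gt <- sparsebb:::flatten_atoms(aug@atoms)
  perfect <- fapeLosses(list(gt), gt, bb)
  expect_equal(perfect$l_fape, 0, tolerance = 1e-9)

  set.seed(4)
  pred <- gt + matrix(rnorm(length(gt), sd = 1.5), nrow(gt))
  base <- fapeLosses(list(pred), gt, bb, n_fape = 19L)
  # rigid transform of the prediction only leaves the loss unchanged
  Q <- random_proper_rotation(5)
  predT <- transform_xmat(pred, Q, c(10, -5, 3))
  moved <- fapeLosses(list(predT), gt, bb, n_fape = 19L)
  expect_equal(moved$l_fape, base$l_fape, tolerance = 1e-6)

  # dense oracle with K = 19 (all neighbours) on the same pair list
  pairs_i <- rep(1:20, each = 19)
  pairs_j <- unlist(lapply(1:20, function(i) setdiff(1:20, i)))
  oracle <- dense_fape_oracle(pred, frame_list(pred), gt, frame_list(bb),
                              pairs_i, pairs_j, 20L)
  # fapeLosses averages blocks with final-block weight 2: single block -> 3x
  expect_equal(base$l_fape, 3 * oracle, tolerance = 1e-6)
})

test_that("violation loss: ideal geometry is zero, clashes grow, bonds count", {
  helix <- makeFixture("helix", length = 12, seed = 1)
  expect_equal(violationLoss(helix), 0, tolerance = 1e-6)

  # two atoms forced together produce a growing clash penalty
  clash_at <- function(sep) {
    co <- array(0, c(3, 4, 3))
    for (i in 1:3) {
      co[i, 1, ] <- c(-1.4, 0.5, 0) + c(0, (i - 1) * 100, 0)
      co[i, 2, ] <- c(0, (i - 1) * 100, 0)
      co[i, 3, ] <- c(1.5, (i - 1) * 100, 0)
      co[i, 4, ] <- c(2, 1 + (i - 1) * 100, 0)
    }
    co[3, , 2] <- co[1, , 2] + sep  # bring residue 3 near residue 1
    xm <- cbind(matrix(co[, 1, ], ncol = 3), matrix(co[, 2, ], ncol = 3),
                matrix(co[, 3, ], ncol = 3), matrix(co[, 4, ], ncol = 3))
    # isolate the clash term by ignoring bonded terms across the jump
    sparsebb:::violationLoss(xm, chain_index = c(1, 2, 3))
  }
  v_close <- clash_at(0.5)
  v_closer <- clash_at(0.1)
  v_far <- clash_at(50)
  expect_gt(v_close, 0)
  expect_gt(v_closer, v_close)
  expect_equal(v_far, 0, tolerance = 1e-9)

  # stretching all bonds (doubling coordinates) trips the bonded term
  stretched <- helix
  stretched@coords <- stretched@coords * 2
  expect_gt(violationLoss(stretched), 0)
})

test_that("auxiliary losses: uniform logits give ln(K), weights audit holds", {
  n <- 30L
  seqs <- rep(c("A", "G", "W"), 10)
  ss <- rep(c("H", "E", "L"), 10)
  aux_u <- auxLosses(aa_logits = matrix(0, n, 20), ss_logits = matrix(0, n, 3),
                     dist_logits = matrix(0, n, 64), gt_seq = seqs, gt_ss = ss,
                     gt_dist = runif(n, 3, 20))
  expect_equal(aux_u$l_aa, log(20), tolerance = 1e-9)
  expect_equal(aux_u$l_dssp, log(3), tolerance = 1e-9)
  expect_equal(aux_u$l_dist, log(64), tolerance = 1e-9)
  expect_equal(aux_u$l_aux, 10 * aux_u$l_aa + aux_u$l_dssp + 0.1 * aux_u$l_dist)

  # near-one-hot logits drive each term toward zero
  big <- 30
  aa_logits <- matrix(-big, n, 20)
  aa_logits[cbind(1:n, match(seqs, sparsebb:::AA_ONE))] <- big
  aux_hot <- auxLosses(aa_logits = aa_logits, gt_seq = seqs)
  expect_lt(aux_hot$l_aa, 1e-4)
})

test_that("total loss is the exact weighted sum with high-noise zeroing", {
  parts <- list(l_traj = 1.1, l_atom = 0.7, l_fape = 2.2, l_rot = 0.5,
                l_local = 3.1, l_aa = 0.9, l_viol = 4.4, l_aux = 1.3)
  low <- totalLoss(parts, noise_level = 0.3, kind = "VP")
  expect_equal(low$total,
               1.1 + 0.7 + 2.2 + 0.5 + 10 * 3.1 + 10 * 0.9 + 0.1 * 4.4 + 1.3,
               tolerance = 1e-9)
  # linearity audit by finite differences in each part
  for (nm in names(parts)) {
    bumped <- parts; bumped[[nm]] <- parts[[nm]] + 1
    w <- totalLoss(bumped, 0.3, "VP")$total - low$total
    expected_w <- switch(nm, l_local = 10, l_aa = 10, l_viol = 0.1, 1)
    expect_equal(w, expected_w, tolerance = 1e-9)
  }
  # VP: t > 0.5 zeroes l_viol and l_local
  high <- totalLoss(parts, noise_level = 0.6, kind = "VP")
  expect_equal(high$l_local, 0); expect_equal(high$l_viol, 0)
  expect_equal(high$total, 1.1 + 0.7 + 2.2 + 0.5 + 10 * 0.9 + 1.3)
  # VE: sigma > 5 A triggers the same rule
  ve_high <- totalLoss(parts, noise_level = 6, kind = "VE")
  expect_equal(ve_high$l_local, 0); expect_equal(ve_high$l_viol, 0)
  ve_low <- totalLoss(parts, noise_level = 4, kind = "VE")
  expect_equal(ve_low$l_viol, 4.4)
})

test_that("autoencoder loss follows its weighted combination", {
  parts <- list(l_fape = 1.5, l_local = 0.4, l_dist = 2.0, l_aa = 0.3)
  res <- autoencoderLoss(parts)
  expect_equal(res$total, 1.5 + 0.4 + 2.0 + 10 * 0.3, tolerance = 1e-9)
  expect_equal(autoencoderLoss(list())$total, 0)
  withvq <- autoencoderLoss(c(parts, list(l_vq_codebook = 0.2,
                                          l_vq_commit = 0.8)))
  expect_equal(withvq$total, res$total + 0.2 + 0.25 * 0.8, tolerance = 1e-9)
  expect_gt(res$total, max(1.5, 0.4, 2.0))
})

test_that("all loss terms are nonnegative and respect their clip bounds", {
  set.seed(6)
  gt <- matrix(rnorm(5 * 60, sd = 4), 5, 60)
  pred <- gt + matrix(rnorm(5 * 60, sd = 30), 5, 60)  # far beyond the clip
  res <- denoisingLosses(list(pred), gt)
  expect_gte(res$per_block[1], 0)
  expect_lte(res$per_block[1], 100)  # clip bound squared
})
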