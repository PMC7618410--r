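# The sparse denoising network: RBF featurization, pair features, SparseIPA
# against a dense oracle, update modules, equivariance and the Encoder /
# AADecoder / autoencoder assemblies.

test_that("RBF grid: spacing 1.375 A, unit response at centres, decay", {
  expect_equal(sparsebb:::RBF_DELTA, 1.375)
  r0 <- rbfEncode(0)
  expect_equal(r0[1, 1], 1.0)
  expect_true(all(diff(as.vector(r0)) < 0))
  c7 <- sparsebb:::RBF_CENTRES[8]
  expect_equal(rbfEncode(c7)[1, 8], 1.0)
  expect_error(rbfEncode(-1), "non-negative")
})

test_that("full pair features have the documented pre-projection width", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 15, seed = 1)
  aug <- encodeStructure(m, bb)
  xm <- sparsebb:::flatten_atoms(aug@atoms)
  fr <- frames_plain(bb)
  frames <- list(rot9 = fr$rot9, trans = fr$trans)
  nbr <- selectNeighbours(caCoords(bb), seed = 1)
  ctx <- sparsebb:::nbr_ctx(nbr)
  raw <- sparsebb:::pair_feature_raw(xm, xm, frames, frames, ctx, "full")
  expect_equal(ncol(raw), 5 * 5 * 16 + 3 + 9 + 2 * (20 * 3))
  minimal <- sparsebb:::pair_feature_raw(xm, xm, frames, frames, ctx, "minimal")
  expect_equal(ncol(minimal), 16 + 9)
})

test_that("pair features are rigid-invariant and zero on masked slots", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 12, seed = 2)
  aug <- encodeStructure(m, bb)
  xm <- sparsebb:::flatten_atoms(aug@atoms)
  nbr <- selectNeighbours(caCoords(bb), seed = 3)
  ctx <- sparsebb:::nbr_ctx(nbr)
  frames_of <- function(x) sparsebb:::frames_from_xmat(x)
  pf <- sparsebb:::pair_features(m$ps, "block1/pair1", xm, xm, frames_of(xm),
                                 frames_of(xm), ctx, "full",
                                 m$config$pair_size)
  Q <- random_proper_rotation(4)
  xmT <- transform_xmat(xm, Q, c(2, -1, 3))
  pfT <- sparsebb:::pair_features(m$ps, "block1/pair1", xmT, xmT,
                                  frames_of(xmT), frames_of(xmT), ctx, "full",
                                  m$config$pair_size)
  expect_lt(max(abs(pf - pfT)), 1e-4)
  masked_rows <- which(as.vector(ctx$maskf) == 0)
  if (length(masked_rows))
    expect_equal(max(abs(pf[masked_rows, ])), 0)
})

test_that("sparse IPA with all neighbours equals a dense IPA oracle", {
  m <- toy_test_model()
  cfg <- m$config
  n <- 10L
  bb <- makeFixture("mixed", length = n, seed = 5)
  set.seed(6)
  local <- matrix(rnorm(n * cfg$local_size), n, cfg$local_size)
  fr <- frames_plain(bb)
  frames <- list(rot9 = fr$rot9, trans = fr$trans)
  # dense neighbour set: K = N - 1
  nbr <- sparsebb:::nearest_ca_neighbours(caCoords(bb), n - 1L)
  ctx <- sparsebb:::nbr_ctx(nbr)
  # deterministic pair features indexed by (i, j)
  pair_array <- array(rnorm(n * n * cfg$pair_size, sd = 0.5),
                      c(n, n, cfg$pair_size))
  pair_flat <- matrix(0, ctx$n * ctx$k, cfg$pair_size)
  for (r in seq_len(ctx$n * ctx$k))
    pair_flat[r, ] <- pair_array[ctx$rep_idx[r], ctx$idxf[r], ]
  sparse_out <- sparsebb:::sparse_ipa(m$ps, "block1/ipa1", local, local,
                                      frames, frames, ctx, pair_flat, cfg)
  rot_list <- lapply(seq_len(n), function(i) fr$set@rotations[i, , ])
  dense_out <- dense_ipa_oracle(m$ps$values, "block1/ipa1", local, rot_list,
                                fr$trans, pair_array, cfg)
  expect_lt(max(abs(sparse_out - dense_out)), 1e-5)
})

test_that("a single valid neighbour receives full attention weight", {
  ad <- asNamespace("sparsebb")
  logits <- matrix(rnorm(6), 2, 3)
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE), 2, 3, byrow = TRUE)
  p <- ad$ad_softmax_rows(logits, mask)
  expect_equal(p[1, 1], 1, tolerance = 1e-12)
  expect_equal(p[2, 2], 1, tolerance = 1e-12)
})

test_that("update module pooling identities hold", {
  m <- toy_test_model()
  cfg <- m$config
  ps <- m$ps
  # two chains with identical features: per-chain pools equal complex pool
  set.seed(7)
  one <- matrix(rnorm(5 * cfg$local_size), 5, cfg$local_size)
  local <- rbind(one, one)
  chain <- rep(1:2, each = 5)
  pooled_in <- sparsebb:::linear(ps, "block1/update/pool_proj", local,
                                 cfg$local_size)
  chain_mean <- rowsum(pooled_in, chain) / 5
  complex_mean <- colMeans(pooled_in)
  expect_lt(max(abs(chain_mean[1, ] - complex_mean)), 1e-9)
  expect_lt(max(abs(chain_mean[2, ] - complex_mean)), 1e-9)
  # permutation within a chain leaves pooled terms invariant
  perm <- c(sample(1:5), sample(6:10))
  pooled_perm <- sparsebb:::linear(ps, "block1/update/pool_proj", local[perm, ],
                                   cfg$local_size)
  expect_lt(max(abs(rowsum(pooled_perm, chain) / 5 - chain_mean)), 1e-9)
})

test_that("position updates: zero weights fix x; unit offset moves 10 A", {
  cfg <- sparsebb:::toyModelConfig()
  m <- denoiserModel(cfg, seed = 20L)
  bb <- makeFixture("helix", length = 8, seed = 1)
  aug <- encodeStructure(m, bb)
  xm <- sparsebb:::flatten_atoms(aug@atoms)
  fr <- sparsebb:::frames_from_xmat(xm)
  local <- matrix(rnorm(8 * cfg$local_size), 8, cfg$local_size)
  m$ps$values[["probe/pos/offsets/w"]] <- matrix(0, cfg$local_size, 60)
  m$ps$values[["probe/pos/offsets/b"]] <- matrix(0, 1, 60)
  out <- sparsebb:::update_positions(m$ps, "probe/pos", local, xm, fr, cfg)
  expect_equal(out, xm)

  # force a unit local-x offset for atom 1 of a residue with identity frame
  co <- array(0, c(1, 4, 3))
  co[1, 1, ] <- c(-0.52, 1.36, 0); co[1, 3, ] <- c(1.53, 0, 0)
  co[1, 4, ] <- c(2, 1, 0)
  xm1 <- cbind(matrix(co[1, 1, ], 1), matrix(co[1, 2, ], 1),
               matrix(co[1, 3, ], 1), matrix(co[1, 4, ], 1),
               matrix(0, 1, 48))
  fr1 <- sparsebb:::frames_from_xmat(xm1)
  l1 <- matrix(1, 1, 1)
  m$ps$values[["unit/pos/offsets/w"]] <- matrix(0, 1, 60)
  m$ps$values[["unit/pos/offsets/w"]][1, 1] <- 1  # atom 1, x component
  m$ps$values[["unit/pos/offsets/b"]] <- matrix(0, 1, 60)
  out1 <- sparsebb:::update_positions(m$ps, "unit/pos", l1, xm1, fr1, cfg)
  expect_equal(out1[1, 1] - xm1[1, 1], 10)
  expect_equal(out1[1, 2:60], xm1[1, 2:60])
})

test_that("denoising is end-to-end equivariant with invariant heads", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 18, seed = 8)
  aug <- encodeStructure(m, bb)
  xt <- applyNoise(aug, noiseSpec("VP", t = 0.4), seed = 9)
  out <- denoiseStructure(m, xt, time = 0.4, seed = 10)
  expect_equal(length(out$trajectory), m$config$n_blocks)
  Q <- random_proper_rotation(11)
  tv <- c(7, -4, 2)
  outT <- denoiseStructure(m, transformStructure(xt, Q, tv), time = 0.4,
                           seed = 10)
  expect_lt(max(abs(transform_xmat(out$xmat, Q, tv) - outT$xmat)), 1e-4)
  expect_lt(max(abs(out$aa_logits - outT$aa_logits)), 1e-4)
  expect_lt(max(abs(out$ss_logits - outT$ss_logits)), 1e-4)
})

test_that("self-conditioning transforms jointly with the input", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 14, seed = 12)
  aug <- encodeStructure(m, bb)
  xt <- applyNoise(aug, noiseSpec("VP", t = 0.5), seed = 13)
  prev <- denoiseStructure(m, xt, time = 0.5, seed = 14)
  cond <- conditioningBundle(selfcond = list(x_prev = prev$xmat,
                                             local_prev = prev$local))
  out <- denoiseStructure(m, xt, cond, time = 0.4, seed = 15)
  Q <- random_proper_rotation(16)
  condT <- conditioningBundle(selfcond = list(
    x_prev = transform_xmat(prev$xmat, Q, c(1, 2, 3)),
    local_prev = prev$local))
  outT <- denoiseStructure(m, transformStructure(xt, Q, c(1, 2, 3)), condT,
                           time = 0.4, seed = 15)
  expect_lt(max(abs(transform_xmat(out$xmat, Q, c(1, 2, 3)) - outT$xmat)), 1e-4)
})

test_that("outputs stay finite at random initialization across seeds", {
  bb <- makeFixture("gaussian_chain", length = 16, seed = 1)
  for (s in 1:20) {
    m <- perturbWeights(denoiserModel(sparsebb:::toyModelConfig(), seed = s),
                        sd = 0.08, seed = s)
    aug <- encodeStructure(m, bb)
    xt <- applyNoise(aug, noiseSpec("VP", t = 0.9), seed = s)
    out <- denoiseStructure(m, xt, time = 0.9, seed = s)
    expect_true(all(is.finite(out$xmat)))
    expect_true(all(is.finite(out$aa_logits)))
  }
})

test_that("non-finite input is rejected before network entry", {
  m <- toy_test_model()
  at <- array(0, c(5, 20, 3))
  aug <- augmentedStructure(at)
  aug@atoms[1, 1, 1] <- NA
  expect_error(denoiseStructure(m, aug), "non-finite")
})

test_that("encoder emits 20 atom slots (5 physical + 15 pseudo), equivariantly", {
  m <- toy_test_model()
  bb <- makeFixture("helix", length = 12, seed = 17)
  aug <- encodeStructure(m, bb)
  expect_equal(dim(aug@atoms), c(12L, 20L, 3L))
  expect_equal(sparsebb:::N_PSEUDO_ATOMS, 15L)
  # physical slots reproduce the backbone + idealized CB
  expect_equal(aug@atoms[, 1:4, ], bb@coords, tolerance = 1e-12)
  expect_equal(aug@atoms[, 5, ], idealizeCb(bb), tolerance = 1e-12)
  Q <- random_proper_rotation(18)
  augT <- encodeStructure(m, transformStructure(bb, Q, c(3, 1, -2)))
  expect_lt(max(abs(transformStructure(aug, Q, c(3, 1, -2))@atoms - augT@atoms)),
            1e-4)
})

test_that("amino-acid decoder: finite logits, invariance, transformed atoms", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 13, seed = 19)
  aug <- encodeStructure(m, bb)
  local <- matrix(rnorm(13 * m$config$local_size, sd = 0.3), 13,
                  m$config$local_size)
  dec <- decodeAminoAcids(m, aug, local)  # fully masked sequence
  expect_true(all(is.finite(dec$aa_logits)))
  expect_equal(dim(dec$aa_logits), c(13L, 20L))
  expect_equal(dim(dec$atoms14), c(13L, 14L, 3L))
  Q <- random_proper_rotation(20)
  decT <- decodeAminoAcids(m, transformStructure(aug, Q, c(1, 1, 1)), local)
  expect_lt(max(abs(dec$aa_logits - decT$aa_logits)), 1e-4)
  at <- sparsebb:::flatten_atoms(dec$atoms14)
  atT <- sparsebb:::flatten_atoms(decT$atoms14)
  expect_lt(max(abs(transform_xmat(at, Q, c(1, 1, 1)) - atT)), 1e-4)
})

test_that("vector quantization picks the nearest codebook entry", {
  set.seed(21)
  codebook <- matrix(rnorm(64 * 8), 64, 8)
  z <- codebook[c(5, 17, 40), ] + 1e-9
  vq <- vqQuantize(z, codebook)
  expect_equal(vq$indices, c(5L, 17L, 40L))
  expect_equal(vq$quantized, codebook[c(5, 17, 40), ], tolerance = 1e-8)
  # brute-force scan oracle on random latents
  z2 <- matrix(rnorm(10 * 8), 10, 8)
  vq2 <- vqQuantize(z2, codebook)
  brute <- apply(z2, 1, function(row)
    which.min(colSums((t(codebook) - row)^2)))
  expect_equal(vq2$indices, as.integer(brute))
  expect_true(all(vq2$indices >= 1L & vq2$indices <= 64L))
})

test_that("autoencoder runs the requested recycles from random positions", {
  m <- toy_test_model()
  bb <- makeFixture("mixed", length = 16, seed = 22)
  res0 <- autoencodeStructure(m, bb, n_recycles = 0L, seed = 1)
  expect_length(res0$decoded, 1L)
  res2 <- autoencodeStructure(m, bb, n_recycles = 2L, seed = 1)
  expect_length(res2$decoded, 3L)
  expect_true(all(is.finite(res2$decoded[[3]]@atoms)))
  resq <- autoencodeStructure(m, bb, n_recycles = 0L, use_vq = TRUE, seed = 1)
  expect_true(all(resq$vq_indices >= 1L &
                    resq$vq_indices <= m$config$vq_codebook))
})
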