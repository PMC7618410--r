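# Noise schedules: cosine VP, VP-scaled, VE, the log-normal sigma sampler
# and shaped-noise initialization.

test_that("cosine schedule endpoints and monotonicity", {
  expect_equal(sigmaOfT(0), 0)
  expect_equal(sigmaOfT(1), 1)
  grid <- seq(0, 1, length.out = 1000)
  expect_true(all(diff(sigmaOfT(grid)) > 0))
  expect_error(sigmaOfT(1.2), "\\[0, 1\\]")
  # signal coefficient is the matching cosine
  expect_equal(sqrt(1 - sigmaOfT(0.3)^2), cos(pi / 2 * 0.3), tolerance = 1e-12)
})

test_that("VP noise is the identity at t = 0 and 10 A at t = 1", {
  bb <- makeFixture("helix", length = 20, seed = 1)
  m <- denoiserModel(sparsebb:::toyModelConfig(), seed = 1)
  aug <- encodeStructure(m, bb)
  expect_equal(applyNoise(aug, noiseSpec("VP", t = 0), seed = 1)@atoms,
               aug@atoms)

  zero <- augmentedStructure(array(0, c(100, 20, 3)))
  draws <- unlist(lapply(1:4, function(s)
    as.vector(applyNoise(zero, noiseSpec("VP", t = 1), seed = s)@atoms)))
  draws <- draws[seq_len(20000)]
  se <- 10 / sqrt(2 * (length(draws) - 1))
  expect_lt(abs(sd(draws) - 10), 3 * se)
})

test_that("VE noise has the right mean and spread", {
  zero <- augmentedStructure(array(0, c(100, 20, 3)))
  draws <- unlist(lapply(1:4, function(s)
    as.vector(applyNoise(zero, noiseSpec("VE", sigma = 5), seed = s)@atoms)))
  draws <- draws[seq_len(20000)]
  expect_lt(abs(mean(draws)), 3 * 5 / sqrt(length(draws)))
  expect_lt(abs(sd(draws) - 5), 3 * 5 / sqrt(2 * (length(draws) - 1)))
})

test_that("VP family variance interpolates as (1-s^2) Var(x) + s^2 sigma^2", {
  set.seed(4)
  base <- array(rnorm(50 * 20 * 3, sd = 7), c(50, 20, 3))
  aug <- augmentedStructure(base)
  for (t in c(0.25, 0.5, 0.75)) {
    s2 <- sigmaOfT(t)^2
    expected_var <- (1 - s2) * stats::var(as.vector(base)) + s2 * 100
    reps <- replicate(30, stats::var(as.vector(
      applyNoise(aug, noiseSpec("VP", t = t))@atoms)))
    expect_lt(abs(mean(reps) - expected_var) / expected_var, 0.1)
  }
})

test_that("VP-scaled endpoints reproduce the CA spread of the input", {
  bb <- makeFixture("gaussian_chain", length = 60, seed = 5)
  bb <- transformStructure(bb, diag(3), -colMeans(caCoords(bb)))
  m <- denoiserModel(sparsebb:::toyModelConfig(), seed = 1)
  aug <- encodeStructure(m, bb)
  s_target <- sparsebb:::sigmaCa(caCoords(aug))
  sds <- replicate(40, sd(as.vector(
    applyNoise(aug, noiseSpec("VP_scaled", t = 1))@atoms)))
  expect_lt(abs(mean(sds) - s_target) / s_target, 0.05)
  expect_error(applyNoise(augmentedStructure(array(0, c(1, 20, 3)), 1L, 1L),
                          noiseSpec("VP_scaled", t = 0.5)), "2 residues")
})

test_that("VE sigma sampler follows LogNormal(1.6, 1.4)", {
  s <- sampleVeSigma(100000L, seed = 0)
  expect_true(all(s > 0))
  ln <- log(s)
  expect_lt(abs(mean(ln) - 1.6), 3 * 1.4 / sqrt(length(ln)))
  expect_lt(abs(sd(ln) - 1.4), 3 * 1.4 / sqrt(2 * (length(ln) - 1)))
})

test_that("shaped centres: counts, chain statistics and compaction", {
  expect_equal(nrow(makeShapedCentres(200, 200, seed = 1)), 1L)
  expect_equal(nrow(makeShapedCentres(1000, 200, seed = 1)), 5L)

  # pre-optimization step offsets are N(0, (10 A)^2) per coordinate
  offs <- do.call(rbind, lapply(seq_len(2000), function(s) {
    ctr <- makeShapedCentres(1000, 200, seed = s, optimize = FALSE)
    diff(ctr)
  }))
  vals <- as.vector(offs)
  se <- 10 / sqrt(2 * (length(vals) - 1))
  expect_lt(abs(sd(vals) - 10), 3 * se)

  # the globularity restraint compacts 5-centre chains on average
  mean_pair <- function(ctr) mean(dist(ctr))
  pre <- post <- numeric(200)
  for (s in 1:200) {
    pre[s] <- mean_pair(makeShapedCentres(1000, 200, seed = s, optimize = FALSE))
    post[s] <- mean_pair(makeShapedCentres(1000, 200, seed = s))
  }
  expect_lt(mean(post), mean(pre))
})

test_that("literal cumulative-sum chain mode is available and different", {
  a <- makeShapedCentres(1000, 200, seed = 3, optimize = FALSE)
  b <- makeShapedCentres(1000, 200, seed = 3, optimize = FALSE,
                         literal_sum = TRUE)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("shaped initial noise: blocking rule and 80 A spread", {
  spec <- shapedNoiseSpec(rbind(c(0, 0, 0), c(300, 0, 0)), 200L)
  assign_id <- centreAssignment(400, 200L)
  expect_equal(assign_id[c(1, 200, 201, 400)], c(1L, 1L, 2L, 2L))
  x <- shapedInitialNoise(spec, 400, seed = 1)
  # residue blocks scatter about their own centres
  m1 <- colMeans(caCoords(x)[1:200, ])
  m2 <- colMeans(caCoords(x)[201:400, ])
  expect_lt(abs(m1[1] - 0), 4 * 80 / sqrt(200))
  expect_lt(abs(m2[1] - 300), 4 * 80 / sqrt(200))

  # pooled residual std over 200 replicates of a single-centre spec
  spec1 <- shapedNoiseSpec(matrix(0, 1, 3), 200L, sigma_init = 80)
  resid <- unlist(lapply(1:200, function(s)
    as.vector(shapedInitialNoise(spec1, 200, seed = s)@atoms[, 2, ])))
  se <- 80 / sqrt(2 * (length(resid) - 1))
  expect_lt(abs(sd(resid) - 80), 3 * se)

  expect_error(shapedInitialNoise(shapedNoiseSpec(matrix(0, 1, 3), 100L), 400),
               "cannot cover")
})

test_that("letter-shape centres from CSV centre their residue clouds", {
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(0, 1, 1), y = c(0, 0, 1)), csv, row.names = FALSE)
  nodes <- readShapeNodes(csv, scale = 100)
  spec <- shapedNoiseSpec(nodes, 200L)
  x <- shapedInitialNoise(spec, 600, seed = 2)
  for (k in 1:3) {
    block <- (k - 1) * 200 + 1:200
    centroid <- colMeans(caCoords(x)[block, ])
    expect_lt(sqrt(sum((centroid - nodes[k, ])^2)), 3 * 80 / sqrt(200) * 2)
  }
})

test_that("all noise samplers are deterministic under a fixed seed", {
  zero <- augmentedStructure(array(0, c(10, 20, 3)))
  expect_identical(applyNoise(zero, noiseSpec("VP", t = 0.5), seed = 7)@atoms,
                   applyNoise(zero, noiseSpec("VP", t = 0.5), seed = 7)@atoms)
  expect_identical(sampleVeSigma(10, seed = 1), sampleVeSigma(10, seed = 1))
  expect_identical(makeShapedCentres(600, 200, seed = 2),
                   makeShapedCentres(600, 200, seed = 2))
})
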