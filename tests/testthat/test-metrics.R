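# Designability, single-linkage TM clustering, the diversity decomposition
# and structure statistics.

test_that("designability counts strict threshold passes", {
  rec <- generationRecords(paste0("d", 1:10),
                           scrmsd = c(rep(1, 3), rep(3, 7)),
                           plddt = c(rep(90, 3), rep(90, 7)))
  expect_equal(designability(rec), 0.3)
  all_good <- generationRecords("a", 1.0, 90)
  expect_equal(designability(all_good), 1.0)
  # boundary records are excluded (strict inequalities)
  boundary <- generationRecords("b", 2.0, 70)
  expect_equal(designability(boundary), 0)
  # configurable cuts
  expect_equal(designability(generationRecords("c", 1.5, 75),
                             plddt_cut = 80), 0)
  expect_error(designability(rec[0, ]), "empty")
})

test_that("single-linkage clustering is transitive and strict", {
  tm <- diag(1, 3)
  tm[1, 2] <- tm[2, 1] <- 0.7
  tm[2, 3] <- tm[3, 2] <- 0.7
  tm[1, 3] <- tm[3, 1] <- 0.1
  expect_equal(singleLinkageClusters(tm), rep(1L, 3))
  # an edge exactly at the threshold does not merge
  tm2 <- diag(1, 2); tm2[1, 2] <- tm2[2, 1] <- 0.6
  expect_equal(singleLinkageClusters(tm2, threshold = 0.6), c(1L, 2L))
  # all-distinct matrix: every item its own cluster
  expect_equal(singleLinkageClusters(diag(1, 4)), 1:4)
  expect_error(singleLinkageClusters(matrix(c(1, 0.2, 0.5, 1), 2, 2)),
               "symmetric")
})

test_that("cluster labels are invariant to input order", {
  set.seed(1)
  n <- 12
  tm <- matrix(runif(n * n, 0, 0.55), n, n)
  tm <- (tm + t(tm)) / 2
  tm[2, 5] <- tm[5, 2] <- 0.9
  tm[7, 8] <- tm[8, 7] <- 0.8
  diag(tm) <- 1
  base <- singleLinkageClusters(tm)
  perm <- sample(n)
  permuted <- singleLinkageClusters(tm[perm, perm])
  # same partition structure after inverting the permutation
  expect_equal(outer(base[perm], base[perm], "=="),
               outer(permuted, permuted, "=="))
})

test_that("diversity decomposition is exact per draw", {
  # 40 designable of 100 forming 10 clusters
  n <- 100
  scrmsd <- c(rep(1, 40), rep(5, 60))
  rec <- generationRecords(paste0("d", 1:n), scrmsd, rep(90, n))
  tm <- diag(1, n)
  # designable structures 1..40 linked into 10 chains of 4
  for (g in 0:9) {
    members <- g * 4 + 1:4
    for (i in members) for (j in members) if (i != j) tm[i, j] <- 0.9
  }
  div <- diversity(rec, tm, subsample = 100, n_draws = 3, seed = 1)
  expect_equal(unname(div$diversity_all["median"]), 0.10)
  expect_equal(unname(div$diversity_designable["median"]), 0.25)
  expect_equal(unname(div$designability["median"]), 0.40)
  # identity holds for every draw
  for (d in div$draws) {
    expect_equal(d$diversity_all,
                 d$diversity_designable * d$designability, tolerance = 1e-12)
    expect_gte(d$diversity_designable, d$diversity_all)
  }
  expect_error(diversity(rec, tm, subsample = 200), "exceeds")
})

test_that("fully designable distinct records give diversity 1", {
  n <- 30
  rec <- generationRecords(paste0("d", 1:n), rep(0.5, n), rep(95, n))
  div <- diversity(rec, diag(1, n), subsample = n, n_draws = 2, seed = 2)
  expect_equal(unname(div$diversity_all["median"]), 1)
  expect_equal(unname(div$diversity_designable["median"]), 1)
})

test_that("secondary-structure statistics: occupancy and entropy", {
  helices <- lapply(1:5, function(s) makeFixture("helix", 20, s))
  stats_h <- ssStatistics(helices)
  expect_equal(sum(stats_h$histogram > 0), 1L)
  expect_equal(stats_h$entropy, 0)
  expect_true(all(abs(rowSums(stats_h$content) - 1) < 1e-12))

  # uniform spread over k bins gives entropy ln k
  mixed <- c(lapply(1:3, function(s) makeFixture("helix", 20, s)),
             lapply(1:3, function(s) makeFixture("strand", 20, s)))
  stats_m <- ssStatistics(mixed)
  expect_equal(stats_m$entropy, log(2), tolerance = 1e-12)
})

test_that("composition statistics: sigma_CA closed form and AA fractions", {
  # hand-computed 3-point toy: CAs at (0,0,0), (3,0,0), (6,0,0)
  co <- array(0, c(3, 4, 3))
  co[, 2, 1] <- c(0, 3, 6)
  co[, 1, ] <- co[, 2, ] + matrix(c(-1.4, 0.5, 0), 3, 3, byrow = TRUE)
  co[, 3, ] <- co[, 2, ] + matrix(c(1.5, 0, 0), 3, 3, byrow = TRUE)
  co[, 4, ] <- co[, 2, ] + matrix(c(2, 1, 0), 3, 3, byrow = TRUE)
  bb <- backboneStructure(co, sequence = c("G", "G", "A"))
  cs <- compositionStats(list(bb))
  # centred CA coords (-3,0,3) on x: pooled per-coordinate sd = sqrt(18/9)
  expect_equal(cs$sigma_ca, sqrt(18 / 9), tolerance = 1e-12)
  expect_equal(cs$gly_fraction, 2 / 3)
  expect_equal(cs$ala_fraction, 1 / 3)
  expect_equal(cs$ala_gly_fraction, 1)

  degenerate <- backboneStructure(array(rep(co[1, , ], each = 1),
                                        c(1, 4, 3)), sequence = "G")
  expect_equal(compositionStats(list(degenerate))$sigma_ca, 0)
})

test_that("record and TM tables round-trip through their file formats", {
  tab <- data.frame(id = rep(c("a", "b"), each = 2), length = 50,
                    scrmsd = c(1.5, 0.8, 2.5, 3.1), plddt = c(80, 85, 60, 65))
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  rec <- readGenerationRecords(f)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$scrmsd[rec$id == "a"], 0.8)  # best sequence kept
  expect_equal(rec$plddt[rec$id == "a"], 85)

  tmtab <- data.frame(id_a = c("a", "b"), id_b = c("b", "a"),
                      tm = c(0.7, 0.65))
  f2 <- tempfile(fileext = ".tsv")
  write.table(tmtab, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  tmm <- readTmMatrix(f2)
  expect_equal(tmm["a", "b"], 0.7)  # asymmetry resolved by the maximum
  expect_equal(tmm["b", "a"], 0.7)
  expect_equal(diag(tmm), c(a = 1, b = 1))
})

test_that("internal TM matrices are symmetric with unit diagonal", {
  structs <- lapply(1:4, function(s) makeFixture("mixed", 30, s))
  tmm <- tmMatrix(structs)
  expect_equal(tmm, t(tmm))
  expect_equal(diag(tmm), rep(1, 4))
  expect_true(all(tmm > 0 & tmm <= 1))
})
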