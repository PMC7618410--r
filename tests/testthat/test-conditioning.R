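# Conditioning construction: random secondary structure, element masking,
# multi-motif masks, contacts/hotspots, the geometric SS assigner and
# training-time dropout.

test_that("random SS strings respect the loop bound and conserve budgets", {
  fractions <- vapply(1:2000, function(s) {
    ss <- sampleRandomSS(128, seed = s)
    expect_equal(length(ss), 128L)
    mean(ss == "L")
  }, numeric(1))
  expect_lte(max(fractions), 0.5)
  # drawn element lengths stay within the heuristic bounds, and the realized
  # per-class counts equal the drawn integer targets exactly
  for (s in 1:50) {
    ss <- sampleRandomSS(200, seed = s)
    el <- attr(ss, "elements")
    expect_true(all(el$len[el$cls == "H"] >= 4 & el$len[el$cls == "H"] <= 30))
    expect_true(all(el$len[el$cls == "E"] >= 3 & el$len[el$cls == "E"] <= 12))
    targets <- attr(ss, "targets")
    expect_equal(unname(sum(ss == "H")), unname(targets["H"]))
    expect_equal(unname(sum(ss == "E")), unname(targets["E"]))
    expect_equal(unname(sum(ss == "L")), unname(targets["L"]))
  }
  expect_error(sampleRandomSS(5), "length >= 10")
})

test_that("short draws can produce helix-only strings", {
  seen_no_strand <- FALSE
  for (s in 1:200) {
    ss <- sampleRandomSS(10, seed = s)
    if (!any(ss == "E") && any(ss == "H")) seen_no_strand <- TRUE
  }
  expect_true(seen_no_strand)
})

test_that("element masking: boundaries unknown, ~50% of elements dropped", {
  # a surviving length-2 element becomes entirely unknown
  ss <- c("L", "H", "H", "L", "L")
  res <- vapply(1:50, function(s)
    paste0(maskSsForConditioning(ss, seed = s), collapse = ""), character(1))
  expect_true(all(res %in% c("LXXLL")))

  # surviving long elements keep their interior
  ss2 <- c(rep("H", 8), rep("L", 3), rep("E", 6))
  kept_interior <- FALSE
  for (s in 1:50) {
    out <- maskSsForConditioning(ss2, seed = s)
    if (all(out[2:7] == "H")) {
      kept_interior <- TRUE
      expect_equal(out[1], "X"); expect_equal(out[8], "X")
    }
  }
  expect_true(kept_interior)

  # fraction of fully-masked elements ~ 0.5 over many elements
  n_full <- 0L; n_el <- 0L
  for (s in 1:2000) {
    out <- maskSsForConditioning(ss2, seed = s)
    n_el <- n_el + 2L
    if (all(out[1:8] == "X")) n_full <- n_full + 1L
    if (all(out[12:17] == "X")) n_full <- n_full + 1L
  }
  se <- sqrt(0.25 / n_el)
  expect_lt(abs(n_full / n_el - 0.5), 3 * se)
})

test_that("multi-motif mask follows the (same group & both active) rule", {
  seg <- data.frame(start = c(1, 21, 41), end = c(20, 40, 60),
                    group = c(1, 2, 1), active = c(TRUE, TRUE, TRUE))
  mm <- makeMultimotifMask(60, segments = seg)
  expect_true(all(mm$mask[1:20, 41:60]))       # same group, both active
  expect_false(any(mm$mask[1:20, 21:40]))      # different groups
  expect_true(isTRUE(all.equal(mm$mask, t(mm$mask))))

  seg$active <- FALSE
  mm0 <- makeMultimotifMask(60, segments = seg)
  expect_false(any(mm0$mask))

  seg_bad <- data.frame(start = c(1, 15), end = c(20, 30), group = 1,
                        active = TRUE)
  expect_error(makeMultimotifMask(60, segments = seg_bad), "overlap")
})

test_that("random segmentation lengths always lie in [10, 50]", {
  for (s in 1:300) {
    mm <- makeMultimotifMask(sample(10:300, 1), seed = s)
    len <- mm$segments$end - mm$segments$start + 1L
    expect_true(all(len >= 10L & len <= 50L))
  }
})

test_that("contacts use a strict 8 A CA threshold and find hotspots", {
  co <- array(0, c(2, 4, 3))
  co[1, , ] <- rbind(c(-1.4, 0.5, 0), c(0, 0, 0), c(1.5, 0, 0), c(2, 1, 0))
  co[2, , ] <- co[1, , ]
  co[2, , 1] <- co[2, , 1] + 7.9
  bb <- backboneStructure(co, residueIndex = c(1, 1), chainIndex = c(1, 2))
  res <- deriveContactsHotspots(bb, ss = c("L", "L"))
  expect_true(res$residue_contacts[1, 2])
  expect_equal(unname(res$hotspots), c(TRUE, TRUE))
  co[2, , 1] <- co[2, , 1] + 0.2  # now 8.1 A apart
  bb2 <- backboneStructure(co, residueIndex = c(1, 1), chainIndex = c(1, 2))
  res2 <- deriveContactsHotspots(bb2, ss = c("L", "L"))
  expect_false(res2$residue_contacts[1, 2])
  expect_equal(unname(res2$hotspots), c(FALSE, FALSE))

  single <- makeFixture("mixed", length = 30, seed = 1)
  expect_false(any(deriveContactsHotspots(single)$hotspots))
})

test_that("contact matrix matches a brute-force recomputation", {
  bb <- makeFixture("gaussian_chain", length = 50, seed = 3)
  res <- deriveContactsHotspots(bb)
  ca <- caCoords(bb)
  brute <- matrix(FALSE, 50, 50)
  for (i in 1:50) for (j in 1:50)
    if (i != j && sqrt(sum((ca[i, ] - ca[j, ])^2)) < 8) brute[i, j] <- TRUE
  expect_equal(unname(res$residue_contacts), brute)
})

test_that("secondary structure assigner labels ideal fixtures correctly", {
  helix <- makeFixture("helix", length = 20, seed = 1)
  ss_h <- assignSecondaryStructure(helix)
  expect_true(all(ss_h[3:17] == "H"))
  strand <- makeFixture("strand", length = 20, seed = 1)
  ss_e <- assignSecondaryStructure(strand)
  expect_true(all(ss_e[3:17] == "E"))
  coil <- makeFixture("gaussian_chain", length = 60, seed = 7)
  expect_gt(mean(assignSecondaryStructure(coil) == "L"), 0.5)
  # chains shorter than the window are all loop
  short <- makeFixture("helix", length = 4, seed = 1)
  expect_equal(assignSecondaryStructure(short), rep("L", 4))
})

test_that("training dropout: whole-bundle rate and masking windows", {
  n <- 200L
  base <- conditioningBundle(
    ss = rep(c("H", "E", "L"), length.out = n),
    sequence = rep("A", n),
    partial_distances = list(dist = matrix(5, n, n),
                             valid = matrix(TRUE, n, n)))
  dropped <- 0L
  frac_ss <- c(); frac_pd <- c()
  for (s in 1:2000) {
    out <- trainingConditioningDropout(base, seed = s)
    if (is.null(out$ss)) {
      dropped <- dropped + 1L
    } else {
      frac_ss <- c(frac_ss, mean(out$ss == "X"))
      frac_pd <- c(frac_pd, attr(out$partial_distances, "masked_fraction"))
    }
  }
  expect_lt(abs(dropped / 2000 - 0.5), 3 * sqrt(0.25 / 2000))
  expect_true(all(frac_pd >= 0.2 - 1 / n & frac_pd <= 0.8 + 1 / n))
  # per-modality masked fraction is uniform on [0.2, 1.0]
  ks <- suppressWarnings(stats::ks.test(frac_ss, "punif", 0.2, 1.0))
  expect_gt(ks$p.value, 0.01)
})

test_that("Eq-style mask symmetry and determinism of samplers", {
  mm1 <- makeMultimotifMask(64, seed = 5)
  mm2 <- makeMultimotifMask(64, seed = 5)
  expect_identical(mm1$mask, mm2$mask)
  expect_identical(sampleRandomSS(64, seed = 9), sampleRandomSS(64, seed = 9))
})
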