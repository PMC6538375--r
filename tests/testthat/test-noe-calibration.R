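# NOE calibration chain: diagonal normalization, sheet distance classes,
# proportionality-constant estimation, bound generation, model-bootstrapped
# methyl recalibration and restraint validation.

test_that("diagonal normalization divides by the geometric mean", {
  pk <- NOEPeakTable(data.frame(
    group_a = c("1.HN", "2.HN", "3.HN"), group_b = c("9.HN", "8.HN", "7.HN"),
    cross = c(0.5, 36, 2), diag_a = c(1, 4, NA), diag_b = c(1, 9, NA)))
  np <- normalizeIntensities(pk)
  expect_true(isNormalized(np))
  expect_equal(peaks(np)$cross[1], 0.5)      # diagonals both 1
  expect_equal(peaks(np)$cross[2], 6)        # divisor sqrt(4 * 9) = 6
  expect_equal(peaks(np)$cross[3], 2)        # flagged pass-through
  expect_true(peaks(np)$flagged[3])
})

test_that("normalization is invariant to a global intensity rescaling", {
  pk <- NOEPeakTable(data.frame(
    group_a = c("1.HN", "2.HN"), group_b = c("9.HN", "8.HN"),
    cross = c(0.4, 1.5), diag_a = c(2, 5), diag_b = c(3, 4)))
  scaled <- NOEPeakTable(within(peaks(pk), {
    cross <- cross * 1000; diag_a <- diag_a * 1000; diag_b <- diag_b * 1000
  })[c("group_a", "group_b", "cross", "diag_a", "diag_b")])
  expect_equal(peaks(normalizeIntensities(scaled))$cross,
               peaks(normalizeIntensities(pk))$cross)
})

test_that("non-positive intensities are rejected at construction", {
  expect_error(NOEPeakTable(data.frame(
    group_a = "1.HN", group_b = "2.HN", cross = -1)), "positive")
  expect_error(NOEPeakTable(data.frame(
    group_a = "1.HN", group_b = "2.HN", cross = 1, diag_a = 0,
    diag_b = 1)), "positive")
})

test_that("sheet distance statistics recover the printed amide-distance classes", {
  sh <- sheetFixture("antiparallel", 2L, 8L)
  st <- sheetDistanceStats(sh$model, sh$pairing, "antiparallel")
  cl <- distanceClasses(st)
  expect_length(cl, 2L)
  expect_lt(abs(cl[1] - 3), 0.5)
  expect_lt(abs(cl[2] - 5), 0.5)
  # an isolated strand has no cross-strand amide pairs
  lone <- makeIdealBackbone(strrep("V", 6), strrep("E", 6))
  expect_error(sheetDistanceStats(lone), "no paired")
})

test_that("calibration recovers c exactly from noiseless intensities", {
  # forced single-peak case: I = 1 at r_ref = 3 gives c = 729
  pk <- NOEPeakTable(data.frame(group_a = "1.HN", group_b = "9.HN",
                                cross = 1, diag_a = 1, diag_b = 1))
  cal <- calibrateConstant(normalizeIntensities(pk), 3.0)
  expect_equal(calibrationConstant(cal), 729)
  # generator round trip on a sheet
  sh <- sheetFixture("antiparallel", 2L, 8L)
  sim <- simulateNOEPeaks(sh$model, c = 512, max_r = 5.5, noise_cv = 0,
                          seed = 2)
  np <- normalizeIntensities(sim)
  tr <- peakTruth(np)
  p <- peaks(np)
  amide <- p$class == "amide-amide"
  r_min <- min(tr$r_true[tr$peak_id %in% p$peak_id[amide]])
  cal2 <- calibrateConstant(np, r_min)
  expect_equal(calibrationConstant(cal2), 512, tolerance = 1e-12)
  expect_error(calibrateConstant(
    NOEPeakTable(data.frame(group_a = "1.CD1", group_b = "2.CD1",
                            cross = 1)), 3), "amide-amide")
})

test_that("noisy calibration matches the closed-form strongest-peak oracle", {
  sh <- sheetFixture("antiparallel", 2L, 8L)
  st <- sheetDistanceStats(sh$model, sh$pairing, "antiparallel")
  r_ref <- min(distanceClasses(st))
  relerr <- numeric(40)
  for (s in seq_along(relerr)) {
    sim <- simulateNOEPeaks(sh$model, c = 729, max_r = 5.5, noise_cv = 0.2,
                            seed = 1000 + s)
    np <- normalizeIntensities(sim)
    cal <- calibrateConstant(np, st)
    # dual route: direct arithmetic on the normalized peak table
    p <- peaks(np)
    expect_equal(calibrationConstant(cal),
                 max(p$cross[p$class == "amide-amide"]) * r_ref^6,
                 tolerance = 1e-12)
    relerr[s] <- abs(calibrationConstant(cal) - 729) / 729
  }
  # The strongest-peak anchor has a max-statistics bias: a closed-form
  # Monte-Carlo of max-of-lognormals over this peak geometry puts the
  # median relative error near 0.27 at 20% intensity noise.
  expect_gt(median(relerr), 0.05)
  expect_lt(median(relerr), 0.45)
})

test_that("bounds invert the sixth-power law, monotonically and clamped", {
  cc <- 729
  pk <- NOEPeakTable(data.frame(
    group_a = c("1.HN", "2.HN", "3.HN"), group_b = c("9.HN", "8.HN", "7.HN"),
    cross = c(cc * 3^-6, cc * 6^-6, 1e-9), diag_a = 1, diag_b = 1))
  np <- normalizeIntensities(pk)
  rl <- boundsFromIntensities(np, cc, pad = 0)
  up <- restraints(rl)$upper
  expect_equal(up[1], 3.0, tolerance = 1e-9)
  expect_equal(up[2] / up[1], 2, tolerance = 1e-9)  # I ratio 64 -> r ratio 2
  expect_equal(up[3], 7.0)                           # weak peak capped
  # antitone in intensity over random tables
  set.seed(7)
  Is <- sort(runif(20, 1e-4, 10), decreasing = TRUE)
  pk2 <- NOEPeakTable(data.frame(
    group_a = sprintf("%d.HN", 1:20), group_b = sprintf("%d.HN", 31:50),
    cross = Is, diag_a = 1, diag_b = 1))
  up2 <- restraints(boundsFromIntensities(normalizeIntensities(pk2), cc))$upper
  expect_true(all(diff(up2) >= -1e-12))
})

test_that("effective distances match a brute-force r^-6 sum and undercut the center distance", {
  m <- twoMethylModel(5)
  pa <- methylProtonCoords(m, 1, "CB")
  pb <- methylProtonCoords(m, 2, "CB")
  expect_equal(effectiveDistance(m, "1.CB", "2.CB"), bruteReff(pa, pb),
               tolerance = 1e-12)
  expect_lt(effectiveDistance(m, "1.CB", "2.CB"), 5.0)
  expect_error(effectiveDistance(m, "1.CD1", "2.CB"), "methyl protons")
})

test_that("model-bootstrapped recalibration bounds behave", {
  m <- twoMethylModel(5)
  pk <- NOEPeakTable(data.frame(group_a = "1.CB", group_b = "2.CB",
                                cross = 0.1, diag_a = 1, diag_b = 1))
  # identical models: zero variance, bound equals r_eff
  ens <- Ensemble(list(m, m, m))
  rl <- recalibrateFromModels(pk, ens, k_sd = 5)
  expect_equal(restraints(rl)$upper, effectiveDistance(m, "1.CB", "2.CB"),
               tolerance = 1e-9)
  expect_error(recalibrateFromModels(pk, Ensemble(list(m, m))), ">= 3")
  amideonly <- NOEPeakTable(data.frame(group_a = "1.HN", group_b = "2.HN",
                                       cross = 1))
  expect_error(recalibrateFromModels(amideonly, ens), "methyl")
})

test_that("recalibrated bounds cover the true distance for most peaks", {
  sh <- sheetFixture("antiparallel", 2L, 6L)
  truth <- simulateNOEPeaks(sh$model, max_r = 5.5, noise_cv = 0, seed = 1)
  p <- peaks(truth)
  tr <- peakTruth(truth)
  methylish <- p$class != "amide-amide"
  covered <- total <- 0
  for (s in 1:25) {
    ens <- perturbEnsemble(sh$model, 5, 0.5, seed = 2000 + s)
    rl <- recalibrateFromModels(truth, ens, k_sd = 1)
    r <- restraints(rl)
    key <- paste(p$group_a, p$group_b)[methylish]
    rt <- tr$r_true[match(p$peak_id[methylish], tr$peak_id)]
    ord <- match(paste(r$group_a, r$group_b), key)
    covered <- covered + sum(r$upper >= rt[ord])
    total <- total + nrow(r)
  }
  expect_gte(covered / total, 0.9)
})

test_that("restraint validation reports violations and conserves totals", {
  sh <- sheetFixture("antiparallel", 2L, 6L)
  m <- sh$model
  pk <- simulateNOEPeaks(m, max_r = 5.5, noise_cv = 0, seed = 1)
  tr <- peakTruth(pk)
  p <- peaks(pk)
  r_true <- tr$r_true[match(p$peak_id, tr$peak_id)]
  # bounds from the model's own distances plus padding: no violations
  rl <- RestraintList(data.frame(group_a = p$group_a, group_b = p$group_b,
                                 upper = pmin(7, pmax(1.8, r_true + 0.5)),
                                 class = p$class))
  rep1 <- validateRestraints(m, rl)
  expect_equal(max(rep1$by_restraint$max_violation), 0)
  # a bound set 1 A below a known distance violates by exactly 1 A
  idx <- which(r_true > 3.3 & r_true < 5.8)[1]
  rl2 <- RestraintList(data.frame(group_a = p$group_a[idx],
                                  group_b = p$group_b[idx],
                                  upper = r_true[idx] - 1,
                                  class = p$class[idx]))
  rep2 <- validateRestraints(m, rl2)
  expect_equal(rep2$by_restraint$max_violation, 1, tolerance = 1e-9)
  # per-model totals equal the sum over restraints
  ens <- perturbEnsemble(m, 3, 0.3, seed = 5)
  rep3 <- validateRestraints(ens, rl)
  expect_equal(sum(rep3$by_model$sum_violation),
               sum(vapply(seq_len(nrow(restraints(rl))), function(i) {
                 sum(vapply(models(ens), function(mm)
                   max(0, effectiveDistance(mm, restraints(rl)$group_a[i],
                                            restraints(rl)$group_b[i]) -
                     restraints(rl)$upper[i]), numeric(1)))
               }, numeric(1))), tolerance = 1e-9)
})

test_that("end-to-end noiseless pipeline bounds never undercut the truth", {
  sh <- sheetFixture("antiparallel", 2L, 8L)
  sim <- simulateNOEPeaks(sh$model, c = 300, max_r = 5.5, noise_cv = 0,
                          seed = 3)
  np <- normalizeIntensities(sim)
  p <- peaks(np)
  tr <- peakTruth(np)
  r_true <- tr$r_true[match(p$peak_id, tr$peak_id)]
  amide <- p$class == "amide-amide"
  cal <- calibrateConstant(np, min(r_true[amide]), pad = 0.5)
  rl <- boundsFromIntensities(np, cal)
  expect_equal(calibrationConstant(cal), 300, tolerance = 1e-9)
  up <- restraints(rl)$upper
  expect_true(all(up >= pmin(r_true, 7.0) - 1e-9))
  # the reference peak's bound minus pad is its true distance
  ref <- which(p$peak_id == cal@ref_peak)
  expect_equal(up[ref] - 0.5, r_true[ref], tolerance = 1e-9)
})
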