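# The cohort generator must reproduce the stated covariate mix, lesion
# geometry, hazard structure and independent censoring, and be bit-identical
# under a fixed seed.

test_that("clinical generator honors effect sizes and determinism", {
  # zero effects: linear predictor identically 0
  g0 <- generate_clinical(50, rep(0, 6), seed = 1)
  expect_true(all(g0$lp == 0))
  # seeded determinism
  a <- generate_clinical(2, rep(0.2, 6), seed = 9)
  b <- generate_clinical(2, rep(0.2, 6), seed = 9)
  expect_identical(a, b)
  # single 0.7 effect on the GTR indicator: exact group difference
  g <- generate_clinical(400, c(0, 0, 0.7, 0, 0, 0), seed = 3)
  gtr <- g$X[, "gtr"] == 1
  expect_equal(mean(g$lp[gtr]) - mean(g$lp[!gtr]), 0.7)
  # dimension mismatch is an explicit error
  expect_error(generate_clinical(10, c(1, 2), seed = 1), "length 6")
})

test_that("volume generator controls the lesion volume fraction", {
  v0 <- generate_volume(0, shape = c(16, 16, 16), seed = 1)
  expect_equal(sum(v0$lesion_mask), 0)
  expect_equal(v0$lesion_fraction, 0)

  v <- generate_volume(0.05, shape = c(32, 32, 32), seed = 5)
  nb <- sum(v$brain_mask)
  frac <- sum(v$lesion_mask) / nb
  expect_lt(abs(frac - 0.05), 1 / nb + 1e-12)
  expect_true(all(v$brain_mask[v$lesion_mask]))  # lesion lies inside the brain

  # same seed, different channel contrasts: identical mask, different voxels
  v1 <- generate_volume(0.08, shape = c(16, 16, 16),
                        channel_contrasts = c(1, 1, 1, 1), seed = 2)
  v2 <- generate_volume(0.08, shape = c(16, 16, 16),
                        channel_contrasts = c(-1, 2, 0.5, 3), seed = 2)
  expect_identical(v1$lesion_mask, v2$lesion_mask)
  expect_false(identical(v1$data, v2$data))
  # identical outside the lesion
  out <- !v1$lesion_mask
  expect_equal(v1$data[1, , , ][out], v2$data[1, , , ][out])
})

test_that("survival sampler reproduces the stated hazards", {
  cuts <- default_cut_points()
  # no censoring: everyone has an event
  sv0 <- sample_survival(rep(0, 50), censoring_rate = 0, seed = 1)
  expect_true(all(sv0$event == 1))

  # per-bin event fraction among at-risk matches logistic(baseline)
  b0 <- stats::qlogis(0.3)
  sv <- sample_survival(rep(0, 2000), baseline_logit_hazard = rep(b0, 5),
                        censoring_rate = 0, seed = 4)
  for (m in 1:5) {
    at_risk <- sum(sv$event_bin >= m)
    frac <- sum(sv$event_bin == m) / at_risk
    se <- sqrt(0.3 * 0.7 / at_risk)
    expect_lt(abs(frac - 0.3), 3 * se)
  }
})

test_that("pairwise death-order frequencies match exhaustive enumeration", {
  bl <- default_baseline_logit_hazard()
  hA <- stats::plogis(bl + 2)
  hB <- stats::plogis(bl - 2)
  pbin <- function(h) {
    p <- numeric(6)
    s <- 1
    for (m in 1:5) { p[m] <- s * h[m]; s <- s * (1 - h[m]) }
    p[6] <- s
    p
  }
  pA <- pbin(hA); pB <- pbin(hB)
  # P(A's continuous time < B's): strictly earlier bin, or same bin with
  # independent uniforms (probability 1/2)
  p_first <- 0
  for (a in 1:6) for (b in 1:6) {
    if (a < b) p_first <- p_first + pA[a] * pB[b]
    if (a == b) p_first <- p_first + 0.5 * pA[a] * pB[b]
  }
  nrep <- 5000
  sv <- sample_survival(rep(c(2, -2), each = nrep), censoring_rate = 0, seed = 11)
  tA <- sv$time_days[seq_len(nrep)]
  tB <- sv$time_days[nrep + seq_len(nrep)]
  emp <- mean(tA < tB)
  se <- sqrt(p_first * (1 - p_first) / nrep)
  expect_lt(abs(emp - p_first), 3 * se)
})

test_that("raising the linear predictor never delays the event bin (fixed randomness)", {
  lp <- rnorm(200)
  a <- sample_survival(lp, censoring_rate = 0, seed = 21)
  b <- sample_survival(lp + 0.8, censoring_rate = 0, seed = 21)
  expect_true(all(b$event_bin <= a$event_bin))
})

test_that("censoring is independent of risk and calibrated to the target rate", {
  lp <- rnorm(2000)
  sv <- sample_survival(lp, censoring_rate = 0.3, seed = 31)
  expect_lt(abs(mean(1 - sv$event) - 0.3), 0.035)
  r <- cor(sv$censor_time, lp)
  expect_lt(abs(r), 3 / sqrt(2000))
})

test_that("oracle concordance behaves at its extremes", {
  # exchangeable subjects: identical hazards give exactly 1/2 by the tie rule
  sv <- sample_survival(rep(0, 80), censoring_rate = 0, seed = 5)
  expect_equal(bayes_optimal_ctd(sv$hazard, sv$time_days, sv$event), 0.5)
  # near-deterministic risk cascade: 6 graded levels, each level dying (with
  # near certainty) one bin later than the previous. Within-level pairs share
  # a bin, so their order is coin-flip/tie and the Antolini ceiling is
  # 1 - 0.5/6 = 0.9167; cross-level pairs are concordant.
  lp <- rep(-12 * (1:6), each = 83)
  sv2 <- sample_survival(lp, baseline_logit_hazard = 12 * (1:5) + 3,
                         censoring_rate = 0, seed = 6)
  v <- bayes_optimal_ctd(sv2$hazard, sv2$time_days, sv2$event)
  expect_gte(v, 0.88)
  expect_lte(v, 1)
})

test_that("cohorts are seed-deterministic and carry consistent ground truth", {
  sc <- synth_config(24, volume_shape = c(16, 16, 16), seed = 8)
  c1 <- generate_cohort(sc)
  c2 <- generate_cohort(sc)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$ground_truth, c2$ground_truth)
  expect_identical(c1$volumes[[3]]$data, c2$volumes[[3]]$data)
  expect_equal(c1$ground_truth$imaging_feature,
               vapply(c1$volumes, function(v) v$lesion_fraction, 0))
  expect_true(all(c1$ground_truth$true_hazard > 0 &
                    c1$ground_truth$true_hazard < 1))
})

test_that("cohorts round-trip to NIfTI and CSV on disk", {
  sc <- synth_config(3, volume_shape = c(16, 16, 16), seed = 2)
  co <- generate_cohort(sc)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "S0001_flair.nii.gz")))
  img <- RNifti::readNifti(file.path(dir, "S0002_t1.nii.gz"))
  expect_equal(dim(img), c(16L, 16L, 16L))
  expect_equal(as.array(img), co$volumes[[2]]$data[1, , , ], ignore_attr = TRUE)
})
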