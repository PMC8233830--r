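test_that("envelope bursts behave as specified in degenerate cases", {
  subj <- subjectParams("S01", noiseFloor = 0)
  eff <- environmentEffect()
  eff$bursts$MG <- rbind(c(0.5, 0.1, 1))
  n <- 201
  env <- makeEnvelope("FGW", "MG", subj, eff, n)
  expect_equal(which.max(env), 101)  # single centered burst peaks mid-stance
  expect_true(all(env >= 0))

  # no bursts, floor 0.1: constant floor x gain
  subj2 <- subjectParams("S02", noiseFloor = 0.1)
  eff2 <- environmentEffect()
  eff2$bursts$MG <- matrix(numeric(0), 0, 3)
  expect_equal(makeEnvelope("US", "MG", subj2, eff2, 50),
               rep(0.1 * subj2$gains[["MG"]], 50))

  expect_error(makeEnvelope("XX", "MG", subj, eff, 10), "unknown environment")
  expect_error(makeEnvelope("FGW", "GAS", subj, eff, 10), "unknown muscle")
})

test_that("zero separation collapses all environments onto flat ground", {
  subj <- subjectParams("S01")
  eff0 <- defaultEnvironmentEffect(separation = 0)
  base <- makeEnvelope("FGW", "Sol", subj, eff0, 300)
  for (e in c("US", "DS", "UW", "DW"))
    expect_equal(makeEnvelope(e, "Sol", subj, eff0, 300), base)
})

test_that("the carrier modulation is reproducible and statistically calibrated", {
  expect_equal(modulateCarrier(rep(0, 5000), 1200, seed = 1), rep(0, 5000))
  expect_error(modulateCarrier(rep(1, 100), 800, seed = 1),
               class = "GaitEnvParameterError")
  x1 <- modulateCarrier(rep(1, 2000), 1200, seed = 7)
  expect_identical(x1, modulateCarrier(rep(1, 2000), 1200, seed = 7))
  # constant envelope c: mean |output| ~ c x E|carrier|, with E|carrier|
  # estimated by Monte Carlo from an independent carrier realization
  cst <- 0.37
  y <- modulateCarrier(rep(cst, 2e5), 1200, seed = 11)
  ref <- modulateCarrier(rep(1, 2e5), 1200, seed = 12)
  expect_lt(abs(mean(abs(y)) - cst * mean(abs(ref))) / (cst * mean(abs(ref))),
            0.05)
})

test_that("the envelope -> carrier -> envelope loop demodulates cleanly", {
  fs <- 1200
  n <- fs  # 1 s stance
  subj <- subjectParams("S01", noiseFloor = 0)
  eff <- environmentEffect()
  eff$bursts$MG <- rbind(c(0.5, 0.12, 1))
  env <- makeEnvelope("FGW", "MG", subj, eff, n)
  raw <- modulateCarrier(env, fs, seed = 3)
  rec <- lowpassEnvelope(rectifySignal(bandpassFilter(raw, fs)), fs)
  expect_gt(cor(rec, env), 0.95)
})

test_that("synthetic vGRF satisfies its construction bounds", {
  fs <- 1200; bw <- 700
  v <- makeVgrf(0.7, fs, bw, pad = 0.2)
  padN <- 0.2 * fs; nStance <- 0.7 * fs
  expect_equal(min(v), 0)
  expect_true(all(v[1:padN] == 0) && all(v[(padN + nStance + 1):length(v)] == 0))
  expect_gte(max(v), 1.0 * bw)
  expect_lte(max(v), 1.3 * bw)
  # first 20 N crossing within 2 samples of the pad boundary
  expect_lte(abs(which(v > 20)[1] - (padN + 1)), 2)
  # strictly above 20 N over the (2%, 98%) core of stance
  core <- (padN + ceiling(0.02 * nStance) + 1):(padN + floor(0.98 * nStance))
  expect_true(all(v[core] > 20))
})

test_that("all randomness derives from the master seed and trial identity", {
  s <- subjectParams("S03")
  t1 <- simulateTrial(s, "DS", "t1", masterSeed = 5)
  t1b <- simulateTrial(s, "DS", "t1", masterSeed = 5)
  expect_identical(emgChannels(t1), emgChannels(t1b))
  expect_identical(vgrf(t1), vgrf(t1b))
  t2 <- simulateTrial(s, "DS", "t2", masterSeed = 5)
  expect_false(identical(emgChannels(t1), emgChannels(t2)))
  tm <- simulateTrial(s, "DS", "t1", masterSeed = 6)
  expect_false(identical(emgChannels(t1), emgChannels(tm)))
})

test_that("study generation has the declared shape and is byte-reproducible", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateStudy(d1, nSubjects = 2, trialsPerEnv = 1, masterSeed = 8)
  expect_equal(nrow(m1), 10)  # 2 subjects x 5 environments x 1 trial
  expect_equal(unname(table(m1$environment)["DW"]), 1 * 2)
  expect_true(all(file.exists(file.path(d1, m1$path))))
  m2 <- generateStudy(d2, nSubjects = 2, trialsPerEnv = 1, masterSeed = 8)
  for (p in m1$path)
    expect_identical(readBin(file.path(d1, p), "raw", 1e6),
                     readBin(file.path(d2, p), "raw", 1e6))
  # round trip through the manifest reader
  trials <- readStudy(file.path(d1, "manifest.csv"))
  expect_length(trials, 10)
  expect_identical(emgChannels(trials[[1]]),
                   emgChannels(simulateTrial(drawSubjectParams("S01", 8),
                                             m1$environment[1],
                                             m1$trial_id[1], masterSeed = 8)))
})

test_that("the default study shape yields 135 trials per environment", {
  # counting only: the full default generation is exercised elsewhere
  m <- expand.grid(t = 1:5, e = walkingEnvironments(), s = 1:27)
  expect_equal(nrow(m), 675)
  expect_equal(sum(m$e == "FGW"), 135)
})
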