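fs <- 1200
tt <- seq(0, 2, by = 1 / fs)
interior <- function(x, fs, edge = 0.25) {
  n <- length(x)
  x[ceiling(edge * fs):(n - ceiling(edge * fs))]
}

test_that("band-pass rejects DC, passes 100 Hz, attenuates 5 Hz", {
  dc <- bandpassFilter(rep(1, length(tt)), fs)
  expect_lt(max(abs(interior(dc, fs))), 0.01)
  s100 <- bandpassFilter(sin(2 * pi * 100 * tt), fs)
  expect_lt(abs(max(abs(interior(s100, fs))) - 1), 0.02)
  s5 <- bandpassFilter(sin(2 * pi * 5 * tt), fs)
  expect_lt(max(abs(interior(s5, fs))), 0.1)
  expect_error(bandpassFilter(tt, fs, high = 600),
               class = "GaitEnvParameterError")
})

test_that("rectification is |x| and matches the half-normal mean", {
  expect_equal(rectifySignal(c(-1, 2, -3)), c(1, 2, 3))
  x <- c(0, 1.5, 7)
  expect_identical(rectifySignal(x), x)
  z <- withr::with_seed(1, rnorm(1e5))
  expect_lt(abs(mean(rectifySignal(z)) - sqrt(2 / pi)) / sqrt(2 / pi), 0.02)
})

test_that("low-pass envelope has unit DC gain and demodulates |sin|", {
  const <- lowpassEnvelope(rep(3, length(tt)), fs)
  expect_lt(max(abs(interior(const, fs) - 3)) / 3, 0.01)
  # mean of |sin| is 2/pi: the envelope of a rectified tone is near-constant
  env <- lowpassEnvelope(abs(sin(2 * pi * 100 * tt)), fs)
  expect_lt(max(abs(interior(env, fs) - 2 / pi)) / (2 / pi), 0.05)
  # a 1 Hz raised-cosine amplitude modulation survives the 10 Hz cut-off
  mod <- 0.5 * (1 - cos(2 * pi * 1 * tt))
  rec <- lowpassEnvelope(abs(sin(2 * pi * 150 * tt)) * mod, fs)
  expect_gt(cor(interior(rec, fs), interior(mod, fs)), 0.99)
  expect_true(all(lowpassEnvelope(rnorm(1000), fs) >= 0))
})

test_that("time normalization is exact on linear input and identity on the grid", {
  for (L in c(2, 37, 1000, 1731)) {
    ramp <- seq(0, 1, length.out = L)
    out <- timeNormalize(ramp, 1000)
    expect_equal(out, seq(0, 1, length.out = 1000), tolerance = 1e-12)
  }
  expect_equal(timeNormalize(rep(2.5, 50)), rep(2.5, 1000))
  x <- rnorm(1000)
  expect_equal(timeNormalize(x), x)
  expect_error(timeNormalize(1), class = "GaitEnvParameterError")
})

test_that("normalization reference uses stance-only peaks, maximized over trials", {
  win <- IRanges::IRanges(11, 20)
  mk <- function(inPeak, outPeak) {
    env <- matrix(0.01, 30, 1, dimnames = list(NULL, "MG"))
    env[15, 1] <- inPeak; env[25, 1] <- outPeak
    list(envelopes = env, window = win)
  }
  ref <- computeNormalizationReference(list(mk(0.8, 1.2)), "S01")
  expect_equal(unname(ref@peaks["MG"]), 0.8)  # outside-stance 1.2 ignored
  ref2 <- computeNormalizationReference(list(mk(0.7, 0), mk(0.9, 0)), "S01")
  expect_equal(unname(ref2@peaks["MG"]), 0.9)
  ref1 <- computeNormalizationReference(list(mk(0.7, 0), mk(0.9, 0)), "S01",
                                        mode = "single")
  expect_equal(unname(ref1@peaks["MG"]), 0.7)
  zero <- list(list(envelopes = matrix(0, 30, 1,
                                       dimnames = list(NULL, "MG")),
                    window = win))
  expect_error(computeNormalizationReference(zero, "S01"),
               class = "GaitEnvDegenerateReference")
})

test_that("normalization is self-consistent and scale-invariant", {
  ref <- new("NormalizationReference", subjectId = "S01",
             peaks = c(MG = 0.5))
  expect_equal(normalizeEnvelope(rep(0.5, 10), ref, "MG"), rep(1, 10))
  x <- runif(20)
  ref2 <- new("NormalizationReference", subjectId = "S01",
              peaks = c(MG = 1.0))
  expect_equal(normalizeEnvelope(2 * x, ref2, "MG") / 2,
               normalizeEnvelope(x, ref2, "MG"))
  expect_error(normalizeEnvelope(x, ref, "TA"),
               class = "GaitEnvMissingReference")
})

test_that("profile assembly concatenates 1000 points per muscle in canonical order", {
  study <- smallStudy()
  trial <- study$trials[[1]]
  proc <- lapply(Filter(function(tr) subjectId(tr) == subjectId(trial) &&
                          environmentLabel(tr) == "FGW", study$trials),
                 processTrial)
  ref <- computeNormalizationReference(proc, subjectId(trial))
  p11 <- buildProfile(trial, ref = ref)
  expect_length(p11, 11000)
  p1 <- buildProfile(trial, ref = ref, muscles = "MG")
  expect_length(p1, 1000)
  p3 <- buildProfile(trial, ref = ref, muscles = c("MG", "LG", "Sol"))
  expect_length(p3, 3000)
  # canonical order puts Sol before MG before LG
  expect_equal(p3, c(buildProfile(trial, ref = ref, muscles = "Sol"),
                     buildProfile(trial, ref = ref, muscles = "MG"),
                     buildProfile(trial, ref = ref, muscles = "LG")))
  expect_error(buildProfile(trial, ref = ref, muscles = "GAS"),
               "unknown muscle")
})

test_that("envelope chain is linear in the input up to normalization", {
  x <- withr::with_seed(3, rnorm(2400))
  e1 <- linearEnvelope(x, fs)
  e3 <- linearEnvelope(3 * x, fs)
  expect_equal(e3, 3 * e1, tolerance = 1e-10)
})

test_that("filtering full trials then cropping agrees with padded-window filtering", {
  tr <- simulateTrial(subjectParams("S01"), "FGW", "t1", masterSeed = 9,
                      pad = 0.25)
  w <- detectStance(vgrf(tr), samplingRate(tr))
  raw <- emgChannels(tr)[, "MG"]
  full <- cropToWindow(linearEnvelope(raw, samplingRate(tr)), w)
  padN <- 0.2 * samplingRate(tr)
  lo <- IRanges::start(w) - padN; hi <- IRanges::end(w) + padN
  seg <- linearEnvelope(raw[lo:hi], samplingRate(tr))
  cropped <- seg[(padN + 1):(padN + IRanges::width(w))]
  rmsRel <- sqrt(mean((full - cropped)^2)) / sqrt(mean(full^2))
  expect_lt(rmsRel, 0.01)
})

test_that("recovered normalized profiles track the generator's ground truth", {
  sim <- simulateTrial(subjectParams("S05"), "UW", "t1", masterSeed = 21,
                       withTruth = TRUE)
  proc <- processTrial(sim$trial)
  rec <- cropToWindow(proc$envelopes[, "MG"], proc$window)
  truth <- sim$truth[, "MG"]
  r <- cor(timeNormalize(rec), timeNormalize(truth))
  expect_gt(r, 0.95)
})
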