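test_that("the generator honors its multiplicative model exactly", {
  # null model: every run equals the baseline
  te0 <- simulateResponses(effects = list(), noiseSD = 0, baseline = 25)
  expect_true(all(responses(te0) == 25))

  # single factor: level-3 runs are 10^0.2 times level-1 runs
  te <- simulateResponses(effects = list(ec = c(-0.1, 0, 0.1)), noiseSD = 0)
  dm <- designMatrix(te)
  y <- responses(te)["response", ]
  expect_equal(unique(y[dm[, "ec"] == 3] / y[dm[, "ec"] == 1]), 10^0.2)

  # full evaluation against the generator formula, run by run
  effects <- list(co2 = c(-0.03, 0.01, 0.02), humidity = c(-0.1, 0.04, 0.06))
  te2 <- simulateResponses(effects = effects, noiseSD = 0, baseline = 12)
  y2 <- responses(te2)["response", ]
  for (r in 1:27) {
    expo <- effects$co2[dm[r, "co2"]] + effects$humidity[dm[r, "humidity"]]
    expect_equal(unname(y2[r]), 12 * 10^expo)
  }
})

test_that("simulation is deterministic given the seed", {
  a <- simulateResponses(effects = list(ec = c(-0.1, 0, 0.1)),
                         noiseSD = 0.05, seed = 123)
  b <- simulateResponses(effects = list(ec = c(-0.1, 0, 0.1)),
                         noiseSD = 0.05, seed = 123)
  c2 <- simulateResponses(effects = list(ec = c(-0.1, 0, 0.1)),
                          noiseSD = 0.05, seed = 124)
  expect_identical(responses(a), responses(b))
  expect_false(identical(responses(a), responses(c2)))
  expect_error(simulateResponses(noiseSD = 0.05), "seed")
})

test_that("the generator rejects non-identifiable specs", {
  expect_error(simulateResponses(effects = list(ec = c(0.1, 0.1, 0.1)),
                                 noiseSD = 0), "summing to 0")
  expect_error(simulateResponses(effects = list(soil = c(-0.1, 0, 0.1)),
                                 noiseSD = 0), "absent from design")
  expect_error(simulateResponses(
    interactionEffects = list(list(factors = c("ec", "led"),
                                   offsets = matrix(0.1, 3, 3))),
    noiseSD = 0), "doubly centered")
  expect_error(simulateResponses(baseline = -1, noiseSD = 0), "baseline")
})

test_that("dB level means recover the generating offsets up to a constant", {
  effects <- list(led = c(-0.08, 0.02, 0.06), night_temp = c(0.05, 0, -0.05))
  te <- simulateResponses(effects = effects, noiseSD = 0, baseline = 25)
  me <- mainEffects(te, "response")
  for (f in names(effects)) {
    row <- me@table[me@table$factor == f, ]
    got <- unlist(row[c("level1", "level2", "level3")])
    want <- 20 * effects[[f]]  # dB scale; common constant = grand mean
    expect_equal(unname(got - mean(got)), unname(want), tolerance = 1e-9)
  }
})

test_that("interaction offsets surface in the non-parallelism score", {
  gamma <- matrix(c(0.04, -0.02, -0.02,
                    -0.02, 0.04, -0.02,
                    -0.02, -0.02, 0.04), 3, 3, byrow = TRUE)
  te <- simulateResponses(
    interactionEffects = list(list(factors = c("co2", "ec"), offsets = gamma)),
    noiseSD = 0)
  m <- interactionCellMeans(te, "response", "co2", "ec")
  expect_gt(nonparallelism(m), 0)
  te0 <- simulateResponses(effects = list(co2 = c(-0.1, 0, 0.1)), noiseSD = 0)
  expect_equal(nonparallelism(
    interactionCellMeans(te0, "response", "co2", "ec")), 0, tolerance = 1e-12)
})

test_that("noise-free recovery is perfect for factors with a unique argmax", {
  r <- recoveryExperiment(list(ec = c(-0.1, 0, 0.1),
                               led = c(0.05, -0.02, -0.03)),
                          noiseSD = 0, nReps = 3, seed = 5)
  expect_equal(unname(r$levelRecovery[c("ec", "led")]), c(1, 1))
  # factors with all-zero offsets have no unique argmax
  expect_true(all(is.na(r$levelRecovery[c("co2", "day_temp")])))
})

test_that("with zero effects and noise, recovered levels are uniform", {
  # all offsets zero: the recovered best level of any factor is pure noise
  # and should be uniform on {1,2,3} across replicates
  counts <- integer(3)
  set.seed(17)
  seeds <- sample.int(.Machine$integer.max - 1L, 900)
  for (s in seeds) {
    te <- simulateResponses(effects = list(), noiseSD = 0.2, seed = s)
    lv <- bestLevels(mainEffects(te, "response"))["humidity"]
    counts[lv] <- counts[lv] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 1e-4)
})
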