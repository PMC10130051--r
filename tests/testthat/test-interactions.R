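test_that("cell means average exactly 3 runs per cell on the L27", {
  te <- loadStudy("lettuce", "growth")
  dm <- designMatrix(te)
  sn <- 20 * log10(responses(te)["fresh_leaf", ])
  m <- interactionCellMeans(te, "fresh_leaf", "ec", "humidity")
  for (i in 1:3) for (j in 1:3) {
    sel <- dm[, "ec"] == i & dm[, "humidity"] == j
    expect_identical(sum(sel), 3L)
    expect_equal(unname(m[i, j]), mean(sn[sel]))
  }
  expect_error(interactionCellMeans(te, "fresh_leaf", "ec", "ec"), "differ")
})

test_that("non-parallelism score is zero iff the profile lines are parallel", {
  # additive matrices score 0
  set.seed(21)
  for (rep in 1:10) {
    r <- rnorm(3); cl <- rnorm(3)
    add <- outer(r, cl, "+")
    expect_equal(nonparallelism(add), 0, tolerance = 1e-12)
    # the two line-profiles of an additive matrix are exactly parallel
    expect_equal(add[, 1] - add[, 2], rep(cl[1] - cl[2], 3))
    # any single-cell bump breaks parallelism and scores 4d/9
    d <- runif(1, 0.1, 2)
    bump <- add; bump[2, 3] <- bump[2, 3] + d
    expect_equal(nonparallelism(bump), 4 * d / 9, tolerance = 1e-12)
    expect_equal(nonparallelism(bump), max(abs(resid_matrix(bump))))
  }
  expect_equal(nonparallelism(matrix(5, 3, 3)), 0)
})

test_that("score is invariant to constants and factor swap", {
  set.seed(22)
  for (rep in 1:10) {
    m <- matrix(rnorm(9), 3, 3)
    expect_equal(nonparallelism(m + 17.3), nonparallelism(m))
    expect_equal(nonparallelism(t(m)), nonparallelism(m))
  }
  cm <- interactionCellMeans(loadStudy("basil"), "fresh_leaf", "co2", "led")
  cm_t <- interactionCellMeans(loadStudy("basil"), "fresh_leaf", "led", "co2")
  expect_equal(nonparallelism(cm), nonparallelism(cm_t))
})

test_that("noise-free effect-free data scores zero on all 15 pairs", {
  te <- simulateResponses(effects = list(), noiseSD = 0)
  ix <- interactionSummary(te, "response", threshold = 1e-9)
  expect_identical(nrow(ix), 15L)
  expect_true(all(ix$score_db < 1e-9))
  expect_false(any(ix$interacting))
})

test_that("saturated-array aliasing bleeds main effects into aliased pairs only", {
  # On this L27, EC is the GF(3) sum of the CO2 and LED columns, so a pure
  # EC main effect e is indistinguishable from a CO2 x LED interaction: the
  # (co2, led) cell matrix becomes M(i,j) = const + e[(i+j-1) %% 3 + 1],
  # whose rows and columns all average to the same constant, leaving the
  # full e as non-additive residual.
  e <- c(-0.1, 0.02, 0.08)
  te <- simulateResponses(effects = list(ec = e), noiseSD = 0)
  m <- interactionCellMeans(te, "response", "co2", "led")
  expect_equal(nonparallelism(m), 20 * max(abs(e)), tolerance = 1e-9)
  # pairs whose span excludes the EC column stay exactly additive:
  # span(led, humidity) = {b, a+c, a+b+c, a+2b+c} over the run digits
  m2 <- interactionCellMeans(te, "response", "led", "humidity")
  expect_equal(nonparallelism(m2), 0, tolerance = 1e-9)
})

test_that("an injected pairwise interaction ranks first", {
  # gamma built from two alias components g1 (on the co2+led line = EC
  # column) and g2 (on the co2+2*led line = day-temperature column); the
  # injected pair sees g1 + g2 jointly while any contaminated pair sees at
  # most one component, so the injected pair scores strictly highest.
  g1 <- c(0.06, -0.03, -0.03)
  g2 <- c(0.04, 0, -0.04)
  gamma <- outer(1:3, 1:3, function(i, j)
    g1[(i + j - 2) %% 3 + 1] + g2[(i + 2 * j) %% 3 + 1])
  te <- simulateResponses(
    interactionEffects = list(list(factors = c("co2", "led"),
                                   offsets = gamma)),
    noiseSD = 0)
  ix <- interactionSummary(te, "response")
  expect_identical(c(ix$factor_a[1], ix$factor_b[1]), c("co2", "led"))
  expect_true(ix$interacting[1])
  expect_gt(ix$score_db[1], ix$score_db[2] + 1e-9)
  # oracle: the injected pair's score is max|gamma| in dB
  expect_equal(ix$score_db[1], 20 * max(abs(gamma)), tolerance = 1e-9)
})

test_that("EC x humidity scores among the lowest pairs on the growth fixtures", {
  for (sp in c("lettuce", "basil")) {
    ix <- interactionSummary(loadStudy(sp, "growth"), "fresh_leaf")
    pos <- which((ix$factor_a == "ec" & ix$factor_b == "humidity") |
                 (ix$factor_a == "humidity" & ix$factor_b == "ec"))
    expect_gte(pos, 11L)  # bottom third of the descending ranking
  }
})
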