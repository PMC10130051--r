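test_that("snRatio matches its defining formulas", {
  expect_equal(snRatio(1), 0)
  expect_equal(snRatio(10), 20)
  expect_equal(snRatio(52.50), 20 * log10(52.50))
  expect_equal(snRatio(52.50), 34.40, tolerance = 1e-3)

  set.seed(1)
  for (rep in 1:10) {
    y <- runif(sample(1:6, 1), 0.1, 50)
    expect_equal(snRatio(y, "larger"), -10 * log10(sum(1 / y^2) / length(y)))
    expect_equal(snRatio(y, "smaller"), -10 * log10(sum(y^2) / length(y)))
    if (length(y) >= 2)
      expect_equal(snRatio(y, "nominal"),
                   10 * log10(mean(y)^2 / var(y)))
  }
  expect_error(snRatio(c(2, -1), "larger"), "positive")
  expect_error(snRatio(3, "nominal"), "at least 2")
  expect_error(snRatio(c(5, 5), "nominal"), "zero variance")
  expect_error(snRatio(numeric(0)), "non-empty")
})

test_that("larger-is-better S/N is strictly increasing in each value", {
  set.seed(7)
  for (rep in 1:20) {
    y <- runif(5, 0.01, 100)
    base <- snRatio(y, "larger")
    i <- sample(5, 1)
    y2 <- y; y2[i] <- y2[i] * (1 + runif(1, 0.01, 1))
    expect_gt(snRatio(y2, "larger"), base)
  }
})

test_that("snValues applies the n=1 S/N cell-wise", {
  te <- loadStudy("lettuce", "growth")
  sn <- snValues(te)
  expect_identical(dim(sn), dim(responses(te)))
  # agrees with snRatio applied one cell at a time
  for (cell in list(c(1, 1), c(3, 25), c(7, 27)))
    expect_equal(sn[cell[1], cell[2]],
                 snRatio(responses(te)[cell[1], cell[2]]))
  # maximal fresh-leaf S/N at run 25, the largest printed value
  expect_identical(colnames(sn)[which.max(sn["fresh_leaf", ])], "run25")
  expect_true(all(is.finite(sn)))
  expect_error(snValues(te, "nominal"), "replicate")
})

test_that("main effects equal brute-force level means of the fixture", {
  te <- loadStudy("lettuce", "growth")
  me <- mainEffects(te, "fresh_leaf")
  dm <- designMatrix(te)
  sn <- 20 * log10(responses(te)["fresh_leaf", ])
  for (f in colnames(dm)) {
    oracle <- group_means(sn, dm[, f])
    row <- me@table[me@table$factor == f, ]
    expect_equal(unlist(row[c("level1", "level2", "level3")]), oracle,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(row$delta, max(oracle) - min(oracle))
  }
  # EC level means as independently derived from the printed tables
  ec <- me@table[me@table$factor == "ec", ]
  expect_equal(c(ec$level1, ec$level2, ec$level3),
               c(26.40, 30.40, 27.68), tolerance = 2e-4)
  expect_equal(ec$delta, 4.00, tolerance = 2e-3)
  expect_identical(ec$rank, 1L)
  expect_identical(sort(me@table$rank), 1:6)
})

test_that("balance identity: mean of level means equals the grand mean", {
  for (sp in c("lettuce", "basil")) {
    te <- loadStudy(sp, "all")
    for (p in rownames(te)) {
      me <- mainEffects(te, p)
      lm <- as.matrix(me@table[, c("level1", "level2", "level3")])
      expect_true(all(abs(rowMeans(lm) - me@grandMean) < 1e-9))
    }
  }
})

test_that("argmax of mean S/N equals argmax of mean log response at n=1", {
  te <- loadStudy("basil", "all")
  dm <- designMatrix(te)
  for (p in rownames(te)) {
    bl <- bestLevels(te, p)
    logy <- log(responses(te)[p, ])
    for (f in colnames(dm))
      expect_identical(unname(bl[f]),
                       unname(which.max(group_means(logy, dm[, f]))))
  }
})

test_that("a single active factor ranks first; constant tables tie cleanly", {
  te <- simulateResponses(effects = list(day_temp = c(-0.1, 0, 0.1)),
                          noiseSD = 0)
  me <- mainEffects(te, "response")
  expect_identical(me@table$rank[me@table$factor == "day_temp"], 1L)
  expect_equal(me@table$delta[me@table$factor != "day_temp"],
               rep(0, 5), tolerance = 1e-12)

  const <- simulateResponses(effects = list(), noiseSD = 0)
  me0 <- mainEffects(const, "response")
  expect_equal(me0@table$delta, rep(0, 6), tolerance = 1e-12)
  # tie-break by design factor order, all flagged
  expect_identical(me0@table$rank, 1:6)
  expect_true(all(me0@table$tie))
})

test_that("best levels reproduce the study's headline EC optima", {
  expect_identical(unname(bestLevels(loadStudy("lettuce"), "fresh_leaf")["ec"]), 2L)
  expect_identical(unname(bestLevels(loadStudy("basil"), "fresh_leaf")["ec"]), 3L)
})

test_that("exact level ties resolve to the lowest level and are flagged", {
  te <- simulateResponses(effects = list(ec = c(0.1, 0.1, -0.2)), noiseSD = 0)
  bl <- bestLevels(mainEffects(te, "response"))
  expect_identical(unname(bl["ec"]), 1L)
  expect_true(attr(bl, "tie")["ec"])
  # inactive factors have three equal level means, so they are tied too
  expect_true(all(attr(bl, "tie")))
})
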