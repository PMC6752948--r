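test_that("hierarchical aggregation averages per parent then per animal", {
  d <- data.frame(unit = 1:2, parent = c("i1", "i2"), animal = "m1",
                  group = "WT", metric = "x", value = c(2, 4))
  expect_equal(aggregateStudy(d)$value, 3)
  one <- data.frame(unit = 1, parent = "i1", animal = "m1", group = "WT",
                    metric = "x", value = 5)
  expect_equal(aggregateStudy(one)$value, 5)

  set.seed(9)
  big <- data.frame(unit = 1:60,
                    parent = rep(sprintf("i%d", 1:12), each = 5),
                    animal = rep(sprintf("m%d", 1:4), each = 15),
                    group = rep(c("WT", "KO"), each = 30),
                    metric = "y", value = rnorm(60))
  got <- aggregateStudy(big)
  # nested group-by oracle
  for (m in unique(big$animal)) {
    sub <- big[big$animal == m, ]
    want <- mean(tapply(sub$value, sub$parent, mean))
    expect_equal(got$value[got$animal == m], want)
  }
  # permutation invariance
  perm <- big[sample(nrow(big)), ]
  expect_equal(aggregateStudy(perm), got)
  dup <- rbind(d, d[1, ])
  expect_error(aggregateStudy(dup), "duplicate")
})

test_that("extreme-outlier rule flags strictly above Q3 + 3 IQR", {
  x <- c(1, 2, 3, 4, 100)
  fl <- extremeOutlierFlags(x)
  expect_identical(which(fl), 5L)
  expect_equal(attr(fl, "upperBound"), 10)  # Q1 = 2, Q3 = 4 (type 7)
  expect_false(any(extremeOutlierFlags(rep(5, 6))))
  # a value exactly at the bound is kept
  y <- c(1, 2, 3, 4)
  b <- attr(extremeOutlierFlags(y), "upperBound")
  expect_false(any(extremeOutlierFlags(c(y, b))))
  expect_warning(extremeOutlierFlags(c(1, 2, 3)), "fewer than 4")
  # lower tail only on request
  z <- c(10, 11, 12, 13, -100)
  expect_false(any(extremeOutlierFlags(z)))
  expect_true(any(extremeOutlierFlags(z, lower = TRUE)))
  # adding one far value flags it and only it
  w <- c(5, 6, 7, 8, 9, 1000)
  expect_identical(which(extremeOutlierFlags(w)), 6L)
})

test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(oracleMannWhitneyP(x, y), 0.1)
  w <- wilcox.test(x, y)
  expect_equal(w$p.value, 0.1)
  expect_equal(unname(w$statistic), 0)
  # a second configuration, enumeration vs exact test
  x2 <- c(1, 4, 7); y2 <- c(2, 3, 9)
  expect_equal(wilcox.test(x2, y2)$p.value, oracleMannWhitneyP(x2, y2))
})

test_that("D'Agostino-Pearson omnibus test reproduces reference values", {
  # reference statistics computed with an independent implementation of the
  # same published formulas
  set.seed(2)
  x <- rnorm(50)
  y <- rexp(50)
  dx <- dagostinoPearson(x)
  expect_equal(dx$statistic, 0.1578529, tolerance = 1e-6)
  expect_equal(dx$p, 0.9241079, tolerance = 1e-6)
  dy <- dagostinoPearson(y)
  expect_equal(dy$statistic, 22.65446, tolerance = 1e-5)
  expect_equal(dy$p, 1.204058e-05, tolerance = 1e-4)
  expect_error(dagostinoPearson(rnorm(5)), "n >= 8")
})

test_that("Dunn post hoc z matches a hand-computed case", {
  v <- 1:6
  g <- rep(c("a", "b"), each = 3)
  dn <- dunnTest(v, g)
  # mean ranks 2 and 5; sigma = sqrt(3.5 * 2/3)
  zExp <- (2 - 5) / sqrt(3.5 * 2 / 3)
  expect_equal(dn$z, zExp, tolerance = 1e-12)
  expect_equal(dn$p, 2 * pnorm(-abs(zExp)), tolerance = 1e-12)
})

test_that("test selection follows the assay-specific decision rule", {
  set.seed(10)
  # imaging: always Mann-Whitney
  ci <- compareGroups(c(rnorm(6), rnorm(6, 2)),
                      rep(c("WT", "KO"), each = 6), assay = "imaging")
  expect_identical(ci@test, "Mann-Whitney U")
  # identical groups: not significant under any rule
  same <- rep(1:8, 2)
  cs <- compareGroups(same, rep(c("WT", "KO"), each = 8), assay = "imaging")
  expect_gt(cs@p, 0.05)

  # autapse: normal data -> ANOVA/Tukey; skewed -> Kruskal-Wallis/Dunn
  vn <- c(rnorm(30), rnorm(30, 0.5), rnorm(30, 1))
  gn <- rep(c("WT", "KO", "rescue"), each = 30)
  can <- compareGroups(vn, gn, assay = "autapse")
  expect_identical(can@test, "one-way ANOVA + Tukey")
  expect_identical(nrow(can@posthoc), 3L)
  vs <- c(rexp(30), rexp(30), rexp(30))
  csk <- compareGroups(vs, gn, assay = "autapse")
  expect_identical(csk@test, "Kruskal-Wallis + Dunn")
  # small groups force the nonparametric branch with a warning
  expect_warning(
    csm <- compareGroups(c(rnorm(5), rnorm(5)),
                         rep(c("WT", "KO"), each = 5), assay = "autapse"),
    "n < 8")
  expect_identical(csm@test, "Kruskal-Wallis + Dunn")

  # EM: normal -> Welch t (equal to a direct call); skewed -> Mann-Whitney
  ve <- c(rnorm(40, 1), rnorm(40, 1.4))
  ge <- rep(c("WT", "KO"), each = 40)
  cem <- compareGroups(ve, ge, assay = "em")
  expect_identical(cem@test, "Welch t")
  expect_equal(cem@p, t.test(ve[1:40], ve[41:80])$p.value)
  cex <- compareGroups(c(rexp(40), rexp(40, 0.5)), ge, assay = "em")
  expect_identical(cex@test, "Mann-Whitney U")
})

test_that("the normality gate routes skewed cohorts to the nonparametric branch", {
  picks <- vapply(1:200, function(s) {
    set.seed(s)
    v <- c(rexp(30), rexp(30))
    g <- rep(c("WT", "KO"), each = 30)
    compareGroups(v, g, assay = "autapse")@test
  }, character(1))
  expect_gte(mean(picks == "Kruskal-Wallis + Dunn"), 0.95)
})

test_that("percent change reporting", {
  expect_equal(percentChange(174, 115), 100 * (174 / 115 - 1))
  expect_equal(percentChange(100, 100), 0)
})
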