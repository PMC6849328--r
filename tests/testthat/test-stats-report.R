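# Outlier rule and group-comparison statistics.

test_that("Grubbs rule removes at most the single most extreme point", {
  res <- removeOneOutlierPerGroup(
    data.frame(value = c(1, 1.1, 0.9, 1, 100), group = "g"))
  expect_identical(res$removed$value, 100)
  expect_identical(nrow(res$table), 4L)

  # two gross outliers in one group: still only one removal
  res2 <- removeOneOutlierPerGroup(
    data.frame(value = c(rep(1, 8), 50, 100), group = "g"))
  expect_identical(nrow(res2$removed), 1L)
  expect_identical(res2$removed$value, 100)

  # undersized group passes through with a warning
  expect_warning(
    res3 <- removeOneOutlierPerGroup(
      data.frame(value = c(1, 2), group = "g")), "fewer than 3")
  expect_identical(nrow(res3$table), 2L)

  # removing then re-inserting restores the original table
  tbl <- data.frame(value = c(1, 1.2, 0.8, 1.1, 30), group = "g")
  r <- removeOneOutlierPerGroup(tbl)
  restored <- rbind(r$table, tbl[r$removed$row, ])
  expect_setequal(restored$value, tbl$value)
})

test_that("Grubbs statistic matches the direct-formula oracle", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    if (runif(1) < 0.3) x[1] <- x[1] + runif(1, 3, 10)
    mine <- grubbsTest(x)
    want <- grubbsOracle(x)
    expect_equal(mine$G, want$G)
    expect_equal(mine$critical, want$crit)
    expect_identical(mine$outlier, want$reject)
  }
})

test_that("null removal rate stays at the nominal level", {
  set.seed(1234)
  removed <- vapply(1:1000, function(i) {
    nrow(removeOneOutlierPerGroup(
      data.frame(value = rnorm(10), group = "g"))$removed) > 0
  }, NA)
  expect_lte(mean(removed), 0.10)
})

test_that("t test and one-way ANOVA flag real effects and not null ones", {
  # identical groups: t ~ 0, p ~ 1
  d0 <- data.frame(value = rep(c(1, 2, 3), 2),
                   group = rep(c("a", "b"), each = 3))
  r0 <- compareGroups(d0, "t_test")
  expect_equal(unname(r0@statistic), 0)
  expect_equal(unname(r0@pValue), 1)

  # overwhelming effect
  set.seed(8)
  d1 <- data.frame(value = c(rnorm(20), rnorm(20, 5)),
                   group = rep(c("a", "b"), each = 20))
  expect_lt(compareGroups(d1, "t_test")@pValue, 0.001)
  # Welch variant differs in df but agrees on direction
  rw <- compareGroups(d1, "t_test", varEqual = FALSE)
  expect_lt(rw@pValue, 0.001)

  # one-way ANOVA + Tukey: only the separated pair is significant
  set.seed(9)
  d2 <- data.frame(value = c(rnorm(10), rnorm(10), rnorm(10, 4)),
                   group = rep(c("a", "b", "c"), each = 10))
  r2 <- compareGroups(d2, "anova1_tukey")
  expect_identical(r2@testName, "anova1_tukey")
  ph <- r2@postHoc
  expect_true(all(ph$significant[grepl("c", ph$pair)]))
  expect_false(ph$significant[ph$pair == "b-a"])
  # Tukey adjusted p never below the raw pooled-t p
  mse <- sum(resid(aov(value ~ group, d2))^2) / 27
  praw <- 2 * pt(abs(diff(tapply(d2$value, d2$group, mean))[1]) /
                   sqrt(mse * 0.2), 27, lower.tail = FALSE)
  expect_gte(ph$p_adjusted[ph$pair == "b-a"], praw)

  expect_error(compareGroups(d2, "t_test"), "exactly 2 groups")
  expect_error(compareGroups(d2[d2$group == "a", ], "anova1_tukey"),
               "at least 2 groups")
  expect_error(compareGroups(
    data.frame(value = rep(1, 6), group = rep(c("a", "b"), each = 3)),
    "t_test"), "degenerate")
})

test_that("two-way ANOVA matches aov on balanced data; Bonferroni is m*p", {
  set.seed(10)
  d <- expand.grid(rep = 1:5, group = c("wt", "mut"),
                   factor2 = c("veh", "trt"))
  d$value <- rnorm(20) + 2 * (d$group == "mut") +
    1.5 * (d$group == "mut" & d$factor2 == "trt")
  r <- compareGroups(d, "anova2_bonferroni")
  # balanced design: Type II equals the sequential sums of squares
  a <- summary(aov(value ~ group * factor2, data = d))[[1]]
  expect_equal(unname(r@statistic),
               unname(a[["F value"]][1:3]), tolerance = 1e-10)
  expect_equal(unname(r@pValue), unname(a[["Pr(>F)"]][1:3]),
               tolerance = 1e-10)
  # Bonferroni: adjusted p = min(1, m * raw p), never below raw
  ph <- r@postHoc
  expect_true(all(ph$p_adjusted <= 1 & ph$p_adjusted >= 0))
  expect_error(compareGroups(d[, c("value", "group")],
                             "anova2_bonferroni"), "factor2")
})

test_that("the chained report flags a 2x effect and reruns identically", {
  set.seed(30)
  vals <- data.frame(
    value = c(rnorm(6, 0.05, 0.005), rnorm(6, 0.10, 0.005)),
    group = rep(c("control", "disease"), each = 6))
  rep1 <- endToEndReport(vals, design = "anova1_tukey")
  expect_true(all(rep1$test@postHoc$significant))
  expect_s4_class(rep1$test, "TestResult")

  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  writeReport(rep1, d1)
  writeReport(endToEndReport(vals, design = "anova1_tukey"), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }

  expect_error(endToEndReport(vals[vals$group == "control", ]),
               "at least 2 groups")
})

test_that("chain type-I error with outlier screening stays below 0.10", {
  set.seed(77)
  rejections <- vapply(1:600, function(i) {
    tbl <- data.frame(value = rnorm(30),
                      group = rep(c("a", "b", "c"), each = 10))
    scr <- removeOneOutlierPerGroup(tbl)$table
    compareGroups(scr, "anova1_tukey")@pValue < 0.05
  }, NA)
  expect_lt(mean(rejections), 0.10)
})
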