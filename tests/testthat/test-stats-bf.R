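test_that("model enumeration respects full marginality", {
  expect_equal(length(enumerate_models("A")), 2)
  m2 <- enumerate_models(c("A", "B"))
  expect_equal(length(m2), 5)
  labs <- vapply(m2, paste, "", collapse = "+")
  expect_setequal(labs, c("", "A", "B", "A+B", "A+B+A:B"))
  m3 <- enumerate_models(c("A", "B", "C"))
  expect_equal(length(m3), 19)
  # no model may contain an interaction without its constituents
  for (m in m3) {
    for (term in m[grepl(":", m)]) {
      parts <- strsplit(term, ":")[[1]]
      expect_true(all(parts %in% unlist(strsplit(m, ":"))))
      for (p in parts) expect_true(p %in% m)
    }
  }
})

test_that("the collapsed paired design matches the quadrature oracle within 1%", {
  set.seed(7)
  for (rep in 1:5) {
    d <- stats::rnorm(17, mean = stats::runif(1, -0.8, 0.8))
    tab <- paired_table(d)
    fit <- jzs_bf(tab, "stimulation", r_fixed = 0.5, seed = 1)
    expect_equal(fit$method, "quadrature")
    t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    expect_equal(fit$logbf, oracle_jzs_t(t, length(d), 0.5),
                 tolerance = 0.01)
  }
})

test_that("Monte-Carlo integration agrees with quadrature within its error", {
  set.seed(8)
  d <- stats::rnorm(15, 0.4)
  tab <- paired_table(d)
  qd <- jzs_bf(tab, "stimulation", seed = 1)
  mc <- jzs_bf(tab, "stimulation", method = "mc", draws = 30000, seed = 2)
  # the full-model MC path carries the subject variance component as well;
  # the two representations agree closely on balanced paired data
  expect_equal(mc$logbf, qd$logbf, tolerance = 0.15)
  expect_identical(mc, jzs_bf(tab, "stimulation", method = "mc",
                              draws = 30000, seed = 2))
  expect_true(mc$mcse > 0)
})

test_that("Bayes factors are invariant under measurement rescaling", {
  tab <- sim_measure_table(9, c("stimulation", "cue"),
                           effects = list(cue = 2), seed = 11)
  f1 <- jzs_bf(tab, c("stimulation", "cue"), draws = 4000, seed = 3)
  tab2 <- tab; tab2$value <- tab2$value * 1000
  f2 <- jzs_bf(tab2, c("stimulation", "cue"), draws = 4000, seed = 3)
  expect_equal(f1$logbf, f2$logbf, tolerance = 1e-9)
})

test_that("a zero effect yields evidence for the null that grows with n", {
  for (n in c(10, 40)) {
    d <- scale(stats::rnorm(n))[, 1] * 0.8  # exactly t = 0 after centering
    d <- d - mean(d)
    tab <- paired_table(d)
    fit <- jzs_bf(tab, "stimulation", seed = 1)
    expect_lt(fit$logbf, 0)
    if (n == 10) bf10 <- fit$logbf else expect_lt(fit$logbf, bf10)
  }
})

test_that("under a simulated null most stimulation Bayes factors favor the null", {
  set.seed(9)
  hits <- replicate(20, {
    tab <- paired_table(stats::rnorm(23))
    jzs_bf(tab, "stimulation", seed = 1)$logbf < 0
  })
  expect_gte(mean(hits), 0.7)
})

test_that("model comparison finds the structure and reports consistent ratios", {
  tab <- sim_measure_table(14, c("stimulation", "cue"),
                           effects = list(cue = 6), sd_noise = 1, seed = 12)
  # zero the sampled stimulation contrast exactly so the fixture carries a
  # cue effect (plus subject-by-cue noise) and nothing else
  for (s in unique(tab$subject)) for (cu in unique(tab$cue)) {
    i <- tab$subject == s & tab$cue == cu
    tab$value[i] <- mean(tab$value[i])
  }
  cmp <- model_comparison(tab, c("stimulation", "cue"), draws = 4000,
                          seed = 5)
  expect_equal(attr(cmp, "strongest"), "cue")
  expect_gt(attr(cmp, "ratio_exclusion"), 1)
  # bookkeeping identities between the table and the reported ratios
  bs <- max(cmp$logbf[cmp$has_stim])
  bfree <- max(cmp$logbf[!cmp$has_stim])
  expect_equal(attr(cmp, "ratio_exclusion"), exp(bfree - bs))
  expect_equal(attr(cmp, "ratio_null_vs_stim"), exp(-bs))
  # all-constant data: the null model is strongest
  flat <- tab; flat$value <- 5
  cmp0 <- model_comparison(flat, c("stimulation", "cue"), draws = 2000,
                           seed = 6)
  expect_equal(attr(cmp0, "strongest"), "null")
})
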