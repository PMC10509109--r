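test_that("embedded study tables carry the published counts", {
  tabs <- embedded_study_tables()
  for (t in tabs) {
    expect_equal(sum(t), 169)
    expect_equal(unname(colSums(t)), c(49, 18, 45, 34, 23))
  }
  expect_equal(sum(diag(tabs$t4)), 157)
  expect_equal(sum(diag(tabs$t5)), 140)
  expect_equal(sum(diag(tabs$t6)), 162)
})

test_that("cross-tabulation round-trips through pair expansion", {
  tabs <- embedded_study_tables()
  for (t in tabs) {
    pairs <- expand_pairs(t)
    back <- cross_tabulate(pairs$reference, pairs$comparison)
    expect_equal(unclass(back)[, ], unclass(t)[, ], ignore_attr = TRUE)
    # column marginals are the reference histogram (conservation)
    expect_equal(unname(colSums(back)),
                 unname(as.integer(table(pairs$reference))))
  }
  expect_equal(sum(cross_tabulate(character(0), character(0))), 0)
  same <- rep(c("0", "11-100"), c(3, 4))
  diagonal <- cross_tabulate(same, same)
  expect_equal(sum(diag(diagonal)), 7)
  expect_error(cross_tabulate("0", "5-10"), "unknown risk class")
})

test_that("kappa matches the published values and an independent oracle", {
  tabs <- embedded_study_tables()
  expect_equal(cohen_kappa(tabs$t4), 0.908, tolerance = 0.001)
  expect_equal(cohen_kappa(tabs$t5), 0.777, tolerance = 0.001)
  expect_equal(cohen_kappa(tabs$t6), 0.947, tolerance = 0.001)
  # diagonal table: perfect agreement
  expect_equal(cohen_kappa(risk_table(diag(c(5, 3, 4, 2, 1)))), 1.0)
  # random tables vs e1071's implementation
  skip_if_not_installed("e1071")
  set.seed(5)
  for (i in 1:25) {
    m <- matrix(rpois(25, 4), 5, 5)
    expect_equal(cohen_kappa(risk_table(m)),
                 e1071::classAgreement(m)$kappa, tolerance = 1e-12)
  }
  # moving one subject off the diagonal lowers kappa
  m <- unclass(tabs$t4)[, ]
  m[1, 1] <- m[1, 1] - 1L; m[2, 1] <- m[2, 1] + 1L
  expect_lt(cohen_kappa(risk_table(m)), cohen_kappa(tabs$t4))
})

test_that("tau-b matches the published values and pair-counting oracles", {
  tabs <- embedded_study_tables()
  expect_equal(kendall_tau_b(tabs$t4), 0.967, tolerance = 0.001)
  expect_equal(kendall_tau_b(tabs$t5), 0.915, tolerance = 0.001)
  expect_equal(kendall_tau_b(tabs$t6), 0.980, tolerance = 0.001)
  expect_equal(kendall_tau_b(risk_table(diag(c(5, 3, 4, 2, 1)))), 1.0)
  # against brute-force pair counting and stats::cor on expanded pairs
  for (t in tabs) {
    p <- expand_pairs(t)
    x <- as.integer(p$reference); y <- as.integer(p$comparison)
    expect_equal(kendall_tau_b(t), tau_b_pairs(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau_b(t),
                 suppressWarnings(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
  }
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rpois(25, 2), 5, 5)
    if (sum(m) <= 1) next
    p <- expand_pairs(risk_table(m))
    expect_equal(kendall_tau_b(risk_table(m)),
                 tau_b_pairs(as.integer(p$reference), as.integer(p$comparison)),
                 tolerance = 1e-12)
  }
  # degenerate: single column
  m1 <- matrix(0L, 5, 5); m1[, 1] <- 2L
  expect_error(kendall_tau_b(risk_table(m1)), "undefined")
})

test_that("reclassification summaries match the published off-diagonals", {
  tabs <- embedded_study_tables()
  r4 <- reclassification_summary(tabs$t4)
  expect_equal(r4$n_reclassified, 12)
  expect_equal(r4$rate, 12 / 169)
  expect_equal(r4$n_upward, 0)
  expect_equal(r4$n_downward, 12)
  r5 <- reclassification_summary(tabs$t5)
  expect_equal(r5$n_reclassified, 29)
  expect_equal(r5$rate, 29 / 169)
  expect_equal(r5$n_upward, 1)  # the one upward move, from class 101-400
  expect_equal(unclass(tabs$t5)[5, 4], 1L)
  r6 <- reclassification_summary(tabs$t6)
  expect_equal(r6$n_reclassified, 7)
  diagonal <- risk_table(diag(c(10, 2, 3, 4, 1)))
  expect_equal(reclassification_summary(diagonal)$n_reclassified, 0)
  expect_equal(reclassification_summary(diagonal)$rate, 0)
})

test_that("Bland-Altman bias and limits behave on degenerate input", {
  same <- c(3, 9, 27, 81)
  ba <- bland_altman(same, same)
  expect_equal(c(ba$bias, ba$loa_lower, ba$loa_upper), c(0, 0, 0))
  ba5 <- bland_altman(same, same + 5)
  expect_equal(c(ba5$bias, ba5$loa_lower, ba5$loa_upper), c(5, 5, 5))
  expect_error(bland_altman(1, 2), "at least 2")
  set.seed(2)
  ref <- runif(50, 0, 100); d <- rnorm(50, -3, 4)
  ba2 <- bland_altman(ref, ref + d)
  expect_equal(ba2$bias, mean(d))
  expect_equal(ba2$loa_upper - ba2$loa_lower, 2 * 1.96 * sd(d))
})

test_that("ICC(A,1) matches a two-way ANOVA oracle", {
  # identical pairs with between-subject spread: perfect agreement
  expect_equal(icc_absolute(c(1, 5, 9, 13), c(1, 5, 9, 13)), 1.0)
  # 6-subject worked set vs explicit aov mean squares
  ref <- c(10, 40, 55, 120, 310, 800)
  cmp <- c(12, 35, 60, 100, 290, 770)
  expect_equal(icc_absolute(ref, cmp), icc_a1_aov(ref, cmp), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:10) {
    r <- rlnorm(6, 3, 1); c2 <- r * runif(6, 0.7, 1.2) + rnorm(6, 0, 2)
    expect_equal(icc_absolute(r, c2), icc_a1_aov(r, c2), tolerance = 1e-8)
  }
  # no subject effect: ICC near zero in large samples
  set.seed(77)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(icc_absolute(a, b)), 0.05)
  expect_error(icc_absolute(c(1, 2), c(1, 2)), "at least 3")
})

test_that("tables and pairs survive CSV round trips", {
  tabs <- embedded_study_tables()
  path <- tempfile(fileext = ".csv")
  write_risk_table_csv(tabs$t5, path)
  back <- read_risk_table_csv(path)
  expect_equal(unclass(back)[, ], unclass(tabs$t5)[, ], ignore_attr = TRUE)
  unlink(path)
  # score pairs are classified on read
  p2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(ref = c(0, 42, 500), cmp = c(0, 8, 380)), p2,
            row.names = FALSE)
  pr <- read_pairs_csv(p2)
  expect_equal(pr$reference, c("0", "11-100", ">400"))
  expect_equal(pr$comparison, c("0", "1-10", "101-400"))
  unlink(p2)
})
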