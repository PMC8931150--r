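test_that("descriptive summary matches a brute-force two-pass computation", {
  withr::with_seed(13, {
    for (i in 1:5) {
      x <- rnorm(sample(5:40, 1), mean = 2, sd = 0.3)
      s <- descriptive_summary(x)
      n <- length(x)
      m <- sum(x) / n
      v <- sum((x - m)^2) / (n - 1)
      expect_equal(s$mean, m, tolerance = 1e-12)
      expect_equal(s$sd, sqrt(v), tolerance = 1e-12)
      expect_equal(s$ci95_halfwidth, qt(0.975, n - 1) * sqrt(v / n),
                   tolerance = 1e-12)
      expect_equal(s$cv, sqrt(v) / m, tolerance = 1e-12)
      expect_true(s$min <= s$mean && s$mean <= s$max)
    }
  })
  cst <- descriptive_summary(rep(2, 10))
  expect_equal(cst$sd, 0)
  expect_equal(cst$cv, 0)
  expect_equal(cst$ci95_halfwidth, 0)
  expect_error(descriptive_summary(1), "insufficient-data")
})

test_that("bimodality amplitude follows the two-peak histogram definition", {
  # adjacent bins with counts 10 / 3 / 8: BA = (8 - 3) / 8
  v <- c(rep(0.95, 10), rep(1.05, 3), rep(1.15, 8))
  expect_equal(bimodality_amplitude(v)$ba, 0.625)
  # well-separated clusters, empty valley
  v2 <- c(rep(1.05, 10), rep(2.05, 10))
  expect_equal(bimodality_amplitude(v2)$ba, 1.0)
  # strictly unimodal: no second local maximum
  v3 <- c(rep(1.05, 5), rep(1.15, 7), rep(1.25, 4))
  expect_equal(bimodality_amplitude(v3)$ba, 0)
  expect_error(bimodality_amplitude(c(1, 2, 3)), "insufficient-data")
  # BA of the published cohort values is positive (bimodal) and within [0,1]
  for (m in c("ddPCR", "qPCR")) {
    ba <- bimodality_amplitude(table3$cnv[table3$method == m])$ba
    expect_gt(ba, 0)
    expect_lte(ba, 1)
  }
})

test_that("paired t-test matches the closed form, flips sign, shifts out", {
  withr::with_seed(31, {
    x <- rnorm(12, 2, 0.1)
    y <- x + rnorm(12, 0.03, 0.05)
    r <- paired_t(x, y)
    d <- x - y
    expect_equal(r$value, mean(d) / (sd(d) / sqrt(length(d))),
                 tolerance = 1e-12)
    expect_equal(r$df, 11)
    expect_equal(paired_t(y, x)$value, -r$value, tolerance = 1e-12)
    # common constant added to both replicates of every specimen cancels
    expect_equal(paired_t(x + 5, y + 5)$value, r$value, tolerance = 1e-12)
  })
  expect_error(paired_t(1:5, 1:5 + 0.5), "degenerate")
})

test_that("Shapiro-Wilk wrapper returns W in (0, 1] and enforces n >= 3", {
  withr::with_seed(17, {
    w <- shapiro_wilk(rnorm(20))$value
    expect_gt(w, 0)
    expect_lte(w, 1)
  })
  expect_error(shapiro_wilk(c(1, 2)), "insufficient-data")
})

test_that("phi coefficient: closed-form cases and the ±1 diagonal law", {
  expect_equal(phi_coefficient(234, 0, 0, 214)$value, 1.0)
  expect_equal(phi_coefficient(5, 5, 5, 5)$value, 0.0)
  expect_equal(phi_coefficient(0, 10, 10, 0)$value, -1.0)
  expect_error(phi_coefficient(0, 0, 5, 5), "undefined-association")
  withr::with_seed(23, {
    for (i in 1:20) {
      tb <- sample(0:30, 4, replace = TRUE)
      margins_ok <- all(c(tb[1] + tb[2], tb[3] + tb[4],
                          tb[1] + tb[3], tb[2] + tb[4]) > 0)
      if (!margins_ok) next
      phi <- phi_coefficient(tb[1], tb[2], tb[3], tb[4])$value
      expect_gte(phi, -1)
      expect_lte(phi, 1)
      diag_zero <- (tb[1] == 0 && tb[4] == 0) || (tb[2] == 0 && tb[3] == 0)
      expect_identical(abs(phi) == 1, diag_zero)
    }
  })
})

test_that("1:1 chi-square is Pearson's uncorrected statistic", {
  expect_equal(chi_square_1to1(25, 25)$value, 0)
  expect_equal(chi_square_1to1(30, 20)$value, 2)     # 2 * 5^2 / 25
  expect_equal(chi_square_1to1(27, 23)$value, 0.32)  # 2 * 2^2 / 25
  expect_equal(chi_square_1to1(27, 23)$df, 1)
})

test_that("validate_cohort assembles the full battery on the published cohort", {
  truth <- unique(table3[, c("specimen_id", "true_sex")])
  v <- validate_cohort(table3[table3$method == "qPCR", ], truth = truth)
  got <- function(name) v$stats[v$stats$statistic_name == name, ]
  expect_equal(round(got("t_paired")$value, 3), -1.809)
  expect_equal(round(got("W_shapiro")$value, 3), 0.953)
  expect_equal(got("phi")$value, 1.0)
  expect_lt(got("phi")$p_value, 0.05)
  expect_equal(got("chi2_gof")$value, 0)  # 10 F vs 10 M
  expect_gt(got("BA")$value, 0)
  expect_identical(unname(v$counts), c(10L, 10L, 0L))
  f_row <- v$summaries[v$summaries$sex == "F", ]
  expect_equal(round(f_row$mean, 3), 1.973)
})
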