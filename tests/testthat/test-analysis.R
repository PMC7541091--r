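test_that("the depth conversion matches a brute-force envelope oracle", {
  for (m in c(0.2, 0.5, 0.95, 1.49, 1.52, 5, 20, 40)) {
    expect_equal(depth_to_20logm(m), numeric_depth_conversion(m),
                 tolerance = 1e-9)
  }
  # frozen oracle values for the cohort-mean depths
  expect_equal(depth_to_20logm(0.95), -19.257, tolerance = 1e-3)
  expect_equal(depth_to_20logm(1.52), -15.227, tolerance = 1e-3)
  expect_equal(depth_to_20logm(1.49), -15.397, tolerance = 1e-3)
  # asymptotes and monotonicity
  expect_lt(depth_to_20logm(1e-6), -100)
  expect_gt(depth_to_20logm(50), -1e-3)
  expect_lt(depth_to_20logm(50), 0)
  m <- seq(0.2, 40, length.out = 200)
  expect_true(all(diff(depth_to_20logm(m)) > 0))
  expect_error(depth_to_20logm(0), "positive")
})

test_that("converted-mean dominates mean-of-converted (concavity)", {
  set.seed(50)
  for (i in 1:20) {
    m <- exp(rnorm(50, log(1.2), 0.5))
    expect_gte(depth_to_20logm(mean(m)), mean(depth_to_20logm(m)))
  }
})

test_that("analysis-unit transforms follow the published conventions", {
  d <- data.frame(
    assessment = c("gap", "diotic_fm", "no_notch", "srm_separated", "tm"),
    value = c(4, 8, 56.85, -4.5, 1.5)
  )
  out <- to_analysis_units(d)
  expect_equal(out$value, c(2, 3, -11.85, -4.5, 1.5))
  expect_equal(out$units, c("log2 (ms)", "log2 (Hz)", "TMR (dB)", "TMR (dB)",
                            "M (dB)"))
  # nonpositive value under a log transform is excluded with a reason
  bad <- to_analysis_units(data.frame(assessment = "gap", value = 0))
  expect_true(is.na(bad$value))
  expect_match(bad$excluded_reason, "nonpositive")
  expect_error(to_analysis_units(data.frame(assessment = "bogus", value = 1)),
               "unknown")
})

test_that("outlier rejection is single-pass with a strict 3-SD rule", {
  v <- c(rep(0, 99), 9.9)
  mask <- reject_outliers(v)
  expect_false(mask[100])
  expect_true(all(mask[1:99]))

  expect_true(all(reject_outliers(rep(5, 10))))      # zero variance

  # value at exactly 3 SD is kept: c(-a, a, 0 x 17) has dev == 3 * sd
  v3 <- c(-1, 1, rep(0, 17))
  expect_equal(max(abs(v3 - mean(v3))) / sd(v3), 3)
  expect_true(all(reject_outliers(v3)))

  expect_error(reject_outliers(c(1, 2)), "at least 3")
})

test_that("Bland-Altman agrees with hand computation and is antisymmetric", {
  s1 <- c(1, 2, 3, 4); s2 <- s1
  perfect <- bland_altman(s1, s2)
  expect_equal(perfect$bias, 0)
  expect_equal(c(perfect$loa_low, perfect$loa_high), c(0, 0))
  expect_equal(perfect$d, 0)

  two <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(two$bias, 0)
  expect_equal(two$sd_diff, sqrt(2), tolerance = 1e-9)
  expect_equal(two$loa_high, 1.96 * sqrt(2), tolerance = 1e-3) # 2.77

  shift <- bland_altman(s1, s1 + 2)
  expect_equal(shift$bias, 2)
  expect_equal(c(shift$loa_low, shift$loa_high), c(2, 2))
  expect_equal(shift$r, 1)

  set.seed(51)
  a <- rnorm(30); b <- a + rnorm(30, 0.3, 0.5)
  ab <- bland_altman(a, b); ba <- bland_altman(b, a)
  expect_equal(ab$bias, -ba$bias)
  expect_equal(ab$loa_high - ab$loa_low, ba$loa_high - ba$loa_low)
  expect_equal(ab$df, 29)
  expect_error(bland_altman(1:4, 1:5), "paired")
})

test_that("composite scores are column-standardised with a coherent alpha", {
  set.seed(52)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, paste0("a", 1:10)))
  cs <- composite_scores(m)
  expect_equal(unname(colMeans(cs$z_matrix)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(cs$z_matrix, 2, sd)), rep(1, 10),
               tolerance = 1e-12)
  # a subject sitting at every column mean gets a composite of zero
  m2 <- rbind(m, colMeans(m))
  expect_equal(unname(composite_scores(m2)$composite[21]), 0,
               tolerance = 1e-9)
  # two duplicated columns have alpha 1
  dup <- cbind(x = m[, 1], y = m[, 1])
  expect_equal(composite_scores(dup)$cronbach_alpha, 1, tolerance = 1e-9)
  # zero-variance column is named in the error
  bad <- m; bad[, 3] <- 7
  expect_error(composite_scores(bad), "a3")
})

test_that("alpha matches the standardized closed form on equicorrelated items", {
  # items with common correlation rho: alpha = k rho / (1 + (k-1) rho)
  set.seed(53)
  n <- 4000; k <- 10; rho <- 0.23
  g <- rnorm(n)
  m <- sqrt(rho) * g + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  expect_equal(cronbach_alpha(m), k * rho / (1 + (k - 1) * rho),
               tolerance = 0.03)
})

test_that("the reliability report recovers an injected session shift", {
  set.seed(54)
  n <- 120
  subj <- sprintf("s%03d", 1:n)
  ability <- rnorm(n, 5, 1.5)
  delta <- -0.5; sigma <- 0.6
  d <- rbind(
    data.frame(subject = subj, session = 1, assessment = "tm",
               value = ability + rnorm(n, 0, sigma)),
    data.frame(subject = subj, session = 2, assessment = "tm",
               value = ability + rnorm(n, 0, sigma) + delta),
    data.frame(subject = subj, session = 1, assessment = "sm",
               value = ability + rnorm(n, 0, sigma)),
    data.frame(subject = subj, session = 2, assessment = "sm",
               value = ability + rnorm(n, 0, sigma) + delta)
  )
  rep <- test_retest_report(d)
  row <- rep$table[rep$table$assessment == "tm", ]
  ci_half <- qt(0.975, row$n - 1) * rep$loa$tm$sd_diff / sqrt(row$n)
  expect_lt(abs(row$bias - delta), ci_half + 0.02)
  # LoA width consistent with 2 * 1.96 * sqrt(2) * sigma
  expect_equal(row$loa_high - row$loa_low, 2 * 1.96 * sqrt(2) * sigma,
               tolerance = 0.15 * 2 * 1.96 * sqrt(2) * sigma)
  # one row per assessment plus the composite; df = n - 1
  expect_equal(nrow(rep$table), 3)
  expect_true("composite" %in% rep$table$assessment)
  expect_equal(rep$table$df, rep$table$n - 1)
  # plot data: one mean/difference pair per paired subject
  expect_setequal(names(rep$plot_data), c("assessment", "subject", "mean",
                                          "diff"))
  expect_equal(sum(rep$plot_data$assessment == "tm"), n)
})

test_that("subjects missing a session are dropped with a log entry", {
  set.seed(55)
  n <- 20
  subj <- sprintf("s%02d", 1:n)
  d <- rbind(
    data.frame(subject = subj, session = 1, assessment = "tm",
               value = rnorm(n)),
    data.frame(subject = subj[-1], session = 2, assessment = "tm",
               value = rnorm(n - 1)),
    data.frame(subject = subj, session = 1, assessment = "sm",
               value = rnorm(n)),
    data.frame(subject = subj, session = 2, assessment = "sm",
               value = rnorm(n))
  )
  expect_message(rep <- test_retest_report(d), "lacked a session")
  expect_equal(rep$dropped, "s01")
  expect_equal(rep$table$n[rep$table$assessment == "tm"], n - 1)
})
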