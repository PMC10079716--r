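# Study pipeline: per-set table, summaries, MCID counting, statistics.

test_that("study table covers the design and is exact at nominal pose", {
  tab <- default_table()
  expect_equal(nrow(tab), 48)
  expect_true(all(tab$icm_converged & tab$ecm_converged))
  expect_equal(tab$abs_diff_pp, abs(tab$rel_diff_pp))
  expect_lt(max(tab$abs_diff_pp[tab$rotation_deg == 0]), 0.1)
  # systematic error grows with rotation on average
  means <- tapply(tab$abs_diff_pp, tab$rotation_deg, mean)
  expect_true(all(diff(means) > 0))
})

test_that("summaries reduce correctly and recombine to the overall mean", {
  tab <- default_table()
  s_all <- summarize_study(tab, "all")
  s_rot <- summarize_study(tab, "rotation")
  expect_equal(unique(s_rot$n), 12)
  for (v in unique(s_all$variable)) {
    parts <- s_rot[s_rot$variable == v, ]
    overall <- s_all[s_all$variable == v, ]
    expect_equal(sum(parts$mean * parts$n) / sum(parts$n), overall$mean)
    expect_equal(min(parts$min), overall$min)
    expect_equal(max(parts$max), overall$max)
  }
  # hand-computed arithmetic on a small synthetic table
  small <- data.frame(series_id = "s", anterior_mm = 20, lateral_mm = 0,
                      rotation_deg = c(0, 0, 10, 10),
                      cf_icm = c(126, 127, 126, 127),
                      cf_ecm = c(125, 126.5, 124, 126),
                      rel_diff_pp = c(1, 0.5, 2, 1),
                      abs_diff_pp = c(1, 0.5, 2, 1),
                      icm_converged = TRUE, ecm_converged = TRUE)
  s <- summarize_study(small, "all")
  row <- s[s$variable == "abs_diff_pp", ]
  expect_equal(row$mean, 1.125)
  expect_equal(row$min, 0.5)
  expect_equal(row$max, 2)
  expect_equal(row$sd, sd(c(1, 0.5, 2, 1)))
  # constant rows collapse to zero spread
  const <- small
  const$abs_diff_pp <- 1
  sc <- summarize_study(const, "all")
  expect_equal(sc[sc$variable == "abs_diff_pp", "sd"], 0)

  t2 <- table2_summary(tab)
  expect_equal(ncol(t2), 2 + 1 + 4)   # statistic, variable, All + 4 rotations
  expect_equal(nrow(t2), 16)
})

test_that("MCID counting uses a strict threshold with rotation breakdown", {
  tab <- default_table()
  rep0 <- mcid_report(tab)
  expect_equal(rep0$n_beyond, 0)

  synth <- tab
  synth$abs_diff_pp <- 0.5
  synth$abs_diff_pp[synth$rotation_deg == 30][1:4] <- 2.0
  r <- mcid_report(synth, 1.5)
  expect_equal(r$n_beyond, 4)
  expect_equal(r$fraction, 4 / 48, tolerance = 1e-12)
  expect_equal(r$by_rotation$n_beyond,
               c(0, 0, 0, 4))
  # boundary value is acceptable (strict inequality)
  synth$abs_diff_pp[1] <- 1.5
  expect_equal(mcid_report(synth, 1.5)$n_beyond, 4)
  # threshold 0 counts every nonzero difference
  expect_equal(mcid_report(synth, 0)$n_beyond, sum(synth$abs_diff_pp > 0))
})

test_that("paired location test matches the textbook t formula", {
  x <- c(126.2, 126.9, 126.5, 127.0, 126.1)
  y <- c(125.6, 126.8, 125.9, 126.2, 125.9)
  res <- paired_location_test(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(-abs(t_manual), length(d) - 1)
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value, p_manual, tolerance = 1e-12)
  expect_false(res$degenerate)

  same <- paired_location_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  # constant shift with tiny noise is overwhelmingly significant
  set.seed(11)
  a <- rnorm(48, 126, 0.1)
  res2 <- paired_location_test(a, a - 1)
  expect_lt(res2$p_value, 1e-3)
})

test_that("rank k-sample test matches the brute-force H formula", {
  vals <- c(1, 2, 3, 10, 11, 12)
  grp <- rep(c("a", "b"), each = 3)
  res <- rank_ksample_test(vals, grp)
  rk <- rank(vals)
  N <- length(vals)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(rk, grp, function(r) length(r) * mean(r)^2)) - 3 * (N + 1)
  expect_equal(res$statistic, H, tolerance = 1e-12)

  # tie-corrected case
  vals2 <- c(1, 2, 2, 2, 5, 6, 6, 9)
  grp2 <- rep(c("a", "b"), each = 4)
  rk2 <- rank(vals2)
  H2 <- 12 / (8 * 9) *
    sum(tapply(rk2, grp2, function(r) length(r) * mean(r)^2)) - 3 * 9
  ties <- table(vals2)
  H2 <- H2 / (1 - sum(ties^3 - ties) / (8^3 - 8))
  expect_equal(rank_ksample_test(vals2, grp2)$statistic, H2,
               tolerance = 1e-12)

  # identical distributions give H = 0
  expect_equal(rank_ksample_test(c(1, 2, 3, 1, 2, 3),
                                 rep(c("a", "b"), each = 3))$statistic, 0)
  # fully constant response is degenerate
  expect_true(rank_ksample_test(rep(1, 6),
                                rep(c("a", "b"), each = 3))$degenerate)
})

test_that("ICC(2,1) matches the mean-squares formula and its limits", {
  m <- matrix(c(9, 10, 11, 14, 8, 12,
                10, 11, 12, 15, 9, 13), ncol = 2)
  res <- icc_agreement(m)
  # brute-force two-way decomposition
  n <- nrow(m); k <- ncol(m)
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  mse <- (sum((m - gm)^2) - k * sum((rowMeans(m) - gm)^2) -
            n * sum((colMeans(m) - gm)^2)) / ((n - 1) * (k - 1))
  icc_manual <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_manual, tolerance = 1e-12)
  expect_true(res$lower <= res$icc && res$icc <= res$upper)

  # identical columns with between-subject variance: perfect agreement
  m2 <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc_agreement(m2)$icc, 1)

  # no between-subject variance: undefined
  m3 <- cbind(rep(5, 6), rep(5, 6))
  expect_true(icc_agreement(m3)$degenerate)

  # independent noise: ICC near zero
  set.seed(21)
  m4 <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_agreement(m4)$icc), 0.1)
})

test_that("simulated raters give high reliability for large measurements", {
  recs <- default_records()
  ratings <- simulate_raters(recs, noise_model(seed = 31), n_raters = 2)
  expect_equal(dim(ratings$m), c(12, 2))
  expect_equal(dim(ratings$a), c(48, 2))
  # variables with real between-subject spread are highly reliable
  expect_gt(icc_agreement(ratings$h)$icc, 0.9)
  expect_gt(icc_agreement(ratings$d)$icc, 0.9)
  # m is identical across series in the phantom, so its reliability under
  # pure noise collapses toward zero (the lack-of-variance phenomenon)
  expect_lt(icc_agreement(ratings$m)$icc, 0.5)
  # reproducible under the seed
  ratings2 <- simulate_raters(recs, noise_model(seed = 31), n_raters = 2)
  expect_identical(ratings, ratings2)
  # zero noise: perfect or degenerate
  r0 <- simulate_raters(recs, noise_model(0, 0), n_raters = 2)
  icc0 <- icc_agreement(r0$h)
  expect_true(isTRUE(all.equal(icc0$icc, 1)) || icc0$degenerate)
})
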