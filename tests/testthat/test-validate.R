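meas_row <- function(id, camp, week, value) {
  data.frame(site_id = id, x = 0, y = 0, pollutant = "PM2.5",
             campaign = camp, week = week, value = value,
             stringsAsFactors = FALSE)
}

test_that("annual means nest weekly and campaign averaging", {
  m <- rbind(meas_row("A", "dry", 1, 12), meas_row("A", "dry", 2, 14),
             meas_row("A", "rainy", 1, 16), meas_row("A", "rainy", 2, 18),
             meas_row("B", "dry", 1, 10), meas_row("B", "dry", 2, 10),
             meas_row("B", "rainy", 1, 20), meas_row("B", "rainy", 2, 20))
  res <- annual_means(m)
  a <- res$means[res$means$site_id == "A", ]
  expect_equal(c(a$dry, a$rainy, a$annual), c(13, 17, 15))
  b <- res$means[res$means$site_id == "B", ]
  expect_equal(b$annual, 15)
  expect_equal(nrow(res$excluded), 0)
})

test_that("sites with one or zero valid campaigns are excluded with reasons", {
  m <- rbind(meas_row("A", "dry", 1, 12), meas_row("A", "dry", 2, 14),
             meas_row("A", "rainy", 1, NA), meas_row("A", "rainy", 2, NA),
             meas_row("B", "dry", 1, NA), meas_row("B", "rainy", 1, NA),
             meas_row("C", "dry", 1, 9), meas_row("C", "rainy", 1, 11))
  res <- annual_means(m)
  expect_equal(res$means$site_id, "C")
  expect_equal(res$excluded$reason[res$excluded$site_id == "A"],
               "single campaign")
  expect_equal(res$excluded$reason[res$excluded$site_id == "B"],
               "no valid campaign")
  # a single valid week still carries its campaign
  expect_equal(res$means$annual, 10)
})

test_that("LOOCV equals an explicit per-fold refit loop", {
  withr::with_seed(80, {
    n <- 6
    tab <- data.frame(a = rnorm(n), b = runif(n))
    y <- 2 + 1.2 * tab$a - 0.5 * tab$b + rnorm(n, 0, 0.3)
  })
  rep <- loocv(tab, y, c("a", "b"))
  manual <- vapply(seq_len(n), function(i) {
    f <- lm(y[-i] ~ a + b, data = tab[-i, ])
    unname(predict(f, newdata = tab[i, ]))
  }, 0)
  expect_equal(rep$pairs$predicted, manual, tolerance = 1e-10)
  expect_equal(rep$cv_r2, cor(y, manual)^2, tolerance = 1e-12)
  expect_equal(rep$cv_mse, mean((y - manual)^2), tolerance = 1e-12)
  expect_equal(rep$cv_sse, sum((y - manual)^2), tolerance = 1e-12)
})

test_that("LOOCV limits and degenerate cases behave as specified", {
  x <- 1:10
  tab <- data.frame(x = x)
  # noiseless linear data: perfect cross-validation
  rep <- loocv(tab, 2 + 3 * x, "x")
  expect_equal(rep$cv_r2, 1, tolerance = 1e-12)
  expect_equal(rep$cv_sse, 0, tolerance = 1e-16)
  # constant outcome: undefined CV R2
  expect_error(loocv(tab, rep(5, 10), "x"), "constant")
  # intercept-only: left-out prediction is the mean of the remaining y
  withr::with_seed(81, y <- rnorm(8))
  rep0 <- loocv(data.frame(z = seq_along(y)), y, character(0))
  expected <- vapply(seq_along(y), function(i) mean(y[-i]), 0)
  expect_equal(rep0$pairs$predicted, expected, tolerance = 1e-12)
  # log-transform models are back-transformed before CV statistics
  withr::with_seed(82, {
    tabl <- data.frame(a = runif(20))
    yl <- exp(1 + 2 * tabl$a + rnorm(20, 0, 0.1))
  })
  repl <- loocv(tabl, yl, "a", transform = "log")
  expect_true(all(repl$pairs$predicted > 0))
  expect_lte(repl$cv_r2, 1)
})

test_that("the R2 gap reproduces the reporting convention", {
  expect_identical(r2_gap(0.82, 0.79), 3L)
  expect_identical(r2_gap(0.77, 0.46), 31L)
  expect_identical(r2_gap(0.5, 0.5), 0L)
  expect_identical(r2_gap(0.44, 0.38), 6L)
  expect_error(r2_gap(1.2, 0.5))
})

test_that("Bland-Altman agreement matches hand computation", {
  # identical pairs: zero difference, zero-width limits
  s <- bland_altman(c(3, 4, 5), c(3, 4, 5))
  expect_equal(c(s$mean_difference, s$lower_limit, s$upper_limit), c(0, 0, 0))
  # constant offset
  a <- c(10, 12, 14); s2 <- bland_altman(a, a - 2)
  expect_equal(s2$mean_difference, 2)
  expect_equal(s2$sd_difference, 0)
  expect_equal(c(s2$lower_limit, s2$upper_limit), c(2, 2))
  # hand-computed: d = (2, -1, 2), dbar = 1, sd = sqrt(3)
  s3 <- bland_altman(c(10, 12, 14), c(8, 13, 12))
  expect_equal(s3$mean_difference, 1)
  expect_equal(s3$sd_difference, sqrt(3), tolerance = 1e-12)
  expect_equal(s3$lower_limit, 1 - 1.96 * sqrt(3), tolerance = 1e-12)
  expect_equal(s3$upper_limit, 1 + 1.96 * sqrt(3), tolerance = 1e-12)
  # antisymmetry: swapping the order negates and mirrors
  s4 <- bland_altman(c(8, 13, 12), c(10, 12, 14))
  expect_equal(s4$mean_difference, -s3$mean_difference)
  expect_equal(s4$lower_limit, -s3$upper_limit, tolerance = 1e-12)
  expect_equal(s4$upper_limit, -s3$lower_limit, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "at least 2")
})
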