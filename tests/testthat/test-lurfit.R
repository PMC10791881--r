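test_that("screening applies the zero-fraction rule before correlation pruning", {
  withr::with_seed(50, {
    n <- 20
    tab <- data.frame(
      sparse = c(rep(0, 19), 5),            # 95% zeros -> removed
      ok = rnorm(n),
      dup = NA)
    tab$dup <- tab$ok                        # |r| = 1 duplicate pair
    y <- rnorm(n)
  })
  scr <- screen_predictors(tab, y)
  expect_false("sparse" %in% names(scr$table))
  expect_equal(scr$log$reason[scr$log$name == "sparse"], "zero_fraction")
  # exactly one of the duplicated pair survives
  expect_equal(sum(c("ok", "dup") %in% names(scr$table)), 1L)
  expect_equal(sum(scr$log$reason == "correlation"), 1L)
  # removed + retained partitions the input columns
  expect_setequal(c(scr$log$name, setdiff(names(scr$table), "site_id")),
                  names(tab))
})

test_that("orthogonal clean columns pass screening untouched", {
  tab <- data.frame(a = c(1, -1, 1, -1, 1, -1, 1, -1),
                    b = c(1, 1, -1, -1, 1, 1, -1, -1),
                    c = c(1, 1, 1, 1, -1, -1, -1, -1))
  y <- c(2, 1, 4, 3, 6, 5, 8, 7)
  scr <- screen_predictors(tab, y)
  expect_equal(names(scr$table), c("a", "b", "c"))
  expect_equal(nrow(scr$log), 0L)
  expect_error(screen_predictors(tab, rep(1, 8)), "constant")
})

test_that("the weaker outcome-correlate loses the correlation duel", {
  withr::with_seed(51, {
    x1 <- rnorm(60)
    x2 <- x1 + rnorm(60, 0, 0.3)   # |r| > 0.7 with x1
    y <- 2 * x1 + rnorm(60, 0, 0.2)
  })
  scr <- screen_predictors(data.frame(x1 = x1, x2 = x2), y)
  expect_equal(names(scr$table), "x1")
  expect_match(scr$log$detail, "with x1")
})

test_that("OLS matches exact data and the normal-equation oracle", {
  # noiseless line
  x <- 1:10
  f <- fit_ols(2 + 3 * x, data.frame(x = x))
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r2, 1)
  # random instance vs (X'X)^{-1} X'y
  withr::with_seed(52, {
    n <- 25
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = runif(n))
    y <- 1 + 0.5 * X$a - 2 * X$b + rnorm(n)
  })
  f <- fit_ols(y, X)
  Xm <- cbind(1, as.matrix(X))
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% y)
  expect_equal(unname(f$coefficients), as.vector(beta), tolerance = 1e-8)
  sse <- sum((y - Xm %*% beta)^2)
  expect_equal(f$rmse, sqrt(sse / (n - 3 - 1)), tolerance = 1e-10)
  r2 <- 1 - sse / sum((y - mean(y))^2)
  expect_equal(f$adj_r2, 1 - (1 - r2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-10)
})

test_that("degenerate OLS designs are refused with informative errors", {
  y <- rnorm(5)
  expect_error(fit_ols(y, data.frame(a = 1:5, b = 2 * (1:5), c = 1:5 + 1,
                                     d = 5:1)),
               "too many predictors")   # p = n - 1 -> df = 0
  withr::with_seed(53, {
    X <- data.frame(a = rnorm(8), b = rnorm(8))
    X$c <- X$a + X$b
  })
  expect_error(fit_ols(rnorm(8), X), "collinear columns: c")
})

test_that("VIF equals the definitional auxiliary-regression oracle", {
  # orthogonal design: all VIF = 1
  Xo <- data.frame(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  expect_equal(unname(vif(Xo)), c(1, 1), tolerance = 1e-12)
  # duplicated column: infinite, flagged
  Xd <- data.frame(a = rnorm(10))
  Xd$b <- Xd$a
  v <- vif(Xd)
  expect_true(all(is.infinite(v)))
  expect_setequal(attr(v, "flagged"), c("a", "b"))
  # random 5-column instance vs 5 separate auxiliary fits
  withr::with_seed(54, {
    X <- as.data.frame(matrix(rnorm(30 * 5), 30))
    X$V5 <- X$V1 * 0.8 + rnorm(30, 0, 0.4)
  })
  v <- vif(X)
  for (j in seq_along(X)) {
    r2j <- summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2j), tolerance = 1e-8)
  }
  expect_error(vif(X[1]), "two columns")
})

test_that("supervised selection keeps a strong true predictor and bounds noise entry", {
  hits <- 0; noise_in <- 0
  n_noise <- 10; reps <- 40
  for (r in seq_len(reps)) {
    withr::with_seed(100 + r, {
      n <- 40
      tab <- as.data.frame(matrix(rnorm(n * n_noise), n,
                                  dimnames = list(NULL,
                                                  paste0("ZN", 1:n_noise))))
      tab$IND200 <- runif(n)
      y <- 5 + 10 * tab$IND200 + rnorm(n, 0, 0.8)
    })
    m <- suppressWarnings(supervised_select(tab, y, mode = "forward"))
    if ("IND200" %in% m$terms$predictor) hits <- hits + 1
    noise_in <- noise_in + sum(grepl("^ZN", m$terms$predictor))
  }
  expect_equal(hits, reps)   # the true predictor is always found
  # noise terms enter at most at the nominal rate per replicate
  expect_lte(noise_in / reps, 0.05 * n_noise)
})

test_that("sign constraints bite: a wrong-direction predictor is excluded", {
  withr::with_seed(55, {
    n <- 30
    tab <- data.frame(IND200 = runif(n), DTER100 = runif(n, 0, 500))
    # distance effect simulated POSITIVE, conflicting with its expected "-"
    y <- 3 + 5 * tab$IND200 + 0.01 * tab$DTER100 + rnorm(n, 0.2)
  })
  m <- suppressWarnings(supervised_select(tab, y))
  expect_false("DTER100" %in% m$terms$predictor)
  path <- attr(m, "path")
  expect_true(any(path$name == "DTER100" & grepl("sign", path$why)))
})

test_that("an empty candidate set yields the intercept-only model", {
  y <- c(3, 5, 7, 9, 11, 13)
  expect_warning(m <- supervised_select(data.frame(row = seq_along(y))[0],
                                        y),
                 "intercept-only")
  expect_equal(nrow(m$terms), 0)
  expect_equal(m$intercept, mean(y))
  expect_equal(predict(m, data.frame(x = 1)), mean(y))
})

test_that("selection is scale-equivariant and deterministic", {
  withr::with_seed(56, {
    n <- 40
    tab <- data.frame(IND200 = runif(n), LOC500 = runif(n, 0, 3000),
                      RES100 = runif(n))
    y <- 4 + 6 * tab$IND200 + 0.002 * tab$LOC500 + rnorm(n, 0, 0.3)
  })
  m1 <- suppressWarnings(supervised_select(tab, y))
  m2 <- suppressWarnings(supervised_select(tab, y))
  expect_identical(m1[1:4], m2[1:4])
  # multiply a predictor by c: coefficient divides by c, fit unchanged
  tab_scaled <- tab; tab_scaled$LOC500 <- tab$LOC500 * 1000
  m3 <- suppressWarnings(supervised_select(tab_scaled, y))
  expect_setequal(m3$terms$predictor, m1$terms$predictor)
  i1 <- match("LOC500", m1$terms$predictor)
  i3 <- match("LOC500", m3$terms$predictor)
  expect_equal(m3$terms$coefficient[i3], m1$terms$coefficient[i1] / 1000,
               tolerance = 1e-9)
  expect_equal(m3$diagnostics$adj_r2, m1$diagnostics$adj_r2,
               tolerance = 1e-12)
  expect_equal(m3$diagnostics$max_vif, m1$diagnostics$max_vif,
               tolerance = 1e-9)
})

test_that("log-transform selection requires positive outcomes and back-transforms", {
  withr::with_seed(57, {
    n <- 35
    tab <- data.frame(IND200 = runif(n))
    y <- exp(2 + 1.5 * tab$IND200 + rnorm(n, 0, 0.05))
  })
  m <- suppressWarnings(supervised_select(tab, y, transform = "log"))
  expect_equal(m$transform, "log")
  expect_true("IND200" %in% m$terms$predictor)
  expect_equal(unname(predict(m, data.frame(IND200 = 0))),
               exp(m$intercept))
  expect_error(supervised_select(tab, y - 100, transform = "log"),
               "positive")
})
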