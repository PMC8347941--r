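test_that("absolute error is the plain measured-minus-true difference", {
  expect_equal(absolute_error(0.62, 0.60), 0.02)
  expect_equal(absolute_error(1.234, 1.234), 0)
  set.seed(5)
  m <- rnorm(50); r <- rnorm(50)
  looped <- numeric(50)
  for (i in 1:50) looped[i] <- m[i] - r[i]
  expect_equal(absolute_error(m, r), looped)
})

test_that("the frozen worked example [1,2,3] reproduces every intermediate", {
  r <- series_report(c(1, 2, 3))
  expect_equal(r$mean, 2)
  expect_equal(r$sigma, 1)
  expect_equal(r$s_md, 1 / sqrt(3))
  expect_equal(r$student_coefficient, 4.302653, tolerance = 1e-6)
  expect_equal(r$error, 2.484138, tolerance = 1e-5)
})

test_that("constant series have zero deviation and zero random error", {
  r <- series_report(c(1, 1, 1))
  expect_equal(r$mean, 1)
  expect_equal(r$sigma, 0)
  expect_equal(r$error, 0)
})

test_that("a single measurement yields the mean with undefined error", {
  r <- series_report(4.2)
  expect_equal(r$mean, 4.2)
  expect_true(is.na(r$error))
})

test_that("sigma and the error chain match brute-force evaluation on random series", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    r <- series_report(x)
    o <- oracle_series(x)
    expect_equal(r$mean, o$mean)
    expect_equal(r$sigma, o$sigma)
    expect_equal(r$sigma, sd(x))          # textbook n-1 cross-check
    expect_equal(r$s_md, o$s_md)
    expect_equal(r$error, o$error)
  }
})

test_that("mean, sigma, S_md and error are scale equivariant", {
  set.seed(8)
  x <- rnorm(7, 3, 1)
  for (c in c(-2.5, 0.5, 10)) {
    a <- series_report(x); b <- series_report(c * x)
    expect_equal(b$mean, c * a$mean)
    expect_equal(b$sigma, abs(c) * a$sigma)
    expect_equal(b$s_md, abs(c) * a$s_md)
    expect_equal(b$error, abs(c) * a$error)
  }
})

test_that("the 0.95 interval achieves nominal coverage on Gaussian repeats", {
  set.seed(2024)
  for (n in c(3, 5, 10)) {
    reps <- 2000
    x <- matrix(rnorm(reps * n, mean = 1.7, sd = 0.4), nrow = n)
    m <- colMeans(x)
    s <- apply(x, 2, sd)
    half <- qt(0.975, n - 1) * s / sqrt(n)
    covered <- mean(abs(m - 1.7) <= half)
    expect_gte(covered, 0.93)
    expect_lte(covered, 0.97)
    # the package's report produces the same interval on a sample column
    r <- series_report(x[, 1])
    expect_equal(r$error, half[1])
  }
})

test_that("parameter summaries group exactly like a hand-rolled split loop", {
  set.seed(12)
  d <- data.frame(
    mode = rep(c("normal", "scrolling"), each = 12),
    parameter = rep(rep(c("amplitude", "stance"), each = 6), 2),
    channel = rep(c("L1", "R1"), 12),
    value = runif(24))
  rep_tab <- summarise_parameters(d, by = c("mode", "parameter", "channel"))
  for (i in seq_len(nrow(rep_tab))) {
    grp <- d[d$mode == rep_tab$mode[i] & d$parameter == rep_tab$parameter[i] &
               d$channel == rep_tab$channel[i], "value"]
    expect_equal(rep_tab$mean[i], mean(grp))
    expect_equal(rep_tab$sigma[i], sd(grp))
    expect_equal(rep_tab$n[i], length(grp))
  }
})
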