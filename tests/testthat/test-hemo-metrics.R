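make_record <- function(f, T = 1, nt = 401, arclength = c(0, 1)) {
  t <- seq(0, T, length.out = nt)
  tau <- matrix(rep(f(t), each = length(arclength)), nrow = length(arclength))
  wall_shear_record(arclength, tau, t, T)
}

test_that("TAWSS matches hand-integrable signals", {
  r <- make_record(function(t) sin(2 * pi * t))
  expect_equal(tawss(r)[1], 2 / pi, tolerance = 1e-4)
  r2 <- make_record(function(t) rep(1.5, length(t)))
  expect_equal(tawss(r2)[1], 1.5)
  r3 <- make_record(function(t) ifelse(t < 0.5, 2, -1), nt = 4001)
  expect_equal(tawss(r3)[1], 1.5, tolerance = 1e-3)
})

test_that("OSI closed forms: unidirectional 0, zero-mean 0.5, piecewise 1/3", {
  expect_equal(osi(make_record(function(t) rep(1.5, length(t))))[1], 0)
  expect_equal(osi(make_record(function(t) sin(2 * pi * t), nt = 2001))[1], 0.5,
               tolerance = 1e-9)
  r <- make_record(function(t) ifelse(t < 0.5, 2, -1), nt = 40001)
  expect_equal(osi(r)[1], 1 / 3, tolerance = 1e-3)
})

test_that("OSI stays in [0, 0.5] for arbitrary finite signals", {
  set.seed(11)
  n <- 10000
  t <- seq(0, 1, length.out = 64)
  tau <- matrix(rnorm(n * 64, sd = rexp(n)), nrow = n)
  tau[1, ] <- 0  # degenerate zero-shear point maps to 0
  r <- wall_shear_record(seq_len(n), tau, t, 1)
  v <- osi(r)
  expect_true(all(v >= 0 & v <= 0.5))
  expect_equal(v[1], 0)
})

test_that("TAWSS and OSI are invariant under time-grid refinement", {
  f <- function(t) 0.8 * sin(2 * pi * t) + 0.3 * cos(4 * pi * t) + 0.1
  a1 <- tawss(make_record(f, nt = 201)); a2 <- tawss(make_record(f, nt = 1601))
  o1 <- osi(make_record(f, nt = 201)); o2 <- osi(make_record(f, nt = 1601))
  expect_lt(abs(a1[1] - a2[1]), 1e-3)
  expect_lt(abs(o1[1] - o2[1]), 1e-3)
})

test_that("cycle grid validation rejects non-uniform or incomplete cycles", {
  t <- c(0, 0.1, 0.5, 1)
  r <- wall_shear_record(c(0, 1), matrix(1, 2, 4), t, 1)
  expect_error(tawss(r), "uniform")
  t2 <- seq(0, 0.9, length.out = 10)
  r2 <- wall_shear_record(c(0, 1), matrix(1, 2, 10), t2, 1)
  expect_error(osi(r2), "one cycle")
})

test_that("feature summary handles uniform, constructed, and identity cases", {
  s <- seq(0, 1, length.out = 101)
  ptr <- list(cca = rep(0, 5), ica = rep(0, 5), eca = rep(0, 5))
  f <- feature_summary(rep(1, 101), rep(0, 101), s, ptr)
  expect_equal(f$peak_tawss, 1)
  expect_equal(f$vessel_avg_tawss, 1)
  expect_equal(f$frac_low_tawss, 0)
  expect_equal(f$frac_high_osi, 0)
  expect_equal(f$p_eca_over_cca, 1)
  expect_equal(f$p_ica_over_cca, 1)

  # TAWSS below threshold on exactly half the wall length
  tw <- ifelse(s < 0.5, 0.1, 1)
  tw[s == 0.5] <- 0.4  # boundary point: strict < excludes it; balance weights
  n <- length(s)
  tw2 <- c(rep(0.1, n / 2), rep(1, n / 2), 1)[seq_len(n)]
  s2 <- seq(0, 1, length.out = 100)  # even count: split cleanly at midpoint
  tw3 <- c(rep(0.1, 50), rep(1, 50))
  f2 <- feature_summary(tw3, rep(0, 100), s2, ptr)
  # wall length with TAWSS < 0.4: points 1..50 -> weights sum to 49.5/99 of total
  w <- c(0.5, rep(1, 98), 0.5) / 99
  expect_equal(f2$frac_low_tawss, sum(w[1:50]) / sum(w), tolerance = 1e-12)
})

test_that("feature fractions are invariant under uniform arc-length rescaling", {
  set.seed(3)
  s <- cumsum(runif(40, 0.5, 1.5)); s <- s - s[1]
  tw <- runif(40, 0, 2); oo <- runif(40, 0, 0.5)
  ptr <- list(cca = 1:5, ica = 2:6, eca = 3:7)
  f1 <- feature_summary(tw, oo, s, ptr)
  f2 <- feature_summary(tw, oo, 7.3 * s, ptr)
  for (nm in c("frac_low_tawss", "frac_high_osi", "vessel_avg_tawss", "vessel_avg_osi")) {
    expect_equal(f1[[nm]], f2[[nm]])
  }
})
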