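test_that("the Wiener mode update matches its closed form", {
  set.seed(41)
  n <- 16
  grid <- seq(0, 0.5, length.out = n)
  f <- complex(real = rnorm(n), imaginary = rnorm(n))
  others <- matrix(complex(real = rnorm(2 * n), imaginary = rnorm(2 * n)),
                   ncol = 2)
  dual <- complex(real = rnorm(n), imaginary = rnorm(n))
  omega_k <- 0.2
  alpha <- 9000
  got <- update_mode_spectrum(f, others, dual, omega_k, alpha, grid)
  # independent element-wise oracle
  expected <- vapply(seq_len(n), function(i) {
    (f[i] - (others[i, 1] + others[i, 2]) + dual[i] / 2) /
      (1 + 2 * alpha * (grid[i] - omega_k)^2)
  }, complex(1))
  expect_equal(got, expected)
  # zero residual and dual -> zero spectrum
  z <- rep(0 + 0i, n)
  expect_equal(update_mode_spectrum(z, matrix(z, ncol = 1), z, 0.1, alpha,
                                    grid), z)
  # at omega = omega_k the denominator is 1
  ik <- which.min(abs(grid - omega_k))
  omega_exact <- grid[ik]
  got2 <- update_mode_spectrum(f, others, dual, omega_exact, alpha, grid)
  num <- f[ik] - (others[ik, 1] + others[ik, 2]) + dual[ik] / 2
  expect_equal(got2[ik], num)
  expect_error(update_mode_spectrum(f, others, dual[1:4], 0.1, alpha, grid),
               class = "rher_invalid_input")
})

test_that("the center-frequency update is the spectral center of gravity", {
  grid <- seq(0, 0.5, length.out = 32)
  point <- rep(0 + 0i, 32)
  point[which.min(abs(grid - 0.25))] <- 3 + 0i
  expect_equal(update_center_frequency(point, grid), grid[which(point != 0)])
  # symmetric spectrum about 0.25
  sym <- rep(0 + 0i, 32)
  c0 <- which.min(abs(grid - 0.25))
  sym[c0 - 3] <- 2i; sym[c0 + 3] <- 2
  expect_equal(update_center_frequency(sym, grid),
               (grid[c0 - 3] + grid[c0 + 3]) / 2)
  set.seed(42)
  spec <- complex(real = rnorm(32), imaginary = rnorm(32))
  oracle <- sum(grid * Mod(spec)^2) / sum(Mod(spec)^2)
  expect_equal(update_center_frequency(spec, grid), oracle)
  expect_error(update_center_frequency(rep(0 + 0i, 32), grid),
               class = "rher_undefined_frequency")
})

test_that("the convergence metric is a relative squared change", {
  set.seed(43)
  u <- matrix(complex(real = rnorm(40), imaginary = rnorm(40)), ncol = 2)
  expect_equal(convergence_metric(u, u), 0)
  eps <- 1e-4
  scaled <- u
  scaled[, 1] <- (1 + eps) * u[, 1]
  expect_equal(convergence_metric(u, scaled), eps^2, tolerance = 1e-6)
  v <- u + matrix(complex(real = rnorm(40, sd = 0.01),
                          imaginary = rnorm(40, sd = 0.01)), ncol = 2)
  oracle <- sum(Mod(v[, 1] - u[, 1])^2) / sum(Mod(u[, 1])^2) +
            sum(Mod(v[, 2] - u[, 2])^2) / sum(Mod(u[, 2])^2)
  expect_equal(convergence_metric(u, v), oracle)
  # zero previous mode falls back to absolute change
  z <- matrix(0 + 0i, nrow = 20, ncol = 1)
  w <- matrix(2 + 0i, nrow = 20, ncol = 1)
  expect_equal(convergence_metric(z, w), 80)
  expect_error(convergence_metric(u, u[1:10, ]),
               class = "rher_invalid_input")
})

test_that("a zero signal decomposes to zero modes immediately", {
  fit <- vmd(rep(0, 64), rate = 20)
  expect_true(all(fit$modes == 0))
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1L)
})

test_that("a single tone's center frequency is recovered within one bin", {
  x <- make_tone(1.0)
  fit <- vmd(x, 20, vmd_config(K = 1, alpha = 2000))
  expect_lt(abs(fit$center_freqs - 1.0), 0.05)
  expect_true(fit$converged)
  expect_equal(nrow(fit$modes), length(x))
})

test_that("two tones separate into sorted, band-separated modes", {
  x <- make_tone(0.35) + make_tone(1.35, amp = 0.25)
  fit <- vmd(x, 20, vmd_config(K = 2))
  expect_lt(abs(fit$center_freqs[1] - 0.35), 0.05)
  expect_lt(abs(fit$center_freqs[2] - 1.35), 0.05)
  expect_true(all(diff(fit$center_freqs) > 0))
  e <- colSums(fit$modes^2)
  expect_gt(e[1], e[2])
  # band separation: little of mode 1's energy above the midpoint
  mag1 <- Mod(fft(fit$modes[, 1]))[1:200]^2
  freq <- (0:199) * 20 / 400
  midpoint <- mean(fit$center_freqs)
  expect_lt(sum(mag1[freq > midpoint]) / sum(mag1), 0.10)
})

test_that("reported center frequencies are fixed points of the update", {
  x <- make_tone(0.35) + make_tone(1.35, amp = 0.25)
  fit <- vmd(x, 20, vmd_config(K = 2))
  n <- length(x)
  for (k in 1:2) {
    spec <- fft(fit$modes[, k])[1:(n %/% 2 + 1)]
    grid <- (0:(n %/% 2)) * 20 / n
    expect_lt(abs(update_center_frequency(spec, grid) -
                  fit$center_freqs[k]), 0.05)
  }
})

test_that("decomposition is deterministic for deterministic inits", {
  x <- make_tone(0.4) + make_tone(1.6, amp = 0.3)
  f1 <- vmd(x, 20)
  f2 <- vmd(x, 20)
  expect_identical(f1$modes, f2$modes)
  expect_identical(f1$center_freqs, f2$center_freqs)
})

test_that("the respiration mode outweighs the heartbeat mode for a
           human-like signal", {
  # human preset regime: respiration displacement ~10x heartbeat
  x <- make_tone(0.35) + make_tone(1.35, amp = 0.1)
  fit <- vmd(x, 20)
  sel <- select_vimfs(fit)
  expect_gt(sum(sel$u_r^2), sum(sel$u_h^2))
})

test_that("invalid inputs are rejected and non-convergence is reported", {
  expect_error(vmd(c(1, NA, 3, 4, 5, 6, 7, 8), 20),
               class = "rher_invalid_input")
  expect_error(vmd(1:4, 20), class = "rher_invalid_input")
  x <- make_tone(0.35) + make_tone(1.35, amp = 0.25)
  fit <- vmd(x, 20, vmd_config(K = 2, max_iter = 3))
  expect_false(fit$converged)
  expect_equal(fit$n_iterations, 3L)
})

test_that("residuals() returns the unexplained part of the signal", {
  x <- make_tone(0.5)
  fit <- vmd(x, 20, vmd_config(K = 1, alpha = 2000))
  expect_equal(residuals(fit), x - rowSums(fit$modes))
  expect_lt(sqrt(sum(residuals(fit)^2) / sum(x^2)), 0.05)
})

test_that("VIMF export writes modes and metadata", {
  x <- make_tone(0.5, duration = 5)
  fit <- vmd(x, 20, vmd_config(K = 1, alpha = 2000))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vimfs(fit, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(x))
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  expect_equal(meta$center_freqs_hz, fit$center_freqs, tolerance = 1e-12)
})
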