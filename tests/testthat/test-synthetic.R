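test_that("prbs is two-level, band-concentrated, and seed-deterministic", {
  x <- prbs(1024, c(0, 0.3), seed = 1)
  expect_true(all(x %in% c(-1, 1)))
  expect_lt(abs(mean(x)), 5 / sqrt(1024))
  expect_identical(x, prbs(1024, c(0, 0.3), seed = 1))
  expect_false(identical(x, prbs(1024, c(0, 0.3), seed = 2)))
  # >= 90% of spectral power below 0.35 normalized frequency
  for (s in 1:5) {
    z <- prbs(1024, c(0, 0.3), seed = s)
    sp <- Mod(stats::fft(z))^2
    f <- 2 * (1:511) / 1024
    expect_gt(sum(sp[2:512][f <= 0.35]) / sum(sp[2:512]), 0.9)
  }
  expect_error(prbs(100, c(0.5, 0.5)), class = "sideobsp_invalid_parameter")
  expect_error(prbs(100, c(-0.1, 0.5)), class = "sideobsp_invalid_parameter")
})

test_that("benchmark subsystem filters have the stated frequency responses", {
  flt <- subsystem_filters()
  H <- function(f, b, a) {
    z <- exp(-2i * pi * f / 2)   # f in half-cycles/sample
    Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
  }
  expect_equal(H(0, flt$f1$b, flt$f1$a), 1, tolerance = 1e-10)  # DC gain 1
  expect_equal(H(0.15, flt$f2$b, flt$f2$a), 1, tolerance = 0.05) # band center
  expect_lt(H(0, flt$f2$b, flt$f2$a), 1e-10)
  expect_lt(H(1, flt$f2$b, flt$f2$a), 1e-10)
  expect_equal(H(0.1, flt$f3$b, flt$f3$a), 1, tolerance = 0.05)
  # truncated FIR reproduces the recursive filter on a PRBS input
  x <- prbs(2048, c(0, 0.3), seed = 4)
  for (f in flt) {
    y_iir <- f$apply(x)
    y_fir <- drop(stats::convolve(x, rev(f$fir), type = "open"))[seq_along(x)]
    expect_lt(sqrt(mean((y_iir - y_fir)^2)), 1e-4)
  }
})

test_that("mix_correlated achieves the target correlation for independent inputs", {
  withr::with_seed(6, {
    x <- rnorm(1e5)
    r <- rnorm(1e5)
  })
  expect_equal(mix_correlated(x, r, 0), (x - mean(x)) / sd(x))
  expect_lt(max(abs(mix_correlated(x, r, 1 - 1e-9) -
    (r - mean(r)) / sd(r))), 1e-3)
  expect_equal(cor(mix_correlated(x, r, 0.5), r), 0.5, tolerance = 0.01)
  expect_error(mix_correlated(x, r, 1), class = "sideobsp_invalid_parameter")
  expect_error(mix_correlated(x, r, -0.2), class = "sideobsp_invalid_parameter")
})

test_that("add_noise_snr hits the requested power ratio with bounded uniform noise", {
  withr::with_seed(14, x <- rnorm(1024))
  expect_identical(add_noise_snr(x, Inf), x)
  y <- add_noise_snr(x, 0, seed = 2)
  e <- y - x
  p_sig <- mean((x - mean(x))^2)
  expect_equal(mean(e^2) / p_sig, 1, tolerance = 0.05)
  # 4 dB realization, exactly scaled
  y4 <- add_noise_snr(x, 4, seed = 2)
  expect_equal(10 * log10(p_sig / mean((y4 - x)^2)), 4, tolerance = 1e-8)
  # uniform noise: bounded support with var = (b - a)^2 / 12
  e4 <- y4 - x
  half_width <- (max(e4) - min(e4)) / 2
  expect_equal(stats::var(e4), (2 * half_width)^2 / 12, tolerance = 0.1)
  expect_lt(max(abs(e4)), 1.05 * sqrt(3 * mean(e4^2)))
  expect_error(add_noise_snr(rep(1, 100), 4), class = "sideobsp_invalid_input")
})

test_that("the benchmark generator is reproducible and keeps exact bookkeeping", {
  b1 <- generate_benchmark(seed = 4, n = 512)
  b2 <- generate_benchmark(seed = 4, n = 512)
  expect_identical(b1$data, b2$data)
  expect_identical(b1$true_h, b2$true_h)
  # y = sum of components + contamination + noise, exactly
  expect_equal(b1$data$y,
    rowSums(b1$true_components) + b1$contamination + b1$noise_y,
    tolerance = 1e-12)
  # realized input correlation near the target
  cors <- cor(b1$clean_inputs)
  expect_lt(max(abs(cors[upper.tri(cors)] - 0.25)), 0.1)
  # realized SNR is exact by construction
  p_sig <- mean((rowSums(b1$true_components) + b1$contamination -
    mean(rowSums(b1$true_components) + b1$contamination))^2)
  expect_equal(10 * log10(p_sig / mean(b1$noise_y^2)), 4, tolerance = 1e-6)
})

test_that("noise-free uncorrelated benchmark is recovered exactly at the true order", {
  b <- generate_benchmark(seed = 6, n = 768, rho = 0, snr_db = Inf,
    output_mix_rho = 0)
  fit <- side_obsp(b$data, "y", order = 50, gamma = 0, center = FALSE)
  expect_lt(max(abs(fit$h - b$true_h)), 1e-4)
  expect_lt(sqrt(mean(fit$residual^2)), 1e-8 * sqrt(mean(fit$y_trim^2)))
})

test_that("the physiological scenario exposes ground truth and decouples the desaturation", {
  s1 <- generate_physio_scenario(seed = 10)
  s2 <- generate_physio_scenario(seed = 10)
  expect_identical(s1$data, s2$data)
  expect_equal(s1$fs, 1 / 3)
  # zero-amplitude events and no baseline fluctuation: no SaO2 component
  s0 <- generate_physio_scenario(seed = 10, event_depth = 0, sao2_noise = 0)
  expect_equal(max(abs(s0$true_components[, "SaO2"])), 0)

  # decomposition: the pressure component stays free of the desaturation step
  fit <- side_obsp(s1$data, "TOI", fs = s1$fs, order = 15, gamma = 0)
  n <- nrow(s1$data)
  tm <- s1$true_components[16:n, ]
  for (t0 in s1$event_times) {
    w <- which(fit$time_trim >= t0 & fit$time_trim <= t0 + 400)
    pre <- which(fit$time_trim >= t0 - 400 & fit$time_trim < t0)
    leak <- max(abs(fit$components[w, "MABP"] - tm[w, "MABP"]))
    step <- max(abs(tm[w, "SaO2"] - stats::median(tm[pre, "SaO2"])))
    expect_lt(leak / step, 0.1)
  }
  # and the SaO2 component tracks its injected truth
  expect_gt(cor(fit$components[, "SaO2"], tm[, "SaO2"]), 0.99)
})
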