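test_that("regularization matrix is the first-difference operator", {
  expect_equal(regularization_matrix(3), rbind(c(-1, 1, 0), c(0, -1, 1)))
  expect_equal(regularization_matrix(2), matrix(c(-1, 1), 1))
  G <- regularization_matrix(12)
  expect_equal(drop(G %*% rep(3.7, 12)), rep(0, 11))
  expect_error(regularization_matrix(1), class = "sideobsp_invalid_order")
})

test_that("solve_block matches the unregularized solution and the penalty limits", {
  blocks <- make_blocks(120, 6, 8, 31, shared = 0.5)
  part <- block_partition(blocks$A_k, blocks$A_rest)
  withr::with_seed(31, y <- rnorm(120))
  # gamma = 0: exactly the complement-projected least-squares solution
  expect_equal(solve_block(part, y, gamma = 0),
    equivalent_ls_solution(part, y), tolerance = 1e-10)
  # penalty-dominant limit: only the constant null space of the difference
  # operator survives
  M <- crossprod(complement_projector(blocks$A_rest) %*% blocks$A_k)
  h_big <- solve_block(part, y, gamma = 1e12 * norm(M, "2"))
  expect_lt(max(abs(h_big - mean(h_big))), 1e-6 * max(abs(h_big), 1e-12))
  expect_error(solve_block(part, y, gamma = -1),
    class = "sideobsp_invalid_parameter")
})

test_that("a single-input noise-free system is recovered exactly", {
  withr::with_seed(8, {
    s <- rnorm(300)
    h_true <- exp(-(0:9) / 3)
  })
  A <- block_hankel(s, 10)
  y <- drop(A %*% h_true)
  part <- block_partition(A, matrix(0, nrow(A), 0))
  expect_lt(max(abs(solve_block(part, y, gamma = 0) - h_true)), 1e-6)
})

test_that("decomposition is additive and equals the oblique projection at gamma 0", {
  withr::with_seed(12, {
    df <- data.frame(a = rnorm(200), b = rnorm(200), y = rnorm(200))
  })
  fit <- side_obsp(df, target = "y", order = 6, gamma = 0)
  # bookkeeping identity holds exactly
  expect_equal(rowSums(fit$components) + fit$residual, fit$y_trim)
  # components equal P_k.(k) y formed explicitly
  des <- build_design(signal_set(df, "y"), 6)
  for (k in 1:2) {
    part <- design_partition(des, k)
    P <- oblique_projector(part)$P_oblique
    expect_equal(fit$components[, k], drop(P %*% des$y_trim),
      tolerance = 1e-8)
  }
})

test_that("the smoothness penalty of the fit is non-increasing in gamma", {
  bench <- generate_benchmark(seed = 5, n = 512)
  G <- regularization_matrix(30)
  gammas <- 10^seq(-2, 4, length.out = 7)
  pen <- vapply(gammas, function(g) {
    h <- side_obsp(bench$data, "y", order = 30, gamma = g)$h
    sqrt(sum((G %*% h)^2))
  }, numeric(1))
  expect_true(all(diff(pen) <= 1e-10))
})

test_that("oblique decomposition recovers correlated-input subsystems where per-input OLS fails", {
  bench <- generate_benchmark(seed = 17, n = 768, rho = 0.5, snr_db = Inf,
    output_mix_rho = 0)
  fit <- side_obsp(bench$data, "y", order = 50, gamma = 0, center = FALSE)
  expect_lt(max(abs(fit$h - bench$true_h)), 1e-6)
  fit_ols <- side_obsp(bench$data, "y", order = 50, gamma = 0,
    center = FALSE, projection = "none")
  expect_gt(max(abs(fit_ols$h - bench$true_h)), 1e-3)
})

test_that("supplying the output as one of its own inputs raises an ill-posed warning", {
  withr::with_seed(23, s <- rnorm(300))
  y <- drop(block_hankel(s, 5) %*% c(1, 0.5, 0.2, 0.1, 0.05))
  df <- data.frame(a = s[6:300], dup = y, y = y)
  warns <- character(0)
  withCallingHandlers(
    side_obsp(df, target = "y", order = 5, gamma = 0, center = FALSE),
    sideobsp_ill_posed = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_gte(length(warns), 1)
  # the warning names the offending channel
  expect_true(any(grepl("'dup'|'a'", warns)))
})

test_that("cross-validation finds the true order on noise-free data and engages gamma under noise", {
  bench <- generate_benchmark(seed = 2, rho = 0, snr_db = Inf,
    output_mix_rho = 0, n_taps = 20, band = c(0, 1))
  cv <- cross_validate(bench$data, "y", order_grid = c(10, 20, 30),
    gamma_grid = 0, folds = 5, center = FALSE)
  expect_equal(cv$order, 20)
  expect_lt(min(cv$cv_trace$cv_error), 1e-12)
  # under benchmark noise the selected regularization constant is positive
  gammas <- vapply(1:3, function(s) {
    cross_validate(generate_benchmark(seed = s, n = 768)$data, "y",
      order_grid = 50, folds = 10)$gamma
  }, numeric(1))
  expect_true(all(gammas > 0))
  expect_error(cross_validate(bench$data, "y", order_grid = 20, folds = 1),
    class = "sideobsp_invalid_fold")
  expect_error(cross_validate(bench$data, "y", order_grid = integer(0)),
    class = "sideobsp_invalid_parameter")
})

test_that("training fit error is non-increasing as gamma decreases on a fixed design", {
  bench <- generate_benchmark(seed = 9, n = 512)
  gammas <- 10^seq(4, -2, length.out = 7)   # decreasing
  sse <- vapply(gammas, function(g) {
    fit <- side_obsp(bench$data, "y", order = 25, gamma = g)
    sum(fit$residual^2)
  }, numeric(1))
  expect_true(all(diff(sse) <= 1e-8 * sse[1]))
})

test_that("frequency response matches closed forms and the benchmark subsystem", {
  # unit impulse: flat amplitude 1
  df <- data.frame(a = c(1, rep(0, 99)), y = c(1, rep(0, 99)))
  fit <- suppressWarnings(
    side_obsp(df, "y", order = 4, gamma = 0, center = FALSE))
  fit$h[, 1] <- c(1, 0, 0, 0)
  fr <- frequency_response(fit, n_freq = 64)
  expect_equal(drop(fr$amplitude), rep(1, 64))
  expect_equal(range(fr$freq), c(0, 0.5))
  # two-tap mean: |cos(pi f / fs)| shape, 1 at DC, 0 at Nyquist
  fit$h[, 1] <- c(0.5, 0.5, 0, 0)
  fr2 <- frequency_response(fit, n_freq = 33)
  expect_equal(drop(fr2$amplitude), abs(cos(pi * fr2$freq)), tolerance = 1e-12)
  expect_error(frequency_response(fit, n_freq = 2),
    class = "sideobsp_invalid_parameter")

  # estimated low-pass subsystem tracks the analytic Butterworth amplitude
  bench <- generate_benchmark(seed = 13, rho = 0, snr_db = Inf,
    output_mix_rho = 0)
  fitb <- side_obsp(bench$data, "y", order = 50, gamma = 0, center = FALSE)
  frb <- frequency_response(fitb, n_freq = 128)
  flt <- subsystem_filters()$f1
  H_ref <- vapply(frb$freq, function(f) {
    z <- exp(-2i * pi * f)
    Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
        sum(flt$a * z^(seq_along(flt$a) - 1)))
  }, numeric(1))
  in_band <- frb$freq <= 0.2
  expect_lt(max(abs(frb$amplitude[in_band, "x1"] - H_ref[in_band])), 0.05)
})

test_that("tidy, glance and plot methods expose the fit consistently", {
  bench <- generate_benchmark(seed = 3, n = 512)
  fit <- side_obsp(bench$data, "y", order = 20, gamma = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3 * length(fit$y_trim))
  ir <- tidy(fit, "impulse_response")
  expect_equal(nrow(ir), 3 * 20)
  g <- glance(fit)
  expect_equal(g$order, 20)
  expect_true(g$r_squared > 0 && g$r_squared <= 1)
  expect_equal(g$residual_rms, sqrt(mean(fit$residual^2)))
  expect_true(all(tail_mass(fit) >= 0 & tail_mass(fit) <= 1))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(frequency_response(fit, 64)), "ggplot")
  expect_s3_class(plot_impulse_responses(fit, bench$true_h[1:20, ]), "ggplot")
})

test_that("a fixed seed and configuration give bit-identical decompositions", {
  b1 <- generate_benchmark(seed = 77, n = 512)
  b2 <- generate_benchmark(seed = 77, n = 512)
  f1 <- side_obsp(b1$data, "y", order = 30, gamma = "auto", folds = 5)
  f2 <- side_obsp(b2$data, "y", order = 30, gamma = "auto", folds = 5)
  expect_identical(f1$h, f2$h)
  expect_identical(f1$components, f2$components)
  expect_identical(f1$gamma, f2$gamma)
})
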