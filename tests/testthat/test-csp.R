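# Epochs whose channels are scaled orthogonal sinusoids, giving exactly
# diagonal per-epoch covariance with the requested variances.
diag_epochs <- function(vars, n = 3, samples = 512, fs = 128,
                        klass = "baseline") {
  t <- (seq_len(samples) - 1) / fs
  arr <- array(0, c(n, length(vars), samples))
  for (tr in seq_len(n))
    for (ch in seq_along(vars))
      arr[tr, ch, ] <- sqrt(2 * vars[ch]) * sin(2 * pi * (8 * ch) * t)
  epoch_set(arr, fs, 17, "c", klass, paste0("ch", seq_along(vars)))
}

rand_epochs <- function(channels, n = 6, samples = 128, seed_mix = NULL,
                        klass = "baseline") {
  mix <- seed_mix %||% matrix(rnorm(channels^2), channels)
  arr <- array(0, c(n, channels, samples))
  for (tr in seq_len(n))
    arr[tr, , ] <- mix %*% matrix(rnorm(channels * samples), channels)
  epoch_set(arr, 128, 17, "c", klass, paste0("ch", seq_len(channels)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("CSP recovers the analytic solution for diagonal covariances", {
  stim <- diag_epochs(c(10, 1), klass = "stimulation")
  base <- diag_epochs(c(1, 1), klass = "baseline")
  flt <- fit_csp(stim, base, normalize = FALSE)
  expect_equal(abs(as.numeric(flt$weights)), c(1, 0), tolerance = 1e-6)
  expect_equal(flt$eigenvalue, 10, tolerance = 1e-6)
  # trace normalization rescales the achieved ratio but not the weights
  fltn <- fit_csp(stim, base)
  expect_equal(abs(as.numeric(fltn$weights)), c(1, 0), tolerance = 1e-6)
  expect_equal(fltn$eigenvalue, (10 / 11) / (1 / 2), tolerance = 1e-6)
})

test_that("identically distributed classes give a variance ratio near 1", {
  set.seed(8)
  mix <- matrix(rnorm(16), 4)
  stim <- rand_epochs(4, n = 50, samples = 512, seed_mix = mix,
                      klass = "stimulation")
  base <- rand_epochs(4, n = 50, samples = 512, seed_mix = mix)
  flt <- fit_csp(stim, base)
  expect_equal(flt$eigenvalue, 1, tolerance = 0.2)
})

test_that("the eigenproblem solution matches brute-force Rayleigh search", {
  set.seed(21)
  for (rep in 1:10) {
    ch <- sample(2:7, 1)
    stim <- rand_epochs(ch, n = 4, klass = "stimulation")
    base <- rand_epochs(ch, n = 4)
    flt <- fit_csp(stim, base)
    cs <- ssvepr:::class_covariance(stim$epochs)
    cb <- ssvepr:::class_covariance(base$epochs)
    w <- matrix(rnorm(20000 * ch), 20000, ch)
    ratios <- rowSums((w %*% cs) * w) / rowSums((w %*% cb) * w)
    expect_gte(flt$eigenvalue, max(ratios) * (1 - 0.01))
  }
})

test_that("CSP is scale-invariant and class-swap consistent", {
  set.seed(3)
  stim <- rand_epochs(3, n = 5, klass = "stimulation")
  base <- rand_epochs(3, n = 5)
  flt <- fit_csp(stim, base)
  scaled <- stim
  scaled$epochs <- stim$epochs * 7.3
  flt_s <- fit_csp(scaled, base)
  # trace normalization makes the fit invariant to class-wide scaling
  expect_equal(flt_s$weights, flt$weights, tolerance = 1e-9)
  expect_equal(flt_s$eigenvalue, flt$eigenvalue, tolerance = 1e-9)
  # swapping the classes: the swapped top eigenvalue is at least 1/lambda
  swap <- fit_csp(base, stim)
  expect_gte(swap$eigenvalue, 1 / flt$eigenvalue - 1e-9)
})

test_that("projection applies the weight vector exactly", {
  set.seed(4)
  ep <- rand_epochs(3, n = 2)
  flt <- structure(list(weights = stats::setNames(c(1, 0, 0), ep$channel_labels),
                        eigenvalue = 1, frequency = 17,
                        channel_labels = ep$channel_labels),
                   class = "csp_filter")
  proj <- apply_csp(ep, flt)
  expect_equal(dim(proj$epochs), c(2, 1, 128))
  expect_equal(proj$epochs[1, 1, ], ep$epochs[1, 1, ])
  # weights orthogonal to the only active axis null the output
  one_axis <- ep
  one_axis$epochs[, 2:3, ] <- 0
  flt$weights <- stats::setNames(c(0, 1, 0), ep$channel_labels)
  expect_equal(max(abs(apply_csp(one_axis, flt)$epochs)), 0)
  # channel mismatch rejected
  flt$channel_labels <- c("x", "y", "z")
  expect_error(apply_csp(ep, flt), "channels")
})

test_that("mismatched or degenerate inputs are rejected", {
  a <- rand_epochs(3, n = 3, klass = "stimulation")
  b <- rand_epochs(4, n = 3)
  expect_error(fit_csp(a, b), "mismatched channels")
  expect_error(fit_csp(a, rand_epochs(3, n = 1)), "at least 2 epochs")
  # rank-deficient baseline: one-dimensional signals on 3 channels
  t <- (0:127) / 128
  arr <- array(0, c(3, 3, 128))
  for (tr in 1:3) arr[tr, , ] <- outer(c(1, 2, 3), sin(2 * pi * 10 * t))
  flat <- epoch_set(arr, 128, 17, "c", "baseline", paste0("ch", 1:3))
  expect_error(fit_csp(a, flat), "rank-deficient")
})

test_that("projected stimulation variance exceeds baseline variance per trial", {
  cfg <- small_config(reps = 10, freqs = c(14, 17, 25, 30), seed = 6)
  rec <- simulate_session(cfg)
  rec <- rereference_mastoids(select_channels(rec))
  em <- extract_epochs(rec)
  wins <- 0; total <- 0
  for (cell in em) {
    spec <- design_bandpass(cell$stimulation$frequency, 128)
    stim <- apply_bandpass(cell$stimulation, spec)
    base <- apply_bandpass(cell$baseline, spec)
    flt <- fit_csp(stim, base)
    ps <- apply_csp(stim, flt)$epochs
    pb <- apply_csp(base, flt)$epochs
    for (tr in seq_len(dim(ps)[1])) {
      wins <- wins + (stats::var(ps[tr, 1, ]) > stats::var(pb[tr, 1, ]))
      total <- total + 1
    }
  }
  expect_gte(wins / total, 0.95)
})
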