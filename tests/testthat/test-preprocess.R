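make_rec <- function(data, fs = 128, labels = NULL, markers = NULL) {
  labels <- labels %||% paste0("ch", seq_len(nrow(data)))
  raw_recording(data, fs, labels, markers)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("select_channels returns requested channels in requested order", {
  rec <- make_rec(matrix(1:12, 4, 3), labels = c("O1", "O2", "M1", "M2"))
  sel <- select_channels(rec, c("m2", "O1"))   # case-insensitive
  expect_equal(sel$channel_labels, c("M2", "O1"))
  expect_equal(sel$data[2, ], rec$data[1, ])
  # identity selection leaves the recording unchanged
  all_sel <- select_channels(rec, rec$channel_labels)
  expect_equal(all_sel$data, rec$data)
  expect_error(select_channels(rec, "O3"), "O3 not found")
})

test_that("linked-mastoid re-referencing subtracts (M1+M2)/2 and drops mastoids", {
  dat <- rbind(O1 = c(5, 7), Pz = c(3, 3), M1 = c(2, 4), M2 = c(4, 4))
  rr <- rereference_mastoids(make_rec(dat, labels = rownames(dat)))
  expect_equal(rr$channel_labels, c("O1", "Pz"))
  expect_equal(rr$data["O1", ], c(2, 3))
  # channels equal to the mastoid mean cancel to zero
  dat2 <- rbind(O1 = c(3, 4), M1 = c(2, 4), M2 = c(4, 4))
  expect_equal(rereference_mastoids(make_rec(dat2, labels = rownames(dat2)))$data["O1", ],
               c(0, 0))
  expect_error(rereference_mastoids(make_rec(dat[1:2, , drop = FALSE],
                                             labels = c("O1", "Pz"))),
               "M1")
})

test_that("re-referencing leaves SSVEP band power intact when mastoids are silent", {
  # background off: the recording holds only the mastoid-silent SSVEP
  cfg <- small_config(reps = 2, freqs = c(17), seed = 2,
                      noise_psd_10hz = 0, alpha_amplitude = 0)
  rec <- simulate_session(cfg)
  rr <- rereference_mastoids(rec)
  o1 <- match("O1", rec$channel_labels)
  mk <- rec$markers
  for (i in seq_len(nrow(mk))) {
    idx <- mk$onset[i] + 1:512
    before <- band_power(rec$data[o1, idx], 128, 17)
    after <- band_power(rr$data[match("O1", rr$channel_labels), idx], 128, 17)
    expect_equal(after, before, tolerance = 1e-9)
  }
})

test_that("downsampling decimates, preserves DC and in-band sinusoids", {
  fs <- 1024
  n <- 4096
  # sample count and rate
  rec <- make_rec(matrix(rnorm(n), 1, n), fs = fs)
  dn <- downsample(rec, 128)
  expect_equal(ncol(dn$data), 512)
  expect_equal(dn$sampling_rate, 128)
  # DC passes with unit gain
  dc <- downsample(make_rec(matrix(2.5, 1, n), fs = fs), 128)
  expect_equal(max(abs(dc$data - 2.5)), 0, tolerance = 1e-6)
  # 10 Hz sinusoid survives with its RMS intact (transients trimmed)
  t <- (0:(n - 1)) / fs
  sn <- downsample(make_rec(matrix(sin(2 * pi * 10 * t), 1, n), fs = fs), 128)
  core <- sn$data[1, 65:(512 - 64)]
  expect_equal(sqrt(mean(core^2)), 1 / sqrt(2), tolerance = 0.01)
  # non-integer factor rejected
  expect_error(downsample(rec, 100), "integer multiple")
  # factor 1 is the identity
  expect_identical(downsample(rec, 1024), rec)
})

test_that("downsampling is linear and rescales marker onsets", {
  fs <- 512
  n <- 2048
  x <- rnorm(n); y <- rnorm(n)
  d <- function(v) downsample(make_rec(matrix(v, 1, n), fs = fs), 128)$data[1, ]
  expect_equal(d(2 * x + 3 * y), 2 * d(x) + 3 * d(y), tolerance = 1e-9)
  mk <- data.frame(onset = 1024, frequency = 17, condition = "c")
  dn <- downsample(make_rec(matrix(x, 1, n), fs = fs, markers = mk), 128)
  expect_equal(dn$markers$onset, 256)
})

test_that("epoch extraction slices [onset, onset+4s) and [onset-4s, onset) exactly", {
  fs <- 128
  n <- 20 * fs
  dat <- matrix(seq_len(2 * n), 2, n, byrow = TRUE)
  mk <- data.frame(onset = 10 * fs, frequency = 17, condition = "c")
  em <- extract_epochs(make_rec(dat, fs = fs, labels = c("a", "b"), markers = mk))
  cell <- em[["c|17"]]
  # 0-based samples [1280, 1792) -> R columns 1281:1792; pure slices
  expect_equal(cell$stimulation$epochs[1, 1, ], dat[1, 1281:1792])
  expect_equal(cell$baseline$epochs[1, 1, ], dat[1, 769:1280])
  expect_equal(dim(cell$stimulation$epochs), c(1, 2, 512))
  expect_equal(n_trials <- dim(cell$baseline$epochs)[1], 1)
})

test_that("markers without a full margin are dropped with a warning", {
  fs <- 128
  dat <- matrix(rnorm(12 * fs), 1, 12 * fs)
  mk <- data.frame(onset = c(2 * fs, 6 * fs), frequency = 17, condition = "c")
  expect_warning(em <- extract_epochs(make_rec(dat, fs = fs, markers = mk)),
                 "dropped 1 marker")
  expect_equal(dim(em[["c|17"]]$stimulation$epochs)[1], 1)
  mk_bad <- data.frame(onset = 2 * fs, frequency = 17, condition = "c")
  expect_error(suppressWarnings(
    extract_epochs(make_rec(dat, fs = fs, markers = mk_bad))),
    "no usable markers")
})

test_that("a simulated session yields equal stimulation/baseline trial counts", {
  cfg <- small_config(reps = 4, freqs = c(14, 17),
                      conditions = list(condition_spec("a", 2),
                                        condition_spec("b", 1)))
  em <- extract_epochs(simulate_session(cfg))
  expect_length(em, 4)
  for (cell in em) {
    expect_equal(dim(cell$stimulation$epochs)[1], 4)
    expect_equal(dim(cell$baseline$epochs)[1], 4)
    expect_equal(dim(cell$stimulation$epochs)[3], 512)
  }
})
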