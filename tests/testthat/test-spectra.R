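test_that("wide CSV round trip builds a collection with joined metadata", {
  wl <- 300:700
  df <- data.frame(wl = wl, s1 = gauss_refl(wl, 550, 30), s2 = rep(20, 401))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  x <- read_spectra(f)
  expect_equal(n_spectra(x), 2)
  expect_equal(length(x$wl), 401)
  expect_equal(x$meta$morph, c("unknown", "unknown"))

  m <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "s1", morph = "green", patch = "dorsal"),
            m, row.names = FALSE)
  x2 <- suppressWarnings(read_spectra(f, m))
  expect_equal(x2$meta$morph, c("green", "unknown"))
  expect_equal(x2$meta$patch[1], "dorsal")
})

test_that("malformed spectra files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wl,s1", "500,1", "500,2", "600,3"), f)
  expect_error(read_spectra(f), "strictly increasing")
  writeLines(c("wl,s1", "500,1", "510,oops"), f)
  expect_error(read_spectra(f), "row 2")
  writeLines(c("wl,s1,s1", "500,1,2", "510,1,2"), f)
  expect_error(read_spectra(f), "[Dd]uplicate")
})

test_that("clip_range restricts inclusively and refuses empty results", {
  wl <- seq(250, 750, by = 1)
  x <- make_spectra(wl, a = rep(10, length(wl)))
  y <- clip_range(x, 300, 700)
  expect_equal(range(y$wl), c(300, 700))
  expect_identical(clip_range(y, 300, 700)$refl, y$refl)
  expect_error(clip_range(y, 800, 900), "no grid points")
})

test_that("non-negativity offset adds |min| per spectrum and is idempotent", {
  x <- make_spectra(500:502, a = c(-0.02, 0.50, 1.00), b = c(1, 2, 3),
                    c = c(-5, -1, -3))
  y <- offset_nonnegative(x)
  expect_equal(y$refl[, "a"], c(0, 0.52, 1.02), ignore_attr = TRUE)
  expect_identical(y$refl[, "b"], x$refl[, "b"])  # no-op branch
  expect_equal(min(y$refl[, "a"]), 0)
  expect_equal(min(y$refl[, "c"]), 0)
  expect_identical(offset_nonnegative(y)$refl, y$refl)
})

test_that("artifact window repair replaces only the window, with the flank mean", {
  wl <- seq(600, 700, by = 0.5)
  y <- rep(10, length(wl))
  y[wl >= 661 & wl <= 664] <- 12
  spike <- ifelse(wl >= 653.5 & wl <= 660.5, 80, y)
  x <- make_spectra(wl, a = spike)
  r <- repair_artifact_window(x)
  in_win <- wl >= 653.5 & wl <= 660.5
  expect_equal(unique(r$refl[in_win, "a"]), 11)  # equal-count flanks at 10 and 12
  expect_identical(r$refl[!in_win, "a"], x$refl[!in_win, "a"])
  expect_identical(repair_artifact_window(r)$refl, r$refl)  # idempotent

  cst <- make_spectra(wl, a = rep(7, length(wl)))
  expect_equal(repair_artifact_window(cst)$refl, cst$refl)
  outside <- make_spectra(300:400, a = rep(3, 101))
  expect_identical(repair_artifact_window(outside)$refl, outside$refl)
  expect_error(repair_artifact_window(x, flanks = list(c(0, 1), c(661, 664))),
               "flank")
})

test_that("replicate averaging is the pointwise group mean", {
  wl <- 300:310
  meta <- data.frame(sample_id = c("a1", "a2", "b1"),
                     individual = c("A", "A", "B"),
                     patch = "dorsal", replicate = c(1, 2, 1))
  x <- make_spectra(wl, a1 = rep(10, 11), a2 = rep(20, 11), b1 = rep(5, 11),
                    meta = meta)
  avg <- average_replicates(x)
  expect_equal(n_spectra(avg), 2)
  expect_equal(unique(avg$refl[, 1]), 15)
  expect_equal(avg$meta$n_replicates, c(2L, 1L))
  expect_true(all(is.na(avg$meta$replicate)))

  # brute-force loop mean on a random replicated design
  set.seed(11)
  n <- 12
  meta2 <- data.frame(sample_id = paste0("s", 1:n),
                      individual = rep(c("A", "B"), each = 6),
                      patch = rep(c("dorsal", "lateral"), times = 6))
  refl <- matrix(runif(11 * n), 11, n, dimnames = list(NULL, meta2$sample_id))
  x2 <- spectra(wl, refl, meta2)
  avg2 <- average_replicates(x2)
  expect_equal(n_spectra(avg2), 4)  # 2 individuals x 2 patches
  for (k in seq_len(4)) {
    sel <- meta2$individual == avg2$meta$individual[k] &
           meta2$patch == avg2$meta$patch[k]
    manual <- rowSums(refl[, sel, drop = FALSE]) / sum(sel)
    expect_equal(avg2$refl[, k], manual, ignore_attr = TRUE)
  }
})

test_that("smoothing preserves constants and ramps, attenuates spikes", {
  wl <- 300:700
  cst <- make_spectra(wl, a = rep(12, 401))
  expect_equal(smooth_spectra(cst, 0.2)$refl[, 1], rep(12, 401),
               tolerance = 1e-6, ignore_attr = TRUE)
  ramp <- make_spectra(wl, a = seq(0, 40, length.out = 401))
  expect_equal(smooth_spectra(ramp, 0.3)$refl[, 1],
               seq(0, 40, length.out = 401), tolerance = 1e-4,
               ignore_attr = TRUE)
  clean <- 20 + 5 * sin(wl / 40)
  noisy <- clean
  noisy[200] <- noisy[200] + 30
  sm <- smooth_spectra(make_spectra(wl, a = noisy), 0.2)$refl[, 1]
  expect_lt(max(abs(sm - clean)), max(abs(noisy - clean)))
  expect_error(smooth_spectra(cst, 0), "span")
  expect_error(smooth_spectra(cst, 1.5), "span")
})

test_that("grid interpolation passes through knots and refuses extrapolation", {
  wl <- seq(300, 700, by = 0.5)
  x <- make_spectra(wl, a = 2 * wl - 100)
  y <- interpolate_to_grid(x, step = 1)
  expect_equal(y$wl, seq(300, 700, by = 1))
  expect_equal(y$refl[, 1], 2 * y$wl - 100, ignore_attr = TRUE)
  shared <- match(y$wl, wl)
  expect_equal(y$refl[, 1], x$refl[shared, 1], ignore_attr = TRUE)
  narrow <- make_spectra(350:700, a = rep(1, 351))
  expect_error(interpolate_to_grid(narrow, 1, range = c(300, 700)),
               "extrapolation")
})

test_that("peak finding matches construction and exhaustive neighbor checks", {
  wl <- 300:700
  expect_equal(find_peaks(gauss_refl(wl, 590, 25), 1, wl = wl), 590)
  two <- gauss_refl(wl, 520, 15, amp = 30) +
         30 * exp(-(wl - 580)^2 / (2 * 15^2))
  expect_equal(find_peaks(two, 1, wl = wl), c(520, 580))
  expect_equal(find_peaks(rep(4, 401), 1, wl = wl), numeric(0))

  # prominence-0 peaks equal exhaustive strict local maxima on rough curves
  set.seed(3)
  for (i in 1:5) {
    y <- cumsum(rnorm(101))
    expect_equal(find_peaks(y, 0, wl = 300:400), sort(naive_maxima(300:400, y)))
  }
  # a shallow secondary bump is dropped once the prominence bar is raised
  shoulder <- gauss_refl(wl, 500, 40, amp = 20) +
              exp(-(wl - 650)^2 / (2 * 8^2))
  expect_true(650 %in% find_peaks(shoulder, 0.5, wl = wl))
  expect_false(650 %in% find_peaks(shoulder, 2, wl = wl))
})
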