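test_that("ENVI round-trip preserves data and wavelengths", {
  set.seed(1)
  cube <- Hypercube(array(runif(4 * 4 * 8), dim = c(4, 4, 8)),
                    seq(950, 1020, by = 10))
  hdr <- file.path(tempdir(), "rt.hdr")
  writeEnviCube(cube, hdr, dataType = 5L)
  back <- readEnviCube(hdr)
  expect_equal(cubeData(back), cubeData(cube))
  expect_equal(wavelengths(back), wavelengths(cube))
})

test_that("a 512-band fixture cube reads back with the full grid", {
  grid <- defaultWavelengthGrid()
  cube <- Hypercube(array(0.5, dim = c(3, 2, 512)), grid)
  hdr <- file.path(tempdir(), "grid.hdr")
  writeEnviCube(cube, hdr, dataType = 4L)
  back <- readEnviCube(hdr)
  expect_length(wavelengths(back), 512L)
  expect_equal(wavelengths(back), grid, tolerance = 1e-9)
  expect_equal(sum(wavelengths(back) >= 950 & wavelengths(back) <= 1650), 421L)
})

test_that("header/data inconsistencies are format errors", {
  cube <- Hypercube(array(1, dim = c(2, 2, 8)), 1:8)
  hdr <- file.path(tempdir(), "bad.hdr")
  paths <- writeEnviCube(cube, hdr, dataType = 5L)
  # truncate the data file to 7 bands' worth
  sz <- file.size(paths["data"])
  con <- file(paths["data"], "r+b"); truncate <- sz * 7 / 8
  seek(con, 0); v <- readBin(con, "raw", n = truncate); close(con)
  writeBin(v, paths["data"])
  expect_error(readEnviCube(hdr), "format error")
  expect_error(readEnviCube(file.path(tempdir(), "absent.hdr")), "not found")
  file.remove(paths["data"])
  expect_error(readEnviCube(hdr), "data file not found")
})

test_that("reflectance correction matches the defining ratio", {
  set.seed(42)
  d <- c(3, 3, 5)
  wl <- seq_len(d[3]) * 100 + 800
  dark <- array(runif(prod(d), 50, 100), d)
  white <- array(runif(prod(d), 3000, 4000), d)
  raw <- array(runif(prod(d), 100, 3000), d)
  pair <- CalibrationPair(Hypercube(white, wl), Hypercube(dark, wl))

  # numerator == denominator and zero-numerator limits
  expect_equal(cubeData(reflectanceCorrect(Hypercube(white, wl), pair)),
               array(1, d))
  expect_equal(cubeData(reflectanceCorrect(Hypercube(dark, wl), pair)),
               array(0, d))

  # brute-force elementwise oracle
  out <- reflectanceCorrect(Hypercube(raw, wl), pair)
  expected <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (b in 1:d[3])
    expected[i, j, b] <- (raw[i, j, b] - dark[i, j, b]) /
      (white[i, j, b] - dark[i, j, b])
  expect_equal(cubeData(out), expected, tolerance = 1e-14)

  # invariance under common positive rescaling of both differences
  a <- 3.7
  raw2 <- dark + a * (raw - dark)
  white2 <- dark + a * (white - dark)
  pair2 <- CalibrationPair(Hypercube(white2, wl), Hypercube(dark, wl))
  expect_equal(cubeData(reflectanceCorrect(Hypercube(raw2, wl), pair2)),
               cubeData(out), tolerance = 1e-12)
})

test_that("dead pixels are filled and flagged; degenerate references error", {
  d <- c(2, 2, 3); wl <- c(1000, 1100, 1200)
  dark <- array(100, d); white <- array(4000, d)
  white[1, 1, 2] <- 100                       # one dead element
  raw <- array(2000, d)
  pair <- CalibrationPair(Hypercube(white, wl), Hypercube(dark, wl))
  out <- reflectanceCorrect(Hypercube(raw, wl), pair, fill = 0)
  expect_equal(cubeData(out)[1, 1, 2], 0)
  expect_equal(metadata(out)$n_invalid, 1L)
  expect_error(
    reflectanceCorrect(Hypercube(array(1, c(3, 2, 3)), wl), pair),
    "contract error")
  allbad <- CalibrationPair(Hypercube(dark, wl), Hypercube(dark, wl))
  expect_error(reflectanceCorrect(Hypercube(raw, wl), allbad),
               "calibration error")
})

test_that("elliptical ROI mask matches exhaustive enumeration", {
  roi <- ROISpec(63.5, 63.5, 45, 30, "row")
  mask <- ellipticalRoiMask(c(128, 128), roi)
  oracle <- matrix(FALSE, 128, 128)
  for (r in 0:127) for (cc in 0:127)
    oracle[r + 1, cc + 1] <-
      ((r - 63.5) / 45)^2 + ((cc - 63.5) / 30)^2 <= 1
  expect_identical(mask, oracle)
  expect_true(abs(sum(mask) - pi * 45 * 30) / (pi * 45 * 30) < 0.01)

  # symmetry through the center
  expect_identical(mask, mask[128:1, ])
  expect_identical(mask, mask[, 128:1])

  # sub-pixel ellipse keeps only the center pixel
  tiny <- ellipticalRoiMask(c(11, 11), ROISpec(5, 5, 0.5, 0.5))
  expect_equal(sum(tiny), 1L)
  expect_true(tiny[6, 6])

  expect_error(ellipticalRoiMask(c(50, 128), roi), "contract error")
})

test_that("mean ROI spectrum is the per-band arithmetic mean", {
  wl <- c(1000, 1100, 1200)
  cube <- Hypercube(array(0.7, c(4, 4, 3)), wl)
  m <- matrix(TRUE, 4, 4)
  expect_equal(unname(meanRoiSpectrum(cube, m)), rep(0.7, 3))

  # hand-computed 2x2 case
  a <- array(0, c(2, 2, 3))
  a[1, 1, ] <- c(1, 2, 3); a[2, 1, ] <- c(4, 5, 6)
  a[1, 2, ] <- c(7, 8, 9); a[2, 2, ] <- c(10, 11, 12)
  cube2 <- Hypercube(a, wl)
  expect_equal(unname(meanRoiSpectrum(cube2, matrix(TRUE, 2, 2))),
               c(5.5, 6.5, 7.5))
  single <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(unname(meanRoiSpectrum(cube2, single)), c(4, 5, 6))
  expect_error(meanRoiSpectrum(cube2, matrix(FALSE, 2, 2)), "contract error")
})

test_that("correction and ROI averaging commute for shared reference frames", {
  set.seed(3)
  d <- c(6, 6, 4); wl <- c(1000, 1100, 1200, 1300)
  darkB <- runif(d[3], 50, 100); whiteB <- runif(d[3], 3000, 4000)
  dark <- array(rep(darkB, each = 36), d)
  white <- array(rep(whiteB, each = 36), d)
  raw <- array(runif(prod(d), 200, 2500), d)
  pair <- CalibrationPair(Hypercube(white, wl), Hypercube(dark, wl))
  mask <- ellipticalRoiMask(c(6, 6), ROISpec(2.5, 2.5, 2, 2))
  viaCube <- meanRoiSpectrum(reflectanceCorrect(Hypercube(raw, wl), pair), mask)
  rawMean <- meanRoiSpectrum(Hypercube(raw, wl), mask)
  viaMean <- (rawMean - darkB) / (whiteB - darkB)
  expect_equal(unname(viaCube), unname(viaMean), tolerance = 1e-12)
})

test_that("band truncation keeps inclusive endpoints and is idempotent", {
  wl <- c(940, 950, 1000, 1650, 1651)
  tab <- SpectrumTable(matrix(runif(10), 2), wl)
  tr <- truncateBands(tab, 950, 1650)
  expect_equal(wavelengths(tr), c(950, 1000, 1650))
  expect_equal(ncol(tr), 2L)
  expect_equal(spectra(truncateBands(tab, 900, 1700)), spectra(tab))
  expect_equal(spectra(truncateBands(tr, 950, 1650)), spectra(tr))
  expect_error(truncateBands(tab, 1700, 1800), "contract error")
  expect_error(truncateBands(tab, 1650, 950), "contract error")

  full <- SpectrumTable(matrix(runif(2 * 512), 2), defaultWavelengthGrid())
  expect_equal(nrow(truncateBands(full, 950, 1650)), 421L)

  cube <- Hypercube(array(runif(4 * 20), c(2, 2, 5)), wl)
  expect_equal(wavelengths(truncateBands(cube, 950, 1650)),
               c(950, 1000, 1650))
})

test_that("SpectrumTable clips reflectance and round-trips through CSV", {
  wl <- c(1000, 1100, 1200)
  sp <- matrix(c(-0.2, 0.5, 1.5, 0.1, 1.1, 0.9), 2, byrow = TRUE)
  tab <- SpectrumTable(sp, wl, targets = data.frame(FI = c(10, 8), SSC = c(12, 13)),
                       stage = c("P1", "P2"))
  expect_equal(min(spectra(tab)), 0)            # floored at 0
  expect_equal(max(spectra(tab)), 1.2)          # ceiling 1.2
  expect_equal(qualityData(tab)$FSR, c(10 / 12, 8 / 13))
  f <- file.path(tempdir(), "tab.csv")
  writeSpectrumTable(tab, f)
  back <- readSpectrumTable(f)
  expect_equal(spectra(back), spectra(tab), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(stages(back), c("P1", "P2"))
  expect_equal(qualityData(back)$FI, c(10, 8))
  expect_error(SpectrumTable(sp, wl, stage = c("P1", "P9")), "P1..P5")
  expect_error(SpectrumTable(matrix(c(1, NaN, 1, 1, 1, 1), 2), wl), "NA")
})
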