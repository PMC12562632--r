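#' Stage-wise quality distribution parameters
#'
#' Per-stage mean, standard deviation and range of FI (N), SSC (%) and FSR
#' across the five maturity stages P1-P5 of the emulated study design
#' (600 fruit, 120 per stage, 950-1650 nm). FI falls monotonically with
#' ripening while SSC follows an accumulation-consumption arc peaking at
#' P3; FSR rows are derived quantities kept for reference and for
#' percent-change bookkeeping.
#'
#' @return data.frame with columns index, stage, min, max, mean, sd
#' @export
stageParams <- function() {
  data.frame(
    index = rep(c("FI", "SSC", "FSR"), each = 5L),
    stage = rep(paste0("P", 1:5), 3L),
    min  = c(10.97, 9.58, 7.99, 6.90, 6.75,
             7.13, 10.23, 12.00, 10.80, 10.37,
             0.99, 0.70, 0.49, 0.48, 0.50),
    max  = c(16.63, 14.09, 12.13, 10.42, 9.55,
             12.10, 14.53, 17.00, 15.10, 14.50,
             2.22, 1.23, 0.90, 0.84, 0.87),
    mean = c(13.98, 11.42, 10.09, 8.43, 8.03,
             9.13, 12.87, 14.55, 13.22, 12.51,
             1.55, 0.89, 0.70, 0.64, 0.65),
    sd   = c(1.24, 0.99, 0.88, 0.76, 0.75,
             0.84, 0.82, 0.93, 1.02, 0.99,
             0.22, 0.10, 0.09, 0.08, 0.08),
    stringsAsFactors = FALSE)
}

#' The fixed 512-point instrument wavelength grid
#'
#' 512 band centers spanning 900-1700 nm, constructed so that exactly 421
#' points fall in the 950-1650 nm effective analysis window: 46 points in
#' [900, 950), 421 uniformly spaced points (step 5/3 nm) in [950, 1650],
#' and 45 points in (1650, 1700]. The flanking segments are denser than the
#' analysis window; they model the noise-dominated spectral margins that
#' are discarded by \code{\link{truncateBands}}.
#'
#' @return strictly increasing numeric vector of length 512 (nm)
#' @export
defaultWavelengthGrid <- function() {
  c(900 + (0:45) * (50 / 46),
    seq(950, 1650, length.out = 421),
    1650 + (1:45) * (50 / 45))
}

#' Synthetic spectrum generator configuration
#'
#' Controls the reflectance model: a smooth scattering baseline whose offset
#' and tilt grow with firmness, Gaussian absorption dips at 970/1080/1270 nm
#' (fixed), at 1200 nm (C-H sugar overtone; depth proportional to SSC) and
#' at 1450 nm (O-H water band; depth tied to a stage-linked moisture proxy
#' with per-fruit jitter), plus smooth per-sample nuisance (offset/tilt)
#' and per-band Gaussian noise. The nuisance and jitter amplitudes scale
#' with \code{noiseSd}, so \code{noiseSd = 0} makes the generator fully
#' deterministic and raising it degrades every stochastic component
#' together.
#'
#' @param nPerStage samples per maturity stage (default 120)
#' @param grid wavelength grid (default \code{\link{defaultWavelengthGrid}})
#' @param noiseSd per-band additive noise SD in reflectance units
#'   (default 0.004)
#' @param offsetNuisanceRatio,tiltNuisanceRatio,moistureJitterRatio
#'   amplitudes of the per-sample nuisance terms as multiples of
#'   \code{noiseSd}
#' @param fiOffsetCoef,fiTiltCoef baseline coupling to FI (per N)
#' @param sscDipCoef 1200 nm dip depth per SSC percent
#' @param fiSscCor within-stage FI-SSC correlation (Gaussian copula)
#' @param clip reflectance clipping interval
#' @param seed default generator seed
#' @return a \code{GeneratorConfig} list
#' @export
generatorConfig <- function(nPerStage = 120L, grid = defaultWavelengthGrid(),
                            noiseSd = 0.004,
                            offsetNuisanceRatio = 2.5,
                            tiltNuisanceRatio = 2.0,
                            moistureJitterRatio = 3.0,
                            fiOffsetCoef = 0.015, fiTiltCoef = 0.006,
                            sscDipCoef = 0.010, fiSscCor = -0.3,
                            clip = c(0.01, 1.0), seed = 2L) {
  if (any(diff(grid) <= 0)) stop("contract error: grid must be strictly increasing")
  if (noiseSd < 0) stop("contract error: noiseSd must be >= 0")
  structure(list(nPerStage = as.integer(nPerStage), grid = grid,
                 noiseSd = noiseSd,
                 offsetNuisanceRatio = offsetNuisanceRatio,
                 tiltNuisanceRatio = tiltNuisanceRatio,
                 moistureJitterRatio = moistureJitterRatio,
                 fiOffsetCoef = fiOffsetCoef, fiTiltCoef = fiTiltCoef,
                 sscDipCoef = sscDipCoef, fiSscCor = fiSscCor,
                 clip = clip, seed = as.integer(seed),
                 bands = data.frame(
                   center = c(970, 1080, 1200, 1270, 1450),
                   width = c(30, 25, 45, 30, 60),
                   depth = c(0.060, 0.020, NA, 0.030, NA))),
            class = "GeneratorConfig")
}

## exact inverse-CDF sampler for a truncated normal (no rejection loops)
.qtruncnorm <- function(p, mean, sd, lo, hi) {
  a <- pnorm((lo - mean) / sd)
  b <- pnorm((hi - mean) / sd)
  if (b <= a) stop("contract error: infeasible truncation bounds")
  mean + sd * qnorm(a + p * (b - a))
}

.stageNumber <- function(stage) {
  s <- match(stage, MATURITY_STAGES)
  if (any(is.na(s))) stop("contract error: stage must be one of P1..P5")
  s
}

.stageRow <- function(params, index, stage) {
  r <- params[params$index == index & params$stage == stage, ]
  if (nrow(r) != 1L) stop("contract error: no parameters for ", index, "/", stage)
  r
}

## draws using the current RNG stream
.sampleQualityCore <- function(stage, n, params, cor) {
  fi <- .stageRow(params, "FI", stage)
  ss <- .stageRow(params, "SSC", stage)
  z1 <- rnorm(n)
  z2 <- cor * z1 + sqrt(1 - cor^2) * rnorm(n)
  FI <- .qtruncnorm(pnorm(z1), fi$mean, fi$sd, fi$min, fi$max)
  SSC <- .qtruncnorm(pnorm(z2), ss$mean, ss$sd, ss$min, ss$max)
  data.frame(FI = FI, SSC = SSC, FSR = fsr(FI, SSC), stage = stage,
             stringsAsFactors = FALSE)
}

#' Sample per-fruit quality records for one maturity stage
#'
#' FI and SSC are drawn from stage-specific truncated normal distributions
#' (inverse-CDF sampling, exact) coupled through a Gaussian copula with the
#' configured within-stage correlation; FSR is computed as FI/SSC for each
#' record.
#'
#' @param stage one of "P1".."P5"
#' @param n number of records (>= 1)
#' @param params distribution table from \code{\link{stageParams}}
#' @param seed integer seed (NULL: continue the current RNG stream)
#' @param cor within-stage FI-SSC correlation (default -0.3)
#' @return data.frame with columns FI, SSC, FSR, stage
#' @export
sampleQuality <- function(stage, n, params = stageParams(), seed = NULL,
                          cor = -0.3) {
  if (n < 1L) stop("contract error: n must be >= 1")
  .stageNumber(stage)
  if (!is.null(seed)) {
    oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
    set.seed(seed)
  }
  .sampleQualityCore(stage, n, params, cor)
}

.gauss <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

## deterministic part + stream-driven stochastic part of one spectrum
.spectrumCore <- function(FI, SSC, stageNum, cfg, stochastic = TRUE) {
  wl <- cfg$grid
  u <- (wl - 900) / 800
  offset <- 0.30 + cfg$fiOffsetCoef * FI
  tilt <- 0.10 + cfg$fiTiltCoef * FI
  refl <- offset + tilt * (0.5 - u)
  b <- cfg$bands
  refl <- refl -
    b$depth[1] * .gauss(wl, b$center[1], b$width[1]) -
    b$depth[2] * .gauss(wl, b$center[2], b$width[2]) -
    b$depth[4] * .gauss(wl, b$center[4], b$width[4]) -
    (cfg$sscDipCoef * SSC) * .gauss(wl, b$center[3], b$width[3])
  moist <- (6 - stageNum) / 5
  if (stochastic && cfg$noiseSd > 0) {
    moist <- moist + rnorm(1, 0, cfg$moistureJitterRatio * cfg$noiseSd)
    refl <- refl + rnorm(1, 0, cfg$offsetNuisanceRatio * cfg$noiseSd) +
      rnorm(1, 0, cfg$tiltNuisanceRatio * cfg$noiseSd) * (u - 0.5) +
      rnorm(length(wl), 0, cfg$noiseSd)
  }
  refl <- refl - (0.15 + 0.10 * moist) * .gauss(wl, b$center[5], b$width[5])
  pmin(pmax(refl, cfg$clip[1]), cfg$clip[2])
}

#' Generate one reflectance spectrum from a quality record
#'
#' Maps (FI, SSC, stage) to a reflectance spectrum on the fixed instrument
#' grid: scattering baseline coupled to firmness, sugar-coupled 1200 nm
#' dip, stage-linked 1450 nm water dip, fixed minor dips, nuisance and
#' noise (see \code{\link{generatorConfig}}). With \code{noiseSd = 0} the
#' mapping is deterministic.
#'
#' @param record one-row data.frame (or list) with FI, SSC, stage
#' @param cfg a \code{\link{generatorConfig}}
#' @param seed integer seed (NULL: continue the current RNG stream)
#' @param truncate return only the 421 analysis bands in 950-1650 nm
#'   (default TRUE); FALSE returns all 512 raw bands
#' @return named numeric reflectance vector
#' @export
spectrumFromQuality <- function(record, cfg = generatorConfig(), seed = NULL,
                                truncate = TRUE) {
  if (!is.null(seed)) {
    oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
    set.seed(seed)
  }
  s <- .stageNumber(record$stage)
  refl <- .spectrumCore(record$FI, record$SSC, s, cfg)
  names(refl) <- sprintf("%.10g", cfg$grid)
  if (truncate) {
    keep <- cfg$grid >= 950 & cfg$grid <= 1650
    refl <- refl[keep]
  }
  refl
}

#' Generate a full synthetic study dataset
#'
#' Emulates the study design: \code{5 * nPerStage} fruit across maturity
#' stages P1-P5 with Table-parameterized quality distributions and one
#' spectrum per fruit, truncated to the 421-band analysis window.
#' Reproducible per seed.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @param params distribution table from \code{\link{stageParams}}
#' @param seed integer seed (default \code{cfg$seed})
#' @return a \linkS4class{SpectrumTable} with FI/SSC/FSR targets and stages
#' @export
generateDataset <- function(cfg = generatorConfig(), params = stageParams(),
                            seed = cfg$seed) {
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  keep <- cfg$grid >= 950 & cfg$grid <= 1650
  recs <- do.call(rbind, lapply(MATURITY_STAGES, function(st)
    .sampleQualityCore(st, cfg$nPerStage, params, cfg$fiSscCor)))
  sp <- matrix(0, nrow(recs), sum(keep))
  for (i in seq_len(nrow(recs)))
    sp[i, ] <- .spectrumCore(recs$FI[i], recs$SSC[i],
                             .stageNumber(recs$stage[i]), cfg)[keep]
  ids <- sprintf("%s_%03d", recs$stage,
                 sequence(rep(cfg$nPerStage, length(MATURITY_STAGES))))
  SpectrumTable(sp, cfg$grid[keep], sampleIds = ids,
                targets = recs[c("FI", "SSC", "FSR")], stage = recs$stage)
}

#' Generate a synthetic hypercube with references and ground truth
#'
#' Builds a raw (digital-number) cube containing an elliptical "fruit"
#' whose per-pixel spectra follow \code{\link{spectrumFromQuality}} with
#' smoothly varying per-pixel FI/SSC fields, over a flat background with no
#' sugar dip. White/dark reference cubes are constructed so that
#' \code{\link{reflectanceCorrect}} recovers the intended reflectance
#' exactly; the intended per-pixel FI/SSC/FSR maps are returned for
#' visualization tests.
#'
#' @param stage maturity stage of the fruit ("P1".."P5")
#' @param size \code{c(rows, cols)}, at least \code{c(100, 70)} so the cube
#'   can host a 90 x 60 analysis region
#' @param cfg a \code{\link{generatorConfig}}
#' @param seed integer seed
#' @return list with elements \code{raw} (\linkS4class{Hypercube}),
#'   \code{cal} (\linkS4class{CalibrationPair}), \code{reflectance}
#'   (intended calibrated cube), and \code{truth} (list of FI/SSC/FSR
#'   matrices, NA outside the fruit, plus the fruit \code{mask})
#' @export
generateCube <- function(stage, size = c(128L, 96L), cfg = generatorConfig(),
                         seed = cfg$seed) {
  if (size[1] < 100L || size[2] < 70L)
    stop("contract error: region too small; need at least 100 x 70 pixels")
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  rows <- size[1]; cols <- size[2]
  wl <- cfg$grid; B <- length(wl)
  sN <- .stageNumber(stage)
  base <- .sampleQualityCore(stage, 1L, stageParams(), cfg$fiSscCor)

  roi <- ROISpec((rows - 1) / 2, (cols - 1) / 2,
                 0.48 * (rows - 1), 0.45 * (cols - 1), "row")
  mask <- ellipticalRoiMask(c(rows, cols), roi)

  # smooth quality fields over the fruit
  r <- matrix((seq_len(rows) - 1) / (rows - 1), rows, cols)
  cc <- matrix(rep((seq_len(cols) - 1) / (cols - 1), each = rows), rows, cols)
  FI <- base$FI + 0.8 * sin(pi * r) * cos(2 * pi * cc) + 0.4 * (cc - 0.5)
  SSC <- base$SSC + 0.6 * cos(pi * r) + 0.3 * sin(2 * pi * cc)
  FI <- pmax(FI, 0.5); SSC <- pmax(SSC, 1)
  FI[!mask] <- NA; SSC[!mask] <- NA

  u <- (wl - 900) / 800
  bnd <- cfg$bands
  fixedDips <- bnd$depth[1] * .gauss(wl, bnd$center[1], bnd$width[1]) +
    bnd$depth[2] * .gauss(wl, bnd$center[2], bnd$width[2]) +
    bnd$depth[4] * .gauss(wl, bnd$center[4], bnd$width[4])
  dip1200 <- .gauss(wl, bnd$center[3], bnd$width[3])
  dip1450 <- .gauss(wl, bnd$center[5], bnd$width[5])

  npix <- rows * cols
  fiV <- as.vector(FI); sscV <- as.vector(SSC); inV <- as.vector(mask)
  refl <- matrix(0.25, npix, B)                           # flat background
  off <- 0.30 + cfg$fiOffsetCoef * fiV[inV]
  tlt <- 0.10 + cfg$fiTiltCoef * fiV[inV]
  moist <- (6 - sN) / 5 +
    if (cfg$noiseSd > 0) rnorm(sum(inV), 0, cfg$moistureJitterRatio * cfg$noiseSd) else 0
  fruit <- outer(off, rep(1, B)) + outer(tlt, 0.5 - u) -
    matrix(fixedDips, sum(inV), B, byrow = TRUE) -
    outer(cfg$sscDipCoef * sscV[inV], dip1200) -
    outer(0.15 + 0.10 * moist, dip1450)
  if (cfg$noiseSd > 0) {
    fruit <- fruit +
      outer(rnorm(sum(inV), 0, cfg$offsetNuisanceRatio * cfg$noiseSd), rep(1, B)) +
      outer(rnorm(sum(inV), 0, cfg$tiltNuisanceRatio * cfg$noiseSd), u - 0.5) +
      matrix(rnorm(sum(inV) * B, 0, cfg$noiseSd), sum(inV), B)
  }
  refl[inV, ] <- fruit
  refl <- pmin(pmax(refl, cfg$clip[1]), cfg$clip[2])

  reflCube <- Hypercube(array(refl, dim = c(rows, cols, B)), wl,
                        metadata = list(stage = stage))
  dark <- Hypercube(array(100, dim = c(rows, cols, B)), wl)
  white <- Hypercube(array(4000, dim = c(rows, cols, B)), wl)
  raw <- Hypercube(dark@data + reflCube@data * (white@data - dark@data), wl,
                   metadata = list(stage = stage))
  list(raw = raw, cal = CalibrationPair(white, dark),
       reflectance = reflCube,
       truth = list(FI = FI, SSC = SSC, FSR = FI / SSC, mask = mask))
}
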