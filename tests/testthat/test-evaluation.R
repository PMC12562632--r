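test_that("FSR is the firmness over soluble-solids ratio", {
  expect_equal(fsr(9.5, 9.5), 1)
  expect_equal(fsr(13.98, 9.13), 1.5312158, tolerance = 1e-7)
  expect_equal(fsr(8.03, 12.51), 0.6418865, tolerance = 1e-7)
  expect_equal(fsr(c(10, 12), c(10, 12)), c(1, 1))
  expect_error(fsr(10, 0), "contract error")
})

test_that("regression metrics follow their defining formulas", {
  y <- c(1, 2, 3, 4, 5)
  perfect <- regressionReport(y, y)
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_true(is.infinite(perfect$RPD) && perfect$overflow)

  meanPred <- regressionReport(y, rep(mean(y), 5))
  expect_equal(meanPred$R2, 0)
  expect_equal(meanPred$RPD, 1)

  # hand example: SSres = 0.11, SStot = 10
  p <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  r <- regressionReport(y, p)
  expect_equal(r$RMSE, sqrt(0.11 / 5))
  expect_equal(r$R2, 1 - 0.11 / 10)
  expect_equal(r$RPD, sqrt(2) / sqrt(0.11 / 5))
  expect_equal(r$RPD, 1 / sqrt(1 - r$R2), tolerance = 1e-9)

  # sample-SD convention differs by the n/(n-1) factor
  rs <- regressionReport(y, p, rpdConvention = "sample")
  expect_equal(rs$RPD, r$RPD * sqrt(5 / 4))

  expect_error(regressionReport(y, p[1:4]), "contract error")
  expect_error(regressionReport(rep(1, 5), p), "zero reference variance")
})

test_that("percent change reproduces the stage-to-stage worked values", {
  expect_equal(percentChange(9.13, 14.55), 59.4)
  expect_equal(percentChange(0.89, 0.64), -28.1)
  expect_equal(percentChange(13.98, 8.03), -42.6)
  expect_equal(percentChange(3, 3), 0)
  expect_error(percentChange(0, 1), "contract error")
})

test_that("stage summaries use sample SD and handle singletons", {
  rec <- data.frame(FI = c(10, 12, 14), SSC = c(10, 11, 12),
                    FSR = c(1, 12 / 11, 14 / 12),
                    stage = c("P1", "P1", "P2"))
  s <- stageSummary(rec)
  p1fi <- s[s$stage == "P1" & s$index == "FI", ]
  expect_equal(p1fi$mean, 11)
  expect_equal(p1fi$sd, sd(c(10, 12)))
  expect_equal(p1fi$min, 10); expect_equal(p1fi$max, 12)
  expect_true(is.na(s[s$stage == "P2" & s$index == "FI", "sd"]))
  expect_equal(unique(s$stage), c("P1", "P2"))
  expect_error(stageSummary(data.frame(FI = 1, SSC = 1, FSR = 1, stage = NA)),
               "contract error")
})

test_that("synthetic stage statistics track the configured distributions", {
  tab <- generateDataset(seed = 2)
  s <- stageSummary(tab)
  pars <- stageParams()
  for (idx in c("FI", "SSC")) for (st in paste0("P", 1:5)) {
    row <- s[s$stage == st & s$index == idx, ]
    par <- pars[pars$stage == st & pars$index == idx, ]
    # sampling bound around the truncated-normal mean implied by the generator
    a <- (par$min - par$mean) / par$sd; b <- (par$max - par$mean) / par$sd
    z <- pnorm(b) - pnorm(a)
    truncMean <- par$mean - par$sd * (dnorm(b) - dnorm(a)) / z
    se <- par$sd / sqrt(120)
    expect_lt(abs(row$mean - truncMean), 3 * se)
    expect_lt(abs(row$mean - par$mean), 4 * se)
    expect_gte(row$min, par$min)
    expect_lte(row$max, par$max)
  }
})

test_that("fold schemes are disjoint, covering and stratified", {
  set.seed(50)
  labels <- rep(paste0("P", 1:5), times = c(11, 12, 13, 11, 12))
  sch <- foldScheme(labels, k = 5, seed = 7)
  all <- sort(unlist(sch$folds))
  expect_equal(all, seq_along(labels))
  for (st in unique(labels)) {
    sizes <- vapply(sch$folds, function(f) sum(labels[f] == st), integer(1))
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_error(foldScheme(labels, k = 100), "contract error")
})

test_that("classification metrics match counting arguments", {
  # degenerate classifier on a balanced 5-class set
  truth <- rep(paste0("P", 1:5), each = 24)
  rep0 <- classificationReport(truth, rep("P1", 120))
  expect_equal(rep0$accuracy, 20)

  # one error among 120: the adjacent-pair misclassification rate is 0.8%
  pred <- truth; pred[1] <- "P2"
  rep1 <- classificationReport(truth, pred)
  expect_equal(unname(rep1$confusion["P1", "P2"]), 1L)
  expect_equal(pearHSI:::roundHalfAway(100 * 1 / 120, 1), 0.8)

  # balanced symmetric confusion: macro precision == recall == accuracy
  truth2 <- rep(c("A", "B"), each = 10)
  pred2 <- truth2; pred2[c(1, 11)] <- c("B", "A")
  rep2 <- classificationReport(truth2, pred2, levels = c("A", "B"))
  expect_equal(rep2$precision, rep2$accuracy)
  expect_equal(rep2$recall, rep2$accuracy)
  expect_equal(rep2$accuracy, 90)
})

test_that("cross-validation is leakage-free for selection-heavy pipelines", {
  # pure-noise labels: a leaking pipeline would report inflated accuracy
  set.seed(51)
  n <- 100
  X <- matrix(rnorm(n * 40), n)
  g <- factor(rep(paste0("P", 1:5), each = n / 5))
  sch <- foldScheme(as.character(g), k = 5, seed = 3)
  rep <- crossvalClassify(baselineSpec("lda_rfe", nFeatures = 4), X, g, sch)
  expect_lt(rep$accuracy, 40)      # chance is 20%; no selection leakage bonus
  expect_error(
    crossvalClassify(baselineSpec("plsda"), X, factor(c(rep("A", 99), "B")),
                     foldScheme(c(rep("A", 99), "B"), k = 5, seed = 1)),
    "stratification error")
})

test_that("published benchmark metrics satisfy the RPD identities", {
  bm <- benchmarkMetrics()
  expect_equal(nrow(bm), 18L)
  expect_true(all(abs(1 / sqrt(1 - bm$Rp2) - bm$RPD) <= 0.01))
  for (idx in unique(bm$index)) {
    sdImplied <- bm$RPD[bm$index == idx] * bm$RMSEP[bm$index == idx]
    expect_true(all(abs(sdImplied - median(sdImplied)) <= 0.003))
  }
})
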