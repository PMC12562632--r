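# minimal NIPALS PLS1 (centered, regression mode) used as the independent
# oracle for the PLSR predictions
nipalsPls1 <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- matrix(0, ncol(X), ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p); f <- f - qa * t
    W[, a] <- w; P[, a] <- p; q[a] <- qa
  }
  B <- W %*% solve(t(P) %*% W) %*% q
  function(Xnew) as.numeric(sweep(Xnew, 2, xm) %*% B) + ym
}

test_that("PLSR recovers exact linear structure and matches NIPALS", {
  set.seed(41)
  # zero-mean orthogonal bands with distinct scales: a target carried by two
  # bands then lies exactly in the 2-dimensional PLS latent space
  Xc <- scale(matrix(rnorm(30 * 8), 30), center = TRUE, scale = FALSE)
  X <- qr.Q(qr(Xc)) %*% diag(1:8)
  y <- 3 * X[, 2] - 2 * X[, 5]
  fit <- fitPlsr(X, y, nLatent = 2)
  expect_equal(1 - sum((predict(fit, X) - y)^2) / sum((y - mean(y))^2), 1,
               tolerance = 1e-8)

  # nested models: a single latent variable explains strictly less
  r2 <- function(m) 1 - sum((predict(m, X) - y)^2) / sum((y - mean(y))^2)
  expect_lt(r2(fitPlsr(X, y, nLatent = 1)), r2(fitPlsr(X, y, nLatent = 2)))

  # small-matrix oracle
  X6 <- matrix(rnorm(6 * 4), 6); y6 <- rnorm(6)
  fit6 <- fitPlsr(X6, y6, nLatent = 2)
  oracle <- nipalsPls1(X6, y6, 2)
  expect_equal(predict(fit6, X6), oracle(X6), tolerance = 1e-8)

  # full-rank PLSR equals ordinary least squares
  set.seed(99)
  yn <- 2 * X[, 1] + rnorm(30)
  fitF <- fitPlsr(X, yn, nLatent = 8)
  expect_equal(predict(fitF, X),
               as.numeric(cbind(1, X) %*% lm.fit(cbind(1, X), yn)$coefficients),
               tolerance = 1e-6)

  # internal CV latent-variable selection is bounded and deterministic
  auto <- fitPlsr(X, yn, autoLv = TRUE, maxLatent = 6)
  expect_true(auto$hyper$nLatent >= 1 && auto$hyper$nLatent <= 6)
  expect_identical(auto$hyper$nLatent,
                   fitPlsr(X, yn, autoLv = TRUE, maxLatent = 6)$hyper$nLatent)
})

test_that("SVR behaves sanely with the stated hyperparameters", {
  set.seed(42)
  X <- matrix(rnorm(40 * 3), 40)
  const <- fitSvr(X, rep(5, 40))
  expect_true(all(abs(predict(const, X) - 5) < 0.1 + 1e-8))  # epsilon tube

  y <- sin(X[, 1]) + 0.5 * X[, 2]
  fit <- fitSvr(X, y, C = 90, gamma = 1)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), sd(y))

  # refit determinism
  fit2 <- fitSvr(X, y, C = 90, gamma = 1)
  expect_identical(predict(fit, X), predict(fit2, X))
  expect_error(fitSvr(X[1, , drop = FALSE], 1), "contract error")
})

test_that("PCR equals least squares on the principal subspace", {
  set.seed(43)
  n <- 40
  scores <- matrix(rnorm(n * 10), n)
  basis <- qr.Q(qr(matrix(rnorm(15 * 10), 15)))      # 10-dim signal subspace
  X <- scores %*% t(basis)
  y <- scores %*% rnorm(10)
  fit <- fitPcr(X, y, nComponents = 10)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-6 * sd(y))

  # full-component PCR equals OLS (n-1 >= B case)
  X2 <- matrix(rnorm(30 * 5), 30); y2 <- rnorm(30)
  fitF <- fitPcr(X2, y2, nComponents = 5)
  expect_equal(predict(fitF, X2),
               as.numeric(cbind(1, X2) %*% lm.fit(cbind(1, X2), y2)$coefficients),
               tolerance = 1e-8)

  # sign convention makes refits bitwise identical
  fa <- fitPcr(X2, y2, 3); fb <- fitPcr(X2, y2, 3)
  expect_identical(fa$fit$rotation, fb$fit$rotation)
  expect_identical(predict(fa, X2), predict(fb, X2))
  expect_error(fitPcr(X2, y2, 40), "contract error")
})

test_that("PLS-DA separates a linear toy and respects band rescaling", {
  set.seed(44)
  n <- 30
  X <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, 3), n))
  g <- rep(c("A", "B"), each = n)
  fit <- fitPlsda(X, g, nLatent = 2)
  expect_equal(mean(as.character(predict(fit, X)) == g), 1)

  # common rescaling of all bands leaves the standardized pipeline unchanged
  fitS <- fitPlsda(X, g, nLatent = 2, standardize = TRUE)
  fitS2 <- fitPlsda(X * 7, g, nLatent = 2, standardize = TRUE)
  expect_equal(as.character(predict(fitS2, X * 7)),
               as.character(predict(fitS, X)))
  expect_error(fitPlsda(X, rep("A", 2 * n)), "contract error")
})

test_that("SVM classifier separates and confuses only adjacent ordinal classes", {
  set.seed(45)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0), n), matrix(rnorm(n * 3, 4), n))
  g <- rep(c("A", "B"), each = n)
  fit <- fitSvmClassifier(X, g)
  expect_equal(mean(as.character(predict(fit, X)) == g), 1)
  expect_identical(predict(fitSvmClassifier(X, g), X), predict(fit, X))

  # ordinal toy: five classes along one axis with overlap
  mu <- seq(0, 8, by = 2)
  Xo <- do.call(rbind, lapply(mu, function(m) matrix(rnorm(60 * 2, m, 0.9), 60)))
  go <- factor(rep(paste0("P", 1:5), each = 60))
  fo <- fitSvmClassifier(Xo, go)
  pred <- predict(fo, Xo)
  wrong <- which(pred != go)
  expect_gt(length(wrong), 0)                    # overlap produces errors
  dist <- abs(as.integer(pred[wrong]) - as.integer(go[wrong]))
  expect_true(all(dist == 1))                    # all confusions adjacent
})

test_that("LDA-RFE recovers planted informative bands", {
  set.seed(46)
  n <- 60
  g <- rep(c("A", "B", "C"), each = n)
  X <- matrix(rnorm(3 * n * 10), 3 * n)
  shift <- rep(c(0, 2, 4), each = n)
  X[, 3] <- X[, 3] + shift
  X[, 8] <- X[, 8] - shift
  fit <- fitLdaRfe(X, g, nFeatures = 2)
  expect_setequal(fit$selected, c(3L, 8L))
  expect_gt(mean(as.character(predict(fit, X)) == g), 0.85)

  plain <- fitLdaRfe(X, g)                       # nFeatures = B: plain LDA
  expect_equal(plain$selected, 1:10)
  fit2 <- fitLdaRfe(X, g, nFeatures = 2)
  expect_identical(fit2$selected, fit$selected)
  expect_error(fitLdaRfe(X, g, nFeatures = 1), "contract error")
})
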