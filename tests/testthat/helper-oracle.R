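# Independent layer-by-layer recomputation of the network forward passes,
# written directly from the defining equations (naive loops / small matrix
# products in double precision). Used to validate the package's compiled
# engine; deliberately shares no code with it.

naiveConv1d <- function(x, W, b, stride, pad) {
  # x: Cin x L; W: Cout x Cin x k (or Cout x k when Cin == 1); b: Cout
  if (length(dim(W)) == 2L) dim(W) <- c(dim(W)[1], 1L, dim(W)[2])
  Cin <- nrow(x); L <- ncol(x)
  Cout <- dim(W)[1]; k <- dim(W)[3]
  xp <- cbind(matrix(0, Cin, pad), x, matrix(0, Cin, pad))
  Lout <- floor((L + 2 * pad - k) / stride) + 1
  y <- matrix(0, Cout, Lout)
  for (j in seq_len(Lout)) {
    acc <- b
    for (t in seq_len(k)) {
      col <- (j - 1) * stride + t
      acc <- acc + W[, , t, drop = FALSE][, , 1] %*% xp[, col, drop = FALSE]
    }
    y[, j] <- acc
  }
  y
}

naiveBN <- function(xlist, gamma, beta, runMean, runVar, train, eps = 1e-5) {
  # xlist: list over samples of C x L matrices (batch stats pool all of them)
  if (train) {
    all <- do.call(cbind, xlist)
    mu <- rowMeans(all)
    v <- rowMeans((all - mu)^2)
  } else {
    mu <- runMean; v <- runVar
  }
  lapply(xlist, function(x) (x - mu) / sqrt(v + eps) * gamma + beta)
}

naiveRelu <- function(x) pmax(x, 0)

naivePool <- function(x, k, stride, pad) {
  C <- nrow(x); L <- ncol(x)
  xp <- cbind(matrix(-Inf, C, pad), x, matrix(-Inf, C, pad))
  Lout <- floor((L + 2 * pad - k) / stride) + 1
  y <- matrix(0, C, Lout)
  for (j in seq_len(Lout))
    y[, j] <- apply(xp[, (j - 1) * stride + seq_len(k), drop = FALSE], 1, max)
  y
}

naiveLstmStep <- function(x, Wih, bih, bhh, H) {
  sig <- function(z) 1 / (1 + exp(-z))
  gates <- as.vector(Wih %*% x) + bih + bhh
  i <- sig(gates[seq_len(H)])
  g <- tanh(gates[2 * H + seq_len(H)])
  o <- sig(gates[3 * H + seq_len(H)])
  cc <- i * g                       # c0 = 0, forget gate contributes nothing
  o * tanh(cc)
}

# full forward recomputation for mscnn / mscnn_lstm from the parameter store
oracleMscnnForward <- function(graph, X, mode = "inference") {
  p <- graph@params; s <- graph@state; cfg <- graph@config
  train <- mode == "train"
  N <- nrow(X)
  branchOut <- vector("list", 3L)
  for (b in 1:3) {
    pre <- paste0("branch", b, ".")
    a <- lapply(seq_len(N), function(n)
      naiveConv1d(matrix(X[n, ], 1), p[[paste0(pre, "conv1.W")]],
                  p[[paste0(pre, "conv1.b")]], cfg$stride, cfg$paddings[b]))
    a <- naiveBN(a, p[[paste0(pre, "bn1.gamma")]], p[[paste0(pre, "bn1.beta")]],
                 s[[paste0(pre, "bn1.runMean")]], s[[paste0(pre, "bn1.runVar")]],
                 train)
    a <- lapply(a, naiveRelu)
    a <- lapply(a, function(m)
      naiveConv1d(m, p[[paste0(pre, "conv2.W")]], p[[paste0(pre, "conv2.b")]],
                  cfg$stride, cfg$paddings[b]))
    a <- naiveBN(a, p[[paste0(pre, "bn2.gamma")]], p[[paste0(pre, "bn2.beta")]],
                 s[[paste0(pre, "bn2.runMean")]], s[[paste0(pre, "bn2.runVar")]],
                 train)
    a <- lapply(a, naiveRelu)
    branchOut[[b]] <- lapply(a, naivePool, k = cfg$poolKernel,
                             stride = cfg$poolStride, pad = 0)
  }
  out <- numeric(N)
  for (n in seq_len(N)) {
    Ff <- branchOut[[1]][[n]] * p[["fusion.w1"]] +
      branchOut[[2]][[n]] * p[["fusion.w2"]] +
      branchOut[[3]][[n]] * p[["fusion.w3"]]
    h <- naiveRelu(as.vector(p[["fc1.W"]] %*% as.vector(Ff)) + p[["fc1.b"]])
    if (graph@architecture == "mscnn_lstm")
      h <- naiveLstmStep(h, p[["lstm.W_ih"]], p[["lstm.b_ih"]],
                         p[["lstm.b_hh"]], cfg$lstmHidden)
    out[n] <- sum(p[["head.W"]] * h) + p[["head.b"]]
  }
  out
}

oracleResnetForward <- function(graph, X, mode = "inference") {
  p <- graph@params; s <- graph@state
  train <- mode == "train"
  N <- nrow(X)
  a <- lapply(seq_len(N), function(n)
    naiveConv1d(matrix(X[n, ], 1), p[["stem.conv.W"]], p[["stem.conv.b"]], 2, 3))
  a <- naiveBN(a, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
               s[["stem.bn.runMean"]], s[["stem.bn.runVar"]], train)
  a <- lapply(a, naiveRelu)
  a <- lapply(a, naivePool, k = 3, stride = 2, pad = 1)
  for (g in 1:4)
    for (i in 1:2) {
      pre <- paste0("group", g, ".block", i, ".")
      stride <- if (i == 1 && g > 1) 2 else 1
      m <- lapply(a, function(x)
        naiveConv1d(x, p[[paste0(pre, "conv1.W")]],
                    p[[paste0(pre, "conv1.b")]], stride, 1))
      m <- naiveBN(m, p[[paste0(pre, "bn1.gamma")]], p[[paste0(pre, "bn1.beta")]],
                   s[[paste0(pre, "bn1.runMean")]], s[[paste0(pre, "bn1.runVar")]],
                   train)
      m <- lapply(m, naiveRelu)
      m <- lapply(m, function(x)
        naiveConv1d(x, p[[paste0(pre, "conv2.W")]],
                    p[[paste0(pre, "conv2.b")]], 1, 1))
      m <- naiveBN(m, p[[paste0(pre, "bn2.gamma")]], p[[paste0(pre, "bn2.beta")]],
                   s[[paste0(pre, "bn2.runMean")]], s[[paste0(pre, "bn2.runVar")]],
                   train)
      skip <- a
      if (i == 1 && g > 1) {
        skip <- lapply(a, function(x)
          naiveConv1d(x, p[[paste0(pre, "proj.W")]],
                      p[[paste0(pre, "proj.b")]], stride, 0))
        skip <- naiveBN(skip, p[[paste0(pre, "bnp.gamma")]],
                        p[[paste0(pre, "bnp.beta")]],
                        s[[paste0(pre, "bnp.runMean")]],
                        s[[paste0(pre, "bnp.runVar")]], train)
      }
      a <- mapply(function(mm, ss) naiveRelu(mm + ss), m, skip,
                  SIMPLIFY = FALSE)
    }
  vapply(a, function(x) sum(p[["head.W"]] * rowMeans(x)) + p[["head.b"]],
         numeric(1))
}

oracleForward <- function(graph, X, mode = "inference") {
  if (graph@architecture == "resnet18_1d") oracleResnetForward(graph, X, mode)
  else oracleMscnnForward(graph, X, mode)
}

# exhaustive re-derivation of Kennard-Stone max-min selection, straight from
# the definition (used as the oracle for spxySelect)
bruteMaxMin <- function(D, nCal) {
  n <- nrow(D)
  best <- c(1, 2); bestVal <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bestVal) { bestVal <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < nCal) {
    rest <- setdiff(seq_len(n), sel)
    score <- vapply(rest, function(r) min(D[r, sel]), numeric(1))
    sel <- c(sel, rest[which.max(score)])
  }
  as.integer(sel)
}

# small geometry used by the engine checks (all branches emit 8 -> 8 -> 2)
tinyMscnnConfig <- function(lstmHidden = 4L)
  mscnnConfig(inputLength = 16L, channels1 = c(2L, 3L, 4L), outChannels = 5L,
              fcHidden = 6L, lstmHidden = lstmHidden)

# a tiny table whose target is an exact linear function of 3 bands
linearToyTable <- function(n = 64L, bands = 16L, seed = 7L) {
  set.seed(seed)
  X <- matrix(rnorm(n * bands), n)
  y <- 2 * X[, 2] - 1.5 * X[, 7] + 0.5 * X[, 11]
  list(X = X, y = y)
}
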