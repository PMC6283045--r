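# Independent dense-matrix oracle: assemble the full N x N marginal
# covariance and N x p design from the per-trial blocks and evaluate the
# profiled (restricted) Gaussian log-likelihood directly.
dense_ll <- function(design, vc, estimation) {
  N <- design$N
  X <- matrix(0, N, design$p)
  y <- numeric(N)
  V <- matrix(0, N, N)
  off <- 0
  for (bl in design$blocks) {
    n <- bl$ss$n
    rows <- off + seq_len(n)
    X[rows, bl$idx] <- bl$Z
    y[rows] <- bl$y
    Vi <- diag(vc[["sigma2"]], n)
    if (length(bl$vc) > 0) {
      for (j in seq_along(bl$vc)) {
        Vi <- Vi + vc[[bl$vc[j]]] * tcrossprod(bl$U[, j])
      }
    }
    V[rows, rows] <- Vi
    off <- off + n
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ll <- -0.5 * (N * log(2 * pi) + determinant(V, TRUE)$modulus[1] +
                  drop(t(r) %*% Vi %*% r))
  if (estimation == "REML") {
    ll <- ll - 0.5 * determinant(XtVX, TRUE)$modulus[1]
  }
  list(criterion = drop(ll), beta = drop(beta), V = V, X = X, y = y,
       Phi = solve(XtVX))
}

# dense evaluation of the expected (REML-adjusted) information of the
# variance components: I[k,l] = tr(P dV_k P dV_l) / 2 with P either V^{-1}
# (ML) or the REML residual projection
dense_varcomp_info <- function(design, vc, estimation) {
  dl <- dense_ll(design, vc, estimation)
  Vi <- solve(dl$V)
  P <- if (estimation == "REML") {
    Vi - Vi %*% dl$X %*% solve(t(dl$X) %*% Vi %*% dl$X) %*% t(dl$X) %*% Vi
  } else {
    Vi
  }
  qn <- design$vc_names
  # dense dV/dpsi_k
  dV <- lapply(qn, function(cn) {
    D <- matrix(0, design$N, design$N)
    off <- 0
    for (bl in design$blocks) {
      n <- bl$ss$n
      rows <- off + seq_len(n)
      if (cn == "sigma2") {
        D[rows, rows] <- diag(n)
      } else {
        j <- match(cn, bl$vc)
        if (!is.na(j)) D[rows, rows] <- tcrossprod(bl$U[, j])
      }
      off <- off + n
    }
    D
  })
  q <- length(qn)
  info <- matrix(0, q, q, dimnames = list(qn, qn))
  for (k in seq_len(q)) for (l in seq_len(q)) {
    info[k, l] <- 0.5 * sum(diag(P %*% dV[[k]] %*% P %*% dV[[l]]))
  }
  info
}

# small deterministic two-arm dataset builders
make_noise_free <- function(K = 10, n = 100, beta = 159.73, theta = -9.66) {
  df <- do.call(rbind, lapply(seq_len(K), function(i) {
    tr <- rep(c(1L, 0L), each = n / 2)
    data.frame(trial = i, treat = tr, yf = beta + theta * tr)
  }))
  ipd_dataset(df)
}

make_small_ipd <- function(K = 4, n_max = 15, seed = 1, baseline = FALSE) {
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(K), function(i) {
    n <- sample(4:n_max, 1)
    tr <- sample(rep(c(1L, 0L), c(floor(n / 2), ceiling(n / 2))))
    out <- data.frame(trial = i, treat = tr,
                      yf = rnorm(n, 160 + 5 * i - 10 * tr, 15))
    if (baseline) out$yb <- rnorm(n, 150, 12)
    out
  }))
  ipd_dataset(df, baseline = if (baseline) "yb")
}
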