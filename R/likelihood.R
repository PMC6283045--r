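# Block marginal likelihood machinery.
#
# Per trial the marginal covariance is V_i = sigma2*I + sum_k psi_k u_k u_k',
# with u_k the random-effect directions (ones vector, treatment vector).
# Writing V_i = sigma2*I + (U B)(U B)' with B = diag(sqrt(psi)), Woodbury
# gives V_i^{-1} = a*I + U A U' with a = 1/sigma2 and
#   A = -(1/sigma2) * B (sigma2*I_r + B U'U B)^{-1} B,
# a representation closed under multiplication:
#   (a1 I + U A1 U')(a2 I + U A2 U') =
#       a1 a2 I + U (a1 A2 + a2 A1 + A1 U'U A2) U'.
# Every quantity the fitter and the small-sample corrections need (GLS
# normal equations, log-determinants, traces, quadratic forms in products of
# V^{-1} and dV/dpsi_k) therefore reduces to r x r algebra (r <= 2) against
# cross-products computed once per dataset, so each likelihood evaluation is
# O(K) after a single O(n) pass.

# ---- generic form algebra (used by the inference path and as the test
# ---- reference for the specialized gradient code below)

f_mult <- function(f1, f2, UtU) {
  a <- f1$a * f2$a
  if (is.null(f1$A) && is.null(f2$A)) return(list(a = a, A = NULL))
  r <- nrow(UtU)
  A1 <- if (is.null(f1$A)) matrix(0, r, r) else f1$A
  A2 <- if (is.null(f2$A)) matrix(0, r, r) else f2$A
  list(a = a, A = f1$a * A2 + f2$a * A1 + A1 %*% UtU %*% A2)
}

f_trace <- function(f, ss) {
  out <- f$a * ss$n
  if (!is.null(f$A)) out <- out + sum(f$A * ss$UtU)
  out
}

f_ZFZ <- function(f, ss) {
  out <- f$a * ss$ZtZ
  if (!is.null(f$A)) out <- out + crossprod(ss$UtZ, f$A %*% ss$UtZ)
  out
}

f_ZFy <- function(f, ss) {
  out <- f$a * ss$Zty
  if (!is.null(f$A)) out <- out + drop(crossprod(ss$UtZ, f$A %*% ss$Uty))
  out
}

f_yFy <- function(f, ss) {
  out <- f$a * ss$yty
  if (!is.null(f$A)) out <- out + drop(crossprod(ss$Uty, f$A %*% ss$Uty))
  out
}

# r'Fr for the residual r = y - Z beta_local, from block cross-products
f_rFr <- function(f, ss, beta_local) {
  f_yFy(f, ss) - 2 * sum(beta_local * f_ZFy(f, ss)) +
    drop(crossprod(beta_local, f_ZFZ(f, ss) %*% beta_local))
}

# V_i^{-1} form and log|V_i|, with closed-form r <= 2 inverses
block_vinv <- function(bl, vc) {
  sigma2 <- vc[["sigma2"]]
  ss <- bl$ss
  r <- length(bl$vc)
  if (r == 0L) {
    return(list(f = list(a = 1 / sigma2, A = NULL), ldet = ss$n * log(sigma2)))
  }
  d <- as.numeric(vc[bl$vc])
  UtU <- ss$UtU
  if (r == 1L) {
    m <- sigma2 + d * UtU[1L, 1L]
    A <- matrix(-d / (sigma2 * m), 1L, 1L)
    ldet <- (ss$n - 1) * log(sigma2) + log(m)
  } else {
    m11 <- sigma2 + d[1L] * UtU[1L, 1L]
    m22 <- sigma2 + d[2L] * UtU[2L, 2L]
    m12 <- sqrt(d[1L] * d[2L]) * UtU[1L, 2L]
    dt <- m11 * m22 - m12 * m12
    # A = -(1/sigma2) * B M^{-1} B elementwise
    s12 <- sqrt(d[1L] * d[2L])
    A <- matrix(c(-d[1L] * m22, s12 * m12, s12 * m12, -d[2L] * m11) /
                  (sigma2 * dt), 2L, 2L)
    ldet <- (ss$n - 2) * log(sigma2) + log(dt)
  }
  list(f = list(a = 1 / sigma2, A = A), ldet = ldet)
}

# derivative form dV/dpsi_k relative to block bl (generic representation)
block_dform <- function(bl, comp) {
  r <- length(bl$vc)
  if (comp == "sigma2") {
    return(list(a = 1, A = if (r > 0L) matrix(0, r, r) else NULL))
  }
  j <- match(comp, bl$vc)
  A <- matrix(0, r, r); A[j, j] <- 1
  list(a = 0, A = A)
}

# Core evaluator: profiled (restricted) Gaussian log-likelihood of the
# one-stage model at fixed variance components, with optional analytic
# gradient and (inference = TRUE) the matrices needed for the
# variance-component information and Kenward-Roger/Satterthwaite
# corrections.
ll_eval <- function(design, vc, estimation, deriv = FALSE, inference = FALSE) {
  p <- design$p
  qn <- design$vc_names
  q <- length(qn)
  vc <- vc[qn]
  blocks <- design$blocks
  K <- length(blocks)
  reml <- estimation == "REML"

  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  yVy <- 0
  ld <- 0
  vinv <- vector("list", K)
  for (b in seq_len(K)) {
    bl <- blocks[[b]]
    bv <- block_vinv(bl, vc)
    f <- bv$f
    vinv[[b]] <- f
    ss <- bl$ss
    idx <- bl$idx
    if (is.null(f$A)) {
      XtVX[idx, idx] <- XtVX[idx, idx] + f$a * ss$ZtZ
      XtVy[idx] <- XtVy[idx] + f$a * ss$Zty
      yVy <- yVy + f$a * ss$yty
    } else {
      AUZ <- f$A %*% ss$UtZ
      XtVX[idx, idx] <- XtVX[idx, idx] + f$a * ss$ZtZ + crossprod(ss$UtZ, AUZ)
      XtVy[idx] <- XtVy[idx] + f$a * ss$Zty + drop(crossprod(AUZ, ss$Uty))
      yVy <- yVy + f$a * ss$yty + drop(crossprod(ss$Uty, f$A %*% ss$Uty))
    }
    ld <- ld + bv$ldet
  }

  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) {
    stop("fitting error: X'V^{-1}X is singular (rank-deficient design)",
         call. = FALSE)
  }
  Phi <- chol2inv(ch)
  beta <- drop(Phi %*% XtVy)
  rVr <- yVy - sum(beta * XtVy)
  ld_XtVX <- 2 * sum(log(diag(ch)))

  llML <- -0.5 * (design$N * log(2 * pi) + ld + rVr)
  crit <- if (reml) llML - 0.5 * ld_XtVX else llML

  out <- list(criterion = crit, loglik_ml = llML, beta = beta, Phi = Phi,
              rVr = rVr, vc = vc)
  if (!deriv && !inference) return(out)

  if (deriv) {
    # fast path: sigma2 via V^{-2} forms, rank-one components via the
    # identity V^{-1} u_j u_j' V^{-1} = (U v)(U v)' with v = a e_j + A U'U e_j
    need_H <- reml
    trV <- numeric(q)
    quad <- numeric(q)
    trPhiH <- numeric(q)
    for (b in seq_len(K)) {
      bl <- blocks[[b]]
      ss <- bl$ss
      f <- vinv[[b]]
      idx <- bl$idx
      bloc <- beta[idx]
      a <- f$a
      A <- f$A
      r <- length(bl$vc)
      Phi_b <- if (need_H) Phi[idx, idx, drop = FALSE]

      if (r == 0L) {
        # sigma2 only: V^{-1} = a I
        trV[1L] <- trV[1L] + a * ss$n
        rr <- ss$yty - 2 * sum(bloc * ss$Zty) +
          drop(crossprod(bloc, ss$ZtZ %*% bloc))
        quad[1L] <- quad[1L] + a * a * rr
        if (need_H) trPhiH[1L] <- trPhiH[1L] + a * a * sum(Phi_b * ss$ZtZ)
        next
      }

      AU <- A %*% ss$UtU
      Ur <- ss$Uty - drop(ss$UtZ %*% bloc)          # U'(y - Z beta)
      # sigma2: F2 = V^{-2} = a^2 I + U (2 a A + A U'U A) U'
      A2 <- 2 * a * A + AU %*% A
      trV[1L] <- trV[1L] + a * ss$n + sum(A * ss$UtU)
      rr <- ss$yty - 2 * sum(bloc * ss$Zty) +
        drop(crossprod(bloc, ss$ZtZ %*% bloc))
      quad[1L] <- quad[1L] + a * a * rr + drop(crossprod(Ur, A2 %*% Ur))
      if (need_H) {
        A2UZ <- A2 %*% ss$UtZ
        H2 <- a * a * ss$ZtZ + crossprod(ss$UtZ, A2UZ)
        trPhiH[1L] <- trPhiH[1L] + sum(Phi_b * H2)
      }
      # rank-one components
      for (k in seq_len(q - 1L)) {
        comp <- qn[k + 1L]
        j <- match(comp, bl$vc)
        if (is.na(j)) next
        v <- AU[, j]
        v[j] <- v[j] + a
        trV[k + 1L] <- trV[k + 1L] + sum(ss$UtU[j, ] * v)
        quad[k + 1L] <- quad[k + 1L] + sum(v * Ur)^2
        if (need_H) {
          h <- drop(crossprod(ss$UtZ, v))
          trPhiH[k + 1L] <- trPhiH[k + 1L] + drop(crossprod(h, Phi_b %*% h))
        }
      }
    }
    grad <- numeric(q)
    for (k in seq_len(q)) {
      trP <- trV[k]
      if (reml) trP <- trP - trPhiH[k]
      grad[k] <- -0.5 * (trP - quad[k])
    }
    names(grad) <- qn
    out$grad <- grad
  }

  if (inference) {
    H <- rep(list(matrix(0, p, p)), q)
    trVV <- matrix(0, q, q)
    Q <- vector("list", q)
    for (k in seq_len(q)) Q[[k]] <- rep(list(matrix(0, p, p)), q)

    for (b in seq_len(K)) {
      bl <- blocks[[b]]
      ss <- bl$ss
      fV <- vinv[[b]]
      dfs <- lapply(qn, function(cn) block_dform(bl, cn))
      VdV <- lapply(dfs, function(fk) f_mult(fV, fk, ss$UtU))
      for (k in seq_len(q)) {
        F2 <- f_mult(VdV[[k]], fV, ss$UtU)                 # V dV_k V
        H[[k]][bl$idx, bl$idx] <- H[[k]][bl$idx, bl$idx] + f_ZFZ(F2, ss)
        for (l in k:q) {
          trVV[k, l] <- trVV[k, l] +
            f_trace(f_mult(VdV[[k]], VdV[[l]], ss$UtU), ss)
          Qc <- f_ZFZ(f_mult(F2, f_mult(dfs[[l]], fV, ss$UtU), ss$UtU), ss)
          Q[[k]][[l]][bl$idx, bl$idx] <- Q[[k]][[l]][bl$idx, bl$idx] + Qc
        }
      }
    }
    for (k in seq_len(q)) for (l in seq_len(q)) {
      if (l < k) {
        trVV[k, l] <- trVV[l, k]
        Q[[k]][[l]] <- t(Q[[l]][[k]])
      }
    }
    out$H <- H
    out$trVV <- trVV
    out$Q <- Q
  }
  out
}

#' Profiled marginal (restricted) log-likelihood at fixed variance components
#'
#' Evaluates the one-stage model's Gaussian marginal log-likelihood with the
#' fixed effects profiled out by generalized least squares (GLS), using
#' per-trial low-rank downdates so the cost is linear in the number of
#' participants.  For `estimation = "REML"` the criterion additionally
#' subtracts \eqn{\frac12 \log |X'V^{-1}X|}.  The value agrees with a direct
#' dense evaluation of the same (restricted) log-likelihood.
#'
#' @param varcomp named numeric vector of variance components; names must
#'   cover `design$vc_names` (`sigma2`, and `tau2` / `tau_beta2` when
#'   active).  All elements must be non-negative with `sigma2 > 0`.
#' @param design an [build_design()] object.
#' @param estimation `"ML"` or `"REML"`.
#' @return A list with `criterion` (the profiled log-likelihood),
#'   `fixed_effects` (the GLS solution \eqn{(X'V^{-1}X)^{-1}X'V^{-1}y},
#'   labelled), and `fixed_cov` (the \eqn{p \times p} GLS covariance
#'   \eqn{(X'V^{-1}X)^{-1}}).
#' @examples
#' cfg <- scenario_config("Base", "normal_random")
#' set.seed(1); d <- generate_ipd(cfg)
#' des <- build_design(d, model_spec())
#' marginal_loglik(c(sigma2 = 334, tau2 = 7.8), des, "REML")$criterion
#' @export
marginal_loglik <- function(varcomp, design, estimation = c("ML", "REML")) {
  estimation <- match.arg(estimation)
  stopifnot(inherits(design, "ipd_design"))
  if (!all(design$vc_names %in% names(varcomp))) {
    stop("`varcomp` must be named and include: ",
         paste(design$vc_names, collapse = ", "), call. = FALSE)
  }
  vc <- varcomp[design$vc_names]
  if (any(vc < 0) || vc[["sigma2"]] <= 0) {
    stop("variance components must be non-negative with sigma2 > 0",
         call. = FALSE)
  }
  ev <- ll_eval(design, vc, estimation)
  list(criterion = ev$criterion,
       fixed_effects = stats::setNames(ev$beta, design$fixed_labels),
       fixed_cov = ev$Phi)
}
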