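# Stationary Kalman-Bucy filtering: algebraic Riccati solver for a scalar
# observation with (possibly) correlated process and observation noise.
#
#   dx = A x dt + dw,            E[dw dw'] = Q dt
#   dy = H x dt + dv,            E[dv^2]   = R dt,   E[dw dv] = S dt
#
# Stationary posterior covariance P solves
#   A P + P A' + Q - (P H' + S) R^-1 (H P + S') = 0.
# Solved by the Hamiltonian eigenvector method on a state-scaled system,
# then polished with Newton (Kleinman) iterations. The de-correlated drift
# is At = A - S R^-1 H with Qt = Q - S S' / R.

# solve A X + X A' + W = 0 for X (A stable), by vectorization; sizes here
# are tiny (<= 4 states) so the kron solve is exact and cheap
lyap_solve <- function(A, W) {
  n <- nrow(A)
  M <- kronecker(diag(n), A) + kronecker(A, diag(n))
  matrix(solve(M, -as.vector(W)), n, n)
}

# stationary prior covariance of a stable channel, solved in scaled
# coordinates for conditioning
stationary_prior <- function(channel) {
  n <- nrow(channel$drift)
  sc <- if (is.null(channel$scale)) rep(1, n) else channel$scale
  Ds <- diag(sc, n); Di <- diag(1 / sc, n)
  X <- lyap_solve(Di %*% channel$drift %*% Ds, Di %*% channel$process_noise %*% Di)
  Ds %*% X %*% Ds
}

care_stationary <- function(A, Q, H, R, S = NULL, scale = NULL,
                            tol = 1e-12) {
  n <- nrow(A)
  H <- matrix(H, nrow = 1)
  S <- if (is.null(S)) matrix(0, n, 1) else matrix(S, ncol = 1)
  if (!(R > 0)) stop("observation noise intensity must be > 0")
  if (is.null(scale)) scale <- rep(1, n)
  if (any(scale <= 0)) stop("state scales must be > 0")
  Ds <- diag(scale, n)
  Di <- diag(1 / scale, n)
  A2 <- Di %*% A %*% Ds
  Q2 <- Di %*% Q %*% Di
  H2 <- (H %*% Ds) / sqrt(R)
  S2 <- (Di %*% S) / sqrt(R)

  At <- A2 - S2 %*% H2
  Qt <- Q2 - S2 %*% t(S2)
  M <- rbind(cbind(t(At), -t(H2) %*% H2),
             cbind(-Qt, -At))
  ev <- eigen(M)
  sel <- order(Re(ev$values))[seq_len(n)]
  V <- ev$vectors[, sel, drop = FALSE]
  X1 <- V[seq_len(n), , drop = FALSE]
  X2 <- V[n + seq_len(n), , drop = FALSE]
  P <- tryCatch(Re(X2 %*% solve(X1)), error = function(e) NULL)
  if (is.null(P)) {
    stop("stationary filter solve failed: the Hamiltonian stable subspace is ",
         "degenerate (channel not detectable?); closed-loop eigenvalues: ",
         paste(format(ev$values, digits = 3), collapse = ", "))
  }
  P <- (P + t(P)) / 2

  resid_of <- function(P) {
    A2 %*% P + P %*% t(A2) + Q2 -
      (P %*% t(H2) + S2) %*% (H2 %*% P + t(S2))
  }
  # Newton polish; each step solves a Lyapunov equation for the closed loop
  for (i in seq_len(40)) {
    K <- P %*% t(H2) + S2
    Acl <- A2 - K %*% H2
    W <- Q2 + K %*% t(K) - S2 %*% t(K) - K %*% t(S2)
    Pn <- tryCatch(lyap_solve(Acl, W), error = function(e) NULL)
    if (is.null(Pn)) break
    Pn <- (Pn + t(Pn)) / 2
    dP <- max(abs(Pn - P))
    P <- Pn
    if (dP <= 1e-14 * max(abs(P), 1e-300)) break
  }
  rel_resid <- norm(resid_of(P), "F") / max(norm(Q2, "F"), 1e-300)
  if (!is.finite(rel_resid) || rel_resid > tol) {
    stop(sprintf(paste0("stationary Riccati solve did not converge: relative ",
                        "residual %.3g (tolerance %.1g); condition of scaled ",
                        "drift %.3g"),
                 rel_resid, tol, kappa(A2)))
  }
  P_full <- Ds %*% P %*% Ds
  list(P = (P_full + t(P_full)) / 2, rel_resid = rel_resid)
}
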