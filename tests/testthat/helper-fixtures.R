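# Shared fixtures and independent oracles used across the test files.

# Random regularized correlation model from the nonstationary-AR(1) family.
random_model <- function(p, seed) {
  regularize(make_covariance(covariance_spec("ar1_corr", p, seed = seed)))
}

equicorrelated <- function(p, rho) {
  sig <- matrix(rho, p, p)
  diag(sig) <- 1
  correlation_model(sig)
}

singleton_partition <- function(p) new_group_partition(seq_len(p))

# Independent maximum-entropy oracle: generic smooth optimizer (BFGS with
# analytic gradient over the free block entries, large finite value outside
# the PD cone). Minimizes -(logdet S + logdet(2 Sigma - S)); shares no code
# with the coordinate-descent solver.
me_objective_oracle <- function(sig, groups) {
  p <- nrow(sig)
  idx <- do.call(rbind, lapply(groups, function(g) {
    cb <- expand.grid(i = g, j = g)
    cb[cb$i <= cb$j, ]
  }))
  to_S <- function(th) {
    S <- matrix(0, p, p)
    S[cbind(idx$i, idx$j)] <- th
    S[cbind(idx$j, idx$i)] <- th
    S
  }
  fn <- function(th) {
    S <- to_S(th)
    D <- 2 * sig - S
    cS <- tryCatch(chol(S), error = function(e) NULL)
    cD <- tryCatch(chol(D), error = function(e) NULL)
    if (is.null(cS) || is.null(cD)) return(1e10)
    -(2 * sum(log(diag(cS))) + 2 * sum(log(diag(cD))))
  }
  gr <- function(th) {
    S <- to_S(th)
    D <- 2 * sig - S
    iS <- chol2inv(chol(S))
    iD <- chol2inv(chol(D))
    mult <- ifelse(idx$i == idx$j, 1, 2)
    -mult * (iS[cbind(idx$i, idx$j)] - iD[cbind(idx$i, idx$j)])
  }
  th0 <- 0.2 * diag(p)[cbind(idx$i, idx$j)]
  optim(th0, fn, gr, method = "BFGS",
        control = list(maxit = 2000, reltol = 1e-14))$value
}

# Direct eigenvalue feasibility check for a proposed coordinate step.
step_is_feasible <- function(S, sigma, m, i, j, delta, tol = 1e-8) {
  Snew <- S
  Snew[i, j] <- Snew[i, j] + delta
  if (i != j) Snew[j, i] <- Snew[j, i] + delta
  Dnew <- ((m + 1) / m) * sigma - Snew
  min(eigen(Snew, TRUE, TRUE)$values) > tol &&
    min(eigen(Dnew, TRUE, TRUE)$values) > tol
}

withr_local_tempfile <- function(env = parent.frame()) {
  withr::local_tempfile(.local_envir = env)
}

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}
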