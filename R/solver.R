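#' Solver options for the group-knockoff S optimization
#'
#' @param method objective: `"maxent"` (maximum entropy / log-determinant),
#'   `"mvr"` (minimum variance-based reconstructability, the trace of the
#'   inverse joint covariance), `"sdp"` (grouped absolute-deviation
#'   semidefinite criterion) or `"equi"` (closed-form equivariant solution
#'   `S_g = tau * Sigma_g`).
#' @param m number of knockoff copies (>= 1).
#' @param max_sweeps maximum number of coordinate+PCA rounds.
#' @param tol_obj relative objective-change stopping tolerance between rounds.
#' @param eps_boundary amount removed from both ends of every feasible
#'   interval so iterates stay strictly inside the positive-definite cone.
#' @param alternation schedule of update phases per round, any ordering of
#'   `"coord"` and `"pca"`, run back-to-back. The default (`NULL`) uses
#'   coordinate-then-PCA for the smooth objectives and PCA-then-coordinate
#'   for `"sdp"`: greedy coordinate moves on the piecewise-linear SDP
#'   criterion can wedge the iterate against the positive-definiteness
#'   boundary where no further single-entry move helps, while leading with
#'   the global eigenvector moves avoids that trap.
#' @return A `solver_options` list.
#' @export
solver_options <- function(method = c("maxent", "mvr", "sdp", "equi"),
                           m = 1L, max_sweeps = 100L, tol_obj = 1e-4,
                           eps_boundary = 1e-6,
                           alternation = NULL) {
  method <- match.arg(method)
  if (is.null(alternation)) {
    alternation <- if (method == "sdp") c("pca", "coord") else c("coord", "pca")
  }
  if (m < 1) gk_stop("m must be >= 1")
  if (eps_boundary < 0) gk_stop("eps_boundary must be positive")
  if (!all(alternation %in% c("coord", "pca"))) {
    gk_stop("alternation phases must be 'coord' or 'pca'")
  }
  structure(list(method = method, m = as.integer(m),
                 max_sweeps = as.integer(max_sweeps), tol_obj = tol_obj,
                 eps_boundary = eps_boundary, alternation = alternation),
            class = "solver_options")
}

#' Joint covariance of the original variables and m knockoff copies
#'
#' Assembles the `(m+1)p x (m+1)p` matrix with `Sigma` on the diagonal blocks
#' and `Sigma - S` everywhere else; a valid `S` is one keeping this matrix
#' positive semidefinite, equivalently `S >= 0` and
#' `(m+1)/m * Sigma - S >= 0`.
#'
#' @param sigma p x p covariance.
#' @param S p x p block-diagonal knockoff matrix.
#' @param m number of knockoff copies.
#' @return The `(m+1)p` square joint covariance.
#' @export
assemble_joint_cov <- function(sigma, S, m) {
  p <- nrow(sigma)
  off <- sigma - S
  G <- matrix(0, (m + 1) * p, (m + 1) * p)
  for (a in 0:m) {
    for (b in 0:m) {
      G[a * p + seq_len(p), b * p + seq_len(p)] <- if (a == b) sigma else off
    }
  }
  G
}

#' Evaluate a group-knockoff objective
#'
#' For minimization: the SDP criterion is the size-normalized absolute
#' deviation `sum_g |A_g|^-2 sum_{i,j in A_g} |S_ij - Sigma_ij|`; the
#' maximum-entropy criterion is `-(m logdet S + logdet D)` with
#' `D = (m+1)/m Sigma - S` (equal to `logdet(G_S^-1)` up to an S-independent
#' constant `p log m`); the MVR criterion is `Tr(G_S^-1)`, computed through
#' the block identity `m Tr(S^-1) + (1/m) Tr(D^-1)`.
#'
#' @param S block-diagonal candidate.
#' @param sigma covariance.
#' @param m copies.
#' @param method `"sdp"`, `"maxent"` or `"mvr"`.
#' @param groups list of group index vectors (required for `"sdp"`).
#' @return Scalar objective; `Inf` when `S` or `D` is singular or indefinite.
#' @export
knockoff_objective <- function(S, sigma, m, method, groups = NULL) {
  D <- ((m + 1) / m) * sigma - S
  if (method == "sdp") {
    if (is.null(groups)) gk_stop("groups are required for the sdp objective")
    val <- 0
    for (idx in groups) {
      val <- val + sum(abs(S[idx, idx] - sigma[idx, idx])) / length(idx)^2
    }
    return(val)
  }
  cS <- tryCatch(chol(S), error = function(e) NULL)
  cD <- tryCatch(chol(D), error = function(e) NULL)
  if (is.null(cS) || is.null(cD)) return(Inf)
  if (method == "maxent") {
    -(2 * m * sum(log(diag(cS))) + 2 * sum(log(diag(cD))))
  } else if (method == "mvr") {
    iS <- backsolve(cS, diag(nrow(S)))
    iD <- backsolve(cD, diag(nrow(S)))
    m * sum(iS^2) + (1 / m) * sum(iD^2)
  } else {
    gk_stop("unknown objective method: ", method)
  }
}

#' Closed-form equivariant group knockoffs
#'
#' Sets `S_g = tau * Sigma_g` with
#' `tau = min(1, (m+1)/m * lambda_min(B Sigma B))` where
#' `B = diag(Sigma_1^-1/2, ..., Sigma_g^-1/2)`, then shrinks by
#' `1 - eps_boundary` to stay strictly feasible. This is the one-parameter
#' construction that the coordinate-descent solvers generalize.
#'
#' @param model a regularized [correlation_model()].
#' @param partition a `group_partition`.
#' @param m number of knockoff copies.
#' @param eps_boundary boundary shrink (set 0 for the exact closed form).
#' @return A `knockoff_solution` (S in canonical group-contiguous order;
#'   `gamma_equi` holds tau before the shrink).
#' @export
solve_equi <- function(model, partition, m = 1L, eps_boundary = 1e-6) {
  sig <- canonical_sigma(model, partition)
  p <- nrow(sig)
  B <- matrix(0, p, p)
  for (idx in partition$groups) {
    eg <- eigen(sig[idx, idx, drop = FALSE], symmetric = TRUE)
    if (min(eg$values) <= 0) gk_stop("non-positive-definite group block")
    B[idx, idx] <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  }
  lam <- min(eigen(B %*% sig %*% B, symmetric = TRUE, only.values = TRUE)$values)
  tau <- min(1, (m + 1) / m * lam)
  S <- matrix(0, p, p)
  for (idx in partition$groups) {
    S[idx, idx] <- tau * (1 - eps_boundary) * sig[idx, idx]
  }
  new_knockoff_solution(S = S, sigma = sig, m = m, method = "equi",
                        partition = partition, objective_trace = numeric(0),
                        gamma_equi = tau, B_whiten = B)
}

new_knockoff_solution <- function(S, sigma, m, method, partition,
                                  objective_trace, gamma_equi = NULL,
                                  B_whiten = NULL) {
  D <- ((m + 1) / m) * sigma - S
  slack <- c(
    lambda_min_S = min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
    lambda_min_D = min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  )
  structure(list(S = S, sigma = sigma, m = m, method = method,
                 partition = partition, objective_trace = objective_trace,
                 slack = slack, gamma_equi = gamma_equi, B_whiten = B_whiten),
            class = "knockoff_solution")
}

#' @export
print.knockoff_solution <- function(x, ...) {
  cat(sprintf(
    "<knockoff_solution> method = %s, m = %d, p = %d, g = %d\n  slack: lambda_min(S) = %.3g, lambda_min(D) = %.3g\n",
    x$method, x$m, nrow(x$S), length(x$partition$groups),
    x$slack[1], x$slack[2]))
  if (length(x$objective_trace)) {
    cat(sprintf("  objective: %.6g after %d rounds\n",
                tail_1(x$objective_trace), length(x$objective_trace)))
  }
  invisible(x)
}

tail_1 <- function(x) x[length(x)]

#' Internal solver state with maintained Cholesky factors
#'
#' Holds `S`, `D = (m+1)/m Sigma - S` and lower-triangular factors
#' `C C^t = S`, `L L^t = D`, updated in place by [apply_update()] through
#' rank-one Cholesky updates/downdates rather than refactorization.
#'
#' @param sigma covariance in canonical (group-contiguous) order.
#' @param groups list of contiguous index vectors.
#' @param S starting block-diagonal matrix, strictly feasible.
#' @param m number of knockoff copies.
#' @param eps_boundary feasible-interval shrink.
#' @return An environment of class `solver_state`.
#' @export
solver_state <- function(sigma, groups, S, m = 1L, eps_boundary = 1e-6) {
  p <- nrow(sigma)
  D <- ((m + 1) / m) * sigma - S
  st <- new.env(parent = emptyenv())
  st$sigma <- sigma
  st$S <- S + 0       # force copies: C/L are modified in place later
  st$D <- D + 0
  st$C <- t(chol(S))
  st$L <- t(chol(D))
  st$m <- m
  st$p <- p
  st$groups <- groups
  st$eps <- eps_boundary
  gid <- integer(p)
  for (k in seq_along(groups)) gid[groups[[k]]] <- k
  st$gid <- gid
  st$rebuilds <- 0L
  class(st) <- "solver_state"
  st
}

# e_i^t (F F^t)^-1 e_j quadratic forms from a lower factor F
quad_pair <- function(F, i, j) {
  ui <- solve_lower_unit(F, i - 1L)
  uj <- if (i == j) ui else solve_lower_unit(F, j - 1L)
  c(ii = sum(ui * ui), ij = sum(ui * uj), jj = sum(uj * uj))
}

#' Feasible interval for a coordinate update
#'
#' Range of `delta` keeping both `S` and `D` positive definite when entry
#' `(i,j)` (and `(j,i)`) of `S` is incremented by `delta`:
#' `(-1/(S^-1)_jj, 1/(D^-1)_jj)` on the diagonal, and
#' `(-2/((e_i+e_j)^t S^-1 (e_i+e_j)), 2/((e_i+e_j)^t D^-1 (e_i+e_j)))`
#' off the diagonal; both ends are pulled in by the solver's
#' `eps_boundary`. The interval always contains 0.
#'
#' @param state a [solver_state()].
#' @param i,j indices in the same group.
#' @return `c(lo, hi)`.
#' @export
feasible_interval <- function(state, i, j) {
  if (state$gid[i] != state$gid[j]) {
    gk_stop("indices ", i, " and ", j, " are in different groups")
  }
  if (i == j) {
    a <- quad_pair(state$C, j, j)
    b <- quad_pair(state$L, j, j)
    lo <- -1 / a[["jj"]]
    hi <- 1 / b[["jj"]]
  } else {
    a <- quad_pair(state$C, i, j)
    b <- quad_pair(state$L, i, j)
    lo <- -2 / (a[["ii"]] + 2 * a[["ij"]] + a[["jj"]])
    hi <- 2 / (b[["ii"]] + 2 * b[["ij"]] + b[["jj"]])
  }
  c(lo + state$eps, hi - state$eps)
}

# Exact positivity range of det(S + delta U_ij)/det(S) and the matching D
# range, used to guard 1-D searches: the conservative printed interval is
# intersected with these roots.
pd_interval_offdiag <- function(a, b) {
  ra <- sqrt(a[["ii"]] * a[["jj"]])
  rb <- sqrt(b[["ii"]] * b[["jj"]])
  loS <- if (ra + a[["ij"]] > 0) -1 / (ra + a[["ij"]]) else -Inf
  hiS <- if (ra - a[["ij"]] > 0) 1 / (ra - a[["ij"]]) else Inf
  loD <- if (rb - b[["ij"]] > 0) -1 / (rb - b[["ij"]]) else -Inf
  hiD <- if (rb + b[["ij"]] > 0) 1 / (rb + b[["ij"]]) else Inf
  c(max(loS, loD), min(hiS, hiD))
}

#' Maximum-entropy coordinate update
#'
#' Returns the increment `delta` for entry `(i,j)` of `S` that maximizes the
#' entropy objective along that coordinate: on the diagonal the closed form
#' `(m s - d) / ((m+1) s d)` with `s = (S^-1)_ii`, `d = (D^-1)_ii` (clipped to
#' the feasible interval); off the diagonal a 1-D concave maximization of the
#' log-determinant gain. The returned `delta` never worsens the objective;
#' its `dobj` attribute is the change in the minimization objective (<= 0).
#'
#' @param state a [solver_state()].
#' @param i,j indices in the same group.
#' @return `delta`, with attribute `dobj`.
#' @export
me_coordinate_update <- function(state, i, j) {
  m <- state$m
  iv <- feasible_interval(state, i, j)
  if (iv[1] >= iv[2]) return(structure(0, dobj = 0))
  if (i == j) {
    s <- quad_pair(state$C, i, i)[["ii"]]
    d <- quad_pair(state$L, i, i)[["ii"]]
    delta <- (m * s - d) / ((m + 1) * s * d)
    delta <- min(max(delta, iv[1]), iv[2])
    gain <- m * log1p(delta * s) + log1p(-delta * d)
    if (!is.finite(gain) || gain < 0) return(structure(0, dobj = 0))
    return(structure(delta, dobj = -gain))
  }
  a <- quad_pair(state$C, i, j)
  b <- quad_pair(state$L, i, j)
  iv <- clip_interval(iv, pd_interval_offdiag(a, b), state$eps)
  if (iv[1] >= iv[2]) return(structure(0, dobj = 0))
  g <- function(delta) {
    qd <- (1 - delta * b[["ij"]])^2 - delta^2 * b[["ii"]] * b[["jj"]]
    qs <- (1 + delta * a[["ij"]])^2 - delta^2 * a[["ii"]] * a[["jj"]]
    if (qd <= 0 || qs <= 0) return(-Inf)
    log(qd) + m * log(qs)
  }
  opt <- optimize(g, interval = iv, maximum = TRUE, tol = 1e-10)
  if (!is.finite(opt$objective) || opt$objective <= 0) {
    return(structure(0, dobj = 0))
  }
  structure(opt$maximum, dobj = -opt$objective)
}

clip_interval <- function(iv, pd, eps) {
  c(max(iv[1], pd[1] + eps), min(iv[2], pd[2] - eps))
}

#' Coordinate update for the MVR and SDP objectives
#'
#' Minimizes the global objective restricted to the line
#' `S + delta * U_ij` over the feasible interval: for `"mvr"` by bounded 1-D
#' minimization of the exact low-rank trace-change identities; for `"sdp"` by
#' exact evaluation of the piecewise-linear deviation at its breakpoint and
#' the interval endpoints. Never worse than `delta = 0`.
#'
#' @param state a [solver_state()].
#' @param i,j indices in the same group.
#' @param method `"mvr"` or `"sdp"`.
#' @return `delta`, with attribute `dobj` (objective change, <= 0).
#' @export
generic_coordinate_update <- function(state, i, j, method = c("mvr", "sdp")) {
  method <- match.arg(method)
  m <- state$m
  iv <- feasible_interval(state, i, j)
  if (iv[1] >= iv[2]) return(structure(0, dobj = 0))

  if (method == "sdp") {
    if (i != j) {
      # the printed interval bounds only one PD constraint per side; clip to
      # the exact determinant roots so endpoint candidates stay feasible
      a <- quad_pair(state$C, i, j)
      b <- quad_pair(state$L, i, j)
      iv <- clip_interval(iv, pd_interval_offdiag(a, b), state$eps)
      if (iv[1] >= iv[2]) return(structure(0, dobj = 0))
    }
    w <- 1 / length(state$groups[[state$gid[i]]])^2
    mult <- if (i == j) 1 else 2
    resid <- state$sigma[i, j] - state$S[i, j]
    cand <- unique(c(min(max(resid, iv[1]), iv[2]), iv[1], iv[2], 0))
    ch <- mult * w * (abs(state$S[i, j] + cand - state$sigma[i, j]) -
                        abs(state$S[i, j] - state$sigma[i, j]))
    k <- which.min(ch)
    if (ch[k] >= 0) return(structure(0, dobj = 0))
    return(structure(cand[k], dobj = ch[k]))
  }

  # MVR: objective m Tr(S^-1) + (1/m) Tr(D^-1); rank-<=2 trace changes
  if (i == j) {
    uS <- solve_lower_unit(state$C, i - 1L)
    uD <- solve_lower_unit(state$L, i - 1L)
    yS <- backsolve(t(state$C), uS)
    yD <- backsolve(t(state$L), uD)
    q1s <- sum(uS^2); q2s <- sum(yS^2)
    q1d <- sum(uD^2); q2d <- sum(yD^2)
    f <- function(delta) {
      den_s <- 1 + delta * q1s
      den_d <- 1 - delta * q1d
      if (den_s <= 0 || den_d <= 0) return(Inf)
      m * (-delta * q2s / den_s) + (1 / m) * (delta * q2d / den_d)
    }
  } else {
    a <- quad_pair(state$C, i, j)
    b <- quad_pair(state$L, i, j)
    iv <- clip_interval(iv, pd_interval_offdiag(a, b), state$eps)
    if (iv[1] >= iv[2]) return(structure(0, dobj = 0))
    uSi <- solve_lower_unit(state$C, i - 1L)
    uSj <- solve_lower_unit(state$C, j - 1L)
    uDi <- solve_lower_unit(state$L, i - 1L)
    uDj <- solve_lower_unit(state$L, j - 1L)
    ySi <- backsolve(t(state$C), uSi); ySj <- backsolve(t(state$C), uSj)
    yDi <- backsolve(t(state$L), uDi); yDj <- backsolve(t(state$L), uDj)
    Ms <- c(sum(uSi^2), sum(uSi * uSj), sum(uSj^2))
    Ns <- c(sum(ySi^2), sum(ySi * ySj), sum(ySj^2))
    Md <- c(sum(uDi^2), sum(uDi * uDj), sum(uDj^2))
    Nd <- c(sum(yDi^2), sum(yDi * yDj), sum(yDj^2))
    # Tr((I + c J M)^-1 c J N) for 2x2 symmetric M = [m1 m2; m2 m3], J swap
    tr_change <- function(cc, M, N) {
      A11 <- 1 + cc * M[2]; A12 <- cc * M[3]
      A21 <- cc * M[1];     A22 <- 1 + cc * M[2]
      det <- A11 * A22 - A12 * A21
      if (det <= 0) return(NA_real_)
      B11 <- cc * N[2]; B12 <- cc * N[3]
      B21 <- cc * N[1]; B22 <- cc * N[2]
      (A22 * B11 - A12 * B21 + A11 * B22 - A21 * B12) / det
    }
    f <- function(delta) {
      ts <- tr_change(delta, Ms, Ns)
      td <- tr_change(-delta, Md, Nd)
      if (is.na(ts) || is.na(td)) return(Inf)
      m * (-ts) + (1 / m) * (-td)
    }
  }
  opt <- optimize(f, interval = iv, tol = 1e-9)
  if (!is.finite(opt$objective) || opt$objective >= 0) {
    return(structure(0, dobj = 0))
  }
  structure(opt$minimum, dobj = opt$objective)
}

#' PCA (eigenvector-direction) update
#'
#' Global rank-one move `S <- S + delta v v^t` along a precomputed eigenvector
#' `v` of the block-diagonal matrix `diag(Sigma_1, ..., Sigma_g)` (so the
#' outer product respects the block pattern). For `"maxent"` the optimal step
#' has the closed form `(m q_s - q_d) / ((m+1) q_s q_d)` with
#' `q_s = v^t S^-1 v`, `q_d = v^t D^-1 v`, which automatically lies in the
#' feasible range `(-1/q_s, 1/q_d)`; `"mvr"` and `"sdp"` use bounded 1-D
#' minimization over that range. The step is returned (not applied); pass it
#' to [apply_update()].
#'
#' @param state a [solver_state()].
#' @param v direction whose support lies within a single group.
#' @param method `"maxent"`, `"mvr"` or `"sdp"`.
#' @return `delta`, with attribute `dobj`.
#' @export
pca_update <- function(state, v, method = c("maxent", "mvr", "sdp")) {
  method <- match.arg(method)
  m <- state$m
  supp <- which(abs(v) > 1e-14)
  if (length(unique(state$gid[supp])) > 1) {
    gk_stop("PCA direction violates the block pattern")
  }
  uS <- forwardsolve(state$C, v)
  uD <- forwardsolve(state$L, v)
  q1s <- sum(uS^2)
  q1d <- sum(uD^2)
  iv <- c(-1 / q1s + state$eps, 1 / q1d - state$eps)
  if (iv[1] >= iv[2]) return(structure(0, dobj = 0))
  if (method == "maxent") {
    delta <- (m * q1s - q1d) / ((m + 1) * q1s * q1d)
    delta <- min(max(delta, iv[1]), iv[2])
    gain <- m * log1p(delta * q1s) + log1p(-delta * q1d)
    if (!is.finite(gain) || gain < 0) return(structure(0, dobj = 0))
    return(structure(delta, dobj = -gain))
  }
  if (method == "mvr") {
    yS <- backsolve(t(state$C), uS)
    yD <- backsolve(t(state$L), uD)
    q2s <- sum(yS^2)
    q2d <- sum(yD^2)
    f <- function(delta) {
      den_s <- 1 + delta * q1s
      den_d <- 1 - delta * q1d
      if (den_s <= 0 || den_d <= 0) return(Inf)
      m * (-delta * q2s / den_s) + (1 / m) * (delta * q2d / den_d)
    }
    opt <- optimize(f, interval = iv, tol = 1e-9)
    if (!is.finite(opt$objective) || opt$objective >= 0) {
      return(structure(0, dobj = 0))
    }
    return(structure(opt$minimum, dobj = opt$objective))
  }
  # sdp: piecewise-linear in delta; exact minimization over breakpoints
  gi <- state$gid[supp[1]]
  idx <- state$groups[[gi]]
  w <- 1 / length(idx)^2
  vb <- v[idx]
  Sb <- state$S[idx, idx, drop = FALSE]
  Gb <- state$sigma[idx, idx, drop = FALSE]
  vv <- tcrossprod(vb)
  bp <- (Gb - Sb)[abs(vv) > 1e-12] / vv[abs(vv) > 1e-12]
  cand <- unique(c(0, iv, bp[bp > iv[1] & bp < iv[2]]))
  ch <- vapply(cand, function(delta) {
    w * (sum(abs(Sb + delta * vv - Gb)) - sum(abs(Sb - Gb)))
  }, numeric(1))
  k <- which.min(ch)
  if (ch[k] >= 0) return(structure(0, dobj = 0))
  structure(cand[k], dobj = ch[k])
}

#' Apply a low-rank feasible update to the solver state
#'
#' Applies either a coordinate increment (`S_ij`, `S_ji` incremented by
#' `delta`; rank <= 2) or a PCA increment (`S + delta v v^t`; rank 1), and
#' maintains the Cholesky factors `C` (of `S`) and `L` (of `D`) through
#' rank-one updates/downdates without refactorization. If a downdate loses
#' positive definiteness numerically, the factors are rebuilt from scratch
#' and a warning is raised.
#'
#' @param state a [solver_state()], modified in place.
#' @param delta step size (0 is a no-op).
#' @param i,j coordinate indices (for a coordinate update).
#' @param v direction (for a PCA update).
#' @return The state, invisibly.
#' @export
apply_update <- function(state, delta, i = NULL, j = NULL, v = NULL) {
  if (delta == 0) return(invisible(state))
  p <- state$p
  if (!is.null(v)) {
    state$S <- state$S + delta * tcrossprod(v)
    state$D <- state$D - delta * tcrossprod(v)
    x <- sqrt(abs(delta)) * v
    sgn <- sign(delta)
    ok <- chol_rank1(state$C, x, sgn) && chol_rank1(state$L, x, -sgn)
  } else if (i == j) {
    state$S[i, i] <- state$S[i, i] + delta
    state$D[i, i] <- state$D[i, i] - delta
    x <- numeric(p); x[i] <- sqrt(abs(delta))
    sgn <- sign(delta)
    ok <- chol_rank1(state$C, x, sgn) && chol_rank1(state$L, x, -sgn)
  } else {
    state$S[i, j] <- state$S[i, j] + delta
    state$S[j, i] <- state$S[j, i] + delta
    state$D[i, j] <- state$D[i, j] - delta
    state$D[j, i] <- state$D[j, i] - delta
    # delta*(e_i e_j^t + e_j e_i^t) = (delta/2) [(e_i+e_j)(.)^t - (e_i-e_j)(.)^t]
    xp <- numeric(p); xp[i] <- 1; xp[j] <- 1
    xm <- numeric(p); xm[i] <- 1; xm[j] <- -1
    h <- sqrt(abs(delta) / 2)
    if (delta > 0) {
      ok <- chol_rank1(state$C, h * xp, 1) && chol_rank1(state$C, h * xm, -1) &&
        chol_rank1(state$L, h * xm, 1) && chol_rank1(state$L, h * xp, -1)
    } else {
      ok <- chol_rank1(state$C, h * xm, 1) && chol_rank1(state$C, h * xp, -1) &&
        chol_rank1(state$L, h * xp, 1) && chol_rank1(state$L, h * xm, -1)
    }
  }
  if (!ok) {
    warning("Cholesky downdate lost positive definiteness; refactorizing")
    state$C <- t(chol(state$S))
    state$L <- t(chol(state$D))
    state$rebuilds <- state$rebuilds + 1L
  }
  invisible(state)
}

# Objective of the current state, computed from the maintained factors.
state_objective <- function(state, method) {
  m <- state$m
  if (method == "maxent") {
    -(2 * m * sum(log(diag(state$C))) + 2 * sum(log(diag(state$L))))
  } else if (method == "mvr") {
    iC <- forwardsolve(state$C, diag(state$p))
    iL <- forwardsolve(state$L, diag(state$p))
    m * sum(iC^2) + (1 / m) * sum(iL^2)
  } else {
    knockoff_objective(state$S, state$sigma, m, "sdp", state$groups)
  }
}

# Eigenvector directions of diag(Sigma_1, ..., Sigma_g), one column per
# variable, each supported on its own group.
pca_directions <- function(sigma, groups) {
  p <- nrow(sigma)
  V <- matrix(0, p, p)
  for (idx in groups) {
    eg <- eigen(sigma[idx, idx, drop = FALSE], symmetric = TRUE)
    V[idx, idx] <- eg$vectors
  }
  V
}

#' Optimize the block-diagonal group-knockoff S matrix
#'
#' Minimizes the chosen objective over block-diagonal `S` subject to
#' `0 <= S <= (m+1)/m Sigma` by alternating full coordinate-descent sweeps
#' (every within-group entry: diagonal first, then the upper triangle in
#' row-major order) with full PCA sweeps (every eigenvector of the
#' block-diagonal part of `Sigma`), maintaining Cholesky factors of `S` and
#' `D` under rank-one updates. Iteration stops when the relative objective
#' change between rounds drops below `tol_obj` or `max_sweeps` is reached.
#' Starts from half the equivariant solution, a strictly interior point.
#'
#' @param model a regularized, positive-definite [correlation_model()].
#' @param partition a `group_partition`.
#' @param options a [solver_options()]; `method = "equi"` dispatches to
#'   [solve_equi()].
#' @return A `knockoff_solution` with `S` in canonical order, the per-round
#'   `objective_trace` (non-increasing) and feasibility `slack`.
#' @export
solve_group_knockoff <- function(model, partition, options = solver_options()) {
  stopifnot(inherits(partition, "group_partition"))
  if (options$method == "equi") {
    return(solve_equi(model, partition, options$m, options$eps_boundary))
  }
  sig <- canonical_sigma(model, partition)
  ok <- tryCatch({chol(sig); TRUE}, error = function(e) FALSE)
  if (!ok) gk_stop("sigma is not positive definite; run regularize() first")
  m <- options$m
  method <- options$method
  groups <- partition$groups

  equi <- solve_equi(model, partition, m, eps_boundary = 0)
  V <- pca_directions(sig, groups)

  descend_from <- function(tau_init) {
    S0 <- matrix(0, nrow(sig), ncol(sig))
    for (idx in groups) S0[idx, idx] <- tau_init * sig[idx, idx]
    st <- solver_state(sig, groups, S0, m, options$eps_boundary)
    trace <- state_objective(st, method)
    for (sweep in seq_len(options$max_sweeps)) {
      for (phase in options$alternation) {
        if (phase == "coord") {
          for (idx in groups) {
            for (i in idx) {
              d <- if (method == "maxent") me_coordinate_update(st, i, i)
                   else generic_coordinate_update(st, i, i, method)
              if (attr(d, "dobj") < 0) apply_update(st, as.numeric(d), i, i)
            }
            if (length(idx) > 1) {
              for (ii in seq_len(length(idx) - 1)) {
                for (jj in (ii + 1):length(idx)) {
                  i <- idx[ii]; j <- idx[jj]
                  d <- if (method == "maxent") me_coordinate_update(st, i, j)
                       else generic_coordinate_update(st, i, j, method)
                  if (attr(d, "dobj") < 0) apply_update(st, as.numeric(d), i, j)
                }
              }
            }
          }
        } else {
          for (k in seq_len(st$p)) {
            v <- V[, k]
            d <- pca_update(st, v, method)
            if (attr(d, "dobj") < 0) apply_update(st, as.numeric(d), v = v)
          }
        }
      }
      obj <- state_objective(st, method)
      trace <- c(trace, obj)
      prev <- trace[length(trace) - 1]
      if (is.finite(obj) &&
          abs(prev - obj) <= options$tol_obj * max(1, abs(prev))) {
        break
      }
    }
    list(st = st, trace = trace)
  }

  run <- descend_from(0.5 * equi$gamma_equi)
  if (method == "sdp") {
    # the piecewise-linear SDP criterion can stall above the equivariant
    # point; a second descent started exactly there guarantees domination
    shrink <- max(options$eps_boundary, 1e-6)  # keep D strictly PD
    run2 <- tryCatch(descend_from(equi$gamma_equi * (1 - shrink)),
                     error = function(e) NULL)
    if (!is.null(run2) && tail_1(run2$trace) < tail_1(run$trace)) run <- run2
  }
  new_knockoff_solution(S = run$st$S, sigma = sig, m = m, method = method,
                        partition = partition, objective_trace = run$trace)
}
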