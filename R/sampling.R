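#' Conditional law of m knockoff copies given the originals
#'
#' From the joint covariance `G_S` of `(Z, Z~_1, ..., Z~_m)`, Gaussian
#' conditioning gives `Z~ = (P Z, ..., P Z) + eps` with `P = I - S Sigma^-1`
#' and `eps ~ N(0, V)` where `V` has diagonal blocks
#' `2S - S Sigma^-1 S` and off-diagonal blocks `S - S Sigma^-1 S`. The
#' implied joint covariance of originals and copies is exactly `G_S`
#' (see [assemble_joint_cov()]).
#'
#' @param sigma p x p covariance.
#' @param S feasible block-diagonal knockoff matrix.
#' @param m number of copies.
#' @return List with `P` (p x p) and `V` (mp x mp, PSD).
#' @export
conditional_knockoff_law <- function(sigma, S, m) {
  p <- nrow(sigma)
  SinvS <- S %*% solve(sigma, S)
  P <- diag(p) - t(solve(sigma, S))      # I - S Sigma^-1 (S, Sigma symmetric)
  off <- S - SinvS
  V <- kronecker(diag(m), S) + kronecker(matrix(1, m, m), off)
  V <- (V + t(V)) / 2
  lam <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < -1e-8) {
    gk_stop("(sigma, S) infeasible for m = ", m, ": V has eigenvalue ", lam)
  }
  list(P = P, V = V)
}

# Symmetric PSD square root with small negative eigenvalues clipped at zero.
psd_sqrt <- function(V, tol = 1e-8) {
  if (nrow(V) == 0) return(V)
  eg <- eigen(V, symmetric = TRUE)
  if (min(eg$values) < -tol) gk_stop("matrix is not PSD within tolerance")
  eg$vectors %*% (t(eg$vectors) * sqrt(pmax(eg$values, 0)))
}

new_knockoff_sample <- function(values, m, seed, kind) {
  structure(list(values = values, m = m,
                 layout = "copy-major", seed = seed, kind = kind),
            class = "knockoff_sample")
}

#' @export
print.knockoff_sample <- function(x, ...) {
  dims <- if (is.matrix(x$values)) paste(dim(x$values), collapse = " x ")
          else length(x$values)
  cat(sprintf("<knockoff_sample> %s, m = %d, %s, layout = %s\n",
              x$kind, x$m, dims, x$layout))
  invisible(x)
}

sample_gaussian_core <- function(X, P, Vhalf, m) {
  n <- nrow(X)
  p <- nrow(P)
  XP <- X %*% t(P)
  base <- do.call(cbind, rep(list(XP), m))
  if (ncol(Vhalf) > 0) {
    E <- matrix(rnorm(n * m * p), n, m * p) %*% Vhalf  # Vhalf symmetric
    base + E
  } else {
    base
  }
}

#' Sample second-order Gaussian group knockoffs for an individual-level design
#'
#' Each row `x` of `X` receives `m` knockoff copies `x~_k = P x + eps_k`
#' with `(eps_1, ..., eps_m)` jointly `N(0, V)` from
#' [conditional_knockoff_law()], so that the second moments of
#' `(X, X~_1, ..., X~_m)` match `G_S`. Columns are laid out copy-major
#' (copy 1 in columns `1..p`, copy 2 in `p+1..2p`, ...), aligned with the
#' column order of `X` and `sigma`.
#'
#' @param X n x p matrix with standardized columns.
#' @param sigma covariance the columns of `X` follow.
#' @param S feasible block-diagonal knockoff matrix.
#' @param m number of copies.
#' @param seed integer seed (reproducible draws).
#' @return A `knockoff_sample` with an `n x (m p)` `values` matrix.
#' @export
sample_knockoffs_gaussian <- function(X, sigma, S, m = 1L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(sigma)) gk_stop("X and sigma disagree on p")
  law <- conditional_knockoff_law(sigma, S, m)
  Vhalf <- psd_sqrt(law$V)
  vals <- with_seed(seed, sample_gaussian_core(X, law$P, Vhalf, m))
  new_knockoff_sample(vals, m, seed, "individual")
}

#' Sample ghost knockoff copies of GWAS summary-statistic Z-scores
#'
#' Draws `z~ = (P z, ..., P z) + eps`, `eps ~ N(0, V)`, producing `m`
#' knockoff copies of the marginal Z-score vector directly from the LD
#' matrix, without individual-level data.
#'
#' @param z length-p vector of marginal Z-scores aligned with `sigma`.
#' @param sigma LD (correlation) matrix.
#' @param S feasible block-diagonal knockoff matrix.
#' @param m number of copies.
#' @param seed integer seed.
#' @return A `knockoff_sample` with a length-`m p` `values` vector.
#' @export
sample_ghost_zscores <- function(z, sigma, S, m = 1L, seed = 1L) {
  z <- as.numeric(z)
  if (length(z) != nrow(sigma)) gk_stop("z and sigma disagree on p")
  law <- conditional_knockoff_law(sigma, S, m)
  Vhalf <- psd_sqrt(law$V)
  vals <- with_seed(seed, {
    base <- rep(as.numeric(law$P %*% z), m)
    base + as.numeric(Vhalf %*% rnorm(m * length(z)))
  })
  new_knockoff_sample(vals, m, seed, "ghost")
}

#' Sample group knockoffs through group-key conditional independence
#'
#' Two-stage sampler: knockoff copies are first drawn for the key variables
#' only, from the (much smaller) solution `solution_star` on the key
#' submatrix; the non-key variables of each group are then drawn from their
#' within-group conditional law given the key knockoffs,
#' `x~_dagger = B_g x~_star(g) + eta`, `eta ~ N(0, R_g)`, independently
#' across copies and groups. When every variable is key (`c = 1`) this
#' reduces exactly to [sample_knockoffs_gaussian()] /
#' [sample_ghost_zscores()] on the full matrix (identical output for matched
#' seeds and the same S).
#'
#' @param data an n x p matrix (individual-level) or length-p vector (ghost
#'   Z-scores), in the original variable order of `model`.
#' @param model the full [correlation_model()].
#' @param keys a `key_selection`.
#' @param regressions the matching [conditional_regressions()].
#' @param solution_star a `knockoff_solution` solved on the key submatrix
#'   (key rows/columns of the canonical sigma, in canonical order).
#' @param m number of copies.
#' @param seed integer seed.
#' @return A `knockoff_sample` in the original variable order (copy-major).
#' @export
sample_knockoffs_group_key <- function(data, model, keys, regressions,
                                       solution_star, m = 1L, seed = 1L) {
  part <- keys$partition
  p <- model$p
  key_all <- sort(unlist(keys$star))
  if (nrow(solution_star$S) != length(key_all)) {
    gk_stop("solution_star dimension does not match the key set")
  }
  sig <- canonical_sigma(model, part)
  sig_star <- sig[key_all, key_all, drop = FALSE]
  law <- conditional_knockoff_law(sig_star, solution_star$S, m)
  Vhalf <- psd_sqrt(law$V)
  ghost <- !is.matrix(data)
  X <- if (ghost) matrix(as.numeric(data), nrow = 1) else as.matrix(data)
  if (ncol(X) != p) gk_stop("data and model disagree on p")
  Xc <- X[, part$perm, drop = FALSE]
  n <- nrow(Xc)
  ps <- length(key_all)
  Rhalf <- lapply(regressions$R, psd_sqrt)

  vals <- with_seed(seed, {
    star_tilde <- sample_gaussian_core(Xc[, key_all, drop = FALSE],
                                       law$P, Vhalf, m)
    out <- matrix(0, n, m * p)
    for (k in seq_len(m)) {
      cols_k <- (k - 1) * ps + seq_len(ps)
      tilde_k <- matrix(0, n, p)
      tilde_k[, key_all] <- star_tilde[, cols_k, drop = FALSE]
      for (gi in seq_len(part$g)) {
        dg <- keys$dagger[[gi]]
        if (length(dg) == 0) next
        st <- keys$star[[gi]]
        eta <- matrix(rnorm(n * length(dg)), n, length(dg)) %*% Rhalf[[gi]]
        tilde_k[, dg] <- tilde_k[, st, drop = FALSE] %*%
          t(regressions$B[[gi]]) + eta
      }
      out[, (k - 1) * p + seq_len(p)] <- tilde_k[, order(part$perm),
                                                 drop = FALSE]
    }
    out
  })
  if (ghost) vals <- as.numeric(vals)
  new_knockoff_sample(vals, m, seed, if (ghost) "ghost" else "individual")
}
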