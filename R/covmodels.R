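#' Correlation model container
#'
#' Wraps a p x p correlation matrix (for GWAS applications, an LD matrix)
#' together with optional per-variant metadata. The matrix must be symmetric
#' with unit diagonal; positive definiteness is enforced separately by
#' [regularize()].
#'
#' @param sigma numeric p x p matrix, symmetric with unit diagonal.
#' @param meta optional data.frame with columns `id`, `chr`, `pos` (1-based),
#'   one row per column of `sigma`.
#' @param gamma shrinkage weight already applied to `sigma` (bookkeeping;
#'   set by [regularize()]).
#' @return An object of class `correlation_model` with fields `sigma`, `p`,
#'   `meta`, `gamma`.
#' @export
correlation_model <- function(sigma, meta = NULL, gamma = 0) {
  sigma <- as.matrix(sigma)
  p <- nrow(sigma)
  if (ncol(sigma) != p) gk_stop("sigma must be square")
  if (!is.numeric(sigma) || anyNA(sigma)) gk_stop("sigma must be numeric and finite")
  if (max(abs(sigma - t(sigma))) > 1e-12) {
    gk_stop("sigma is not symmetric (tolerance 1e-12)")
  }
  if (max(abs(diag(sigma) - 1)) > 1e-12) {
    gk_stop("sigma does not have unit diagonal (tolerance 1e-12)")
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    need <- c("id", "chr", "pos")
    if (!all(need %in% names(meta))) gk_stop("meta must have columns id, chr, pos")
    if (nrow(meta) != p) gk_stop("meta has ", nrow(meta), " rows but sigma has ", p, " columns")
    if (anyDuplicated(meta$id)) gk_stop("duplicate variant ids in meta")
    if (any(meta$pos < 1)) gk_stop("positions must be 1-based (>= 1)")
  }
  structure(list(sigma = sigma, p = p, meta = meta, gamma = gamma),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("<correlation_model> p = %d, gamma = %g%s\n", x$p, x$gamma,
              if (is.null(x$meta)) "" else ", with variant metadata"))
  invisible(x)
}

#' Shrink a correlation matrix towards the identity until positive definite
#'
#' Returns `(1 - gamma) * Sigma + gamma * I` with `gamma` the smallest value
#' on the grid `0, 0.01, 0.02, ...` such that the smallest eigenvalue is at
#' least `eps_pd`. The unit diagonal is preserved and the chosen `gamma` is
#' recorded on the returned model. Idempotent: an already well-conditioned
#' matrix is returned unchanged with `gamma = 0`.
#'
#' @param model a [correlation_model()].
#' @param eps_pd lower bound imposed on the smallest eigenvalue (default 0.01,
#'   which keeps downstream Cholesky factorizations comfortably stable).
#' @return A regularized `correlation_model`.
#' @export
regularize <- function(model, eps_pd = 0.01) {
  stopifnot(inherits(model, "correlation_model"))
  lam <- min(eigen(model$sigma, symmetric = TRUE, only.values = TRUE)$values)
  gamma <- 0
  # lambda_min((1-g) Sigma + g I) = (1-g) lambda_min + g, monotone in g
  while ((1 - gamma) * lam + gamma < eps_pd - 1e-15 && gamma < 1) {
    gamma <- gamma + 0.01
  }
  if (gamma == 0) return(model)
  sig <- (1 - gamma) * model$sigma
  diag(sig) <- 1
  correlation_model(sig, meta = model$meta, gamma = gamma)
}

#' Specification of a synthetic covariance family
#'
#' The five families mirror those used in the simulation studies of the group
#' knockoff literature: equicorrelated blocks, Erdos--Renyi-sparse covariance,
#' Erdos--Renyi-sparse precision, AR(1) with constant correlation, and AR(1)
#' with random adjacent correlations.
#'
#' @param kind one of `"block"`, `"er_cov"`, `"er_prec"`, `"ar1"`, `"ar1_corr"`.
#' @param p number of variables.
#' @param seed integer seed making the draw reproducible.
#' @param ... kind-specific parameters: `b` (block size, default 5) and
#'   `rho_range` (default `c(0.3, 0.9)`) for `block`; `q_er` (edge
#'   probability, default 0.1) and `w_range` (default `c(0.2, 0.6)`) for the
#'   ER families; `rho` (default 0.5) for `ar1`; `rho_range` (default
#'   `c(0.2, 0.8)`) for `ar1_corr`.
#' @return An object of class `covariance_spec`.
#' @export
covariance_spec <- function(kind, p, seed = 1L, ...) {
  kinds <- c("block", "er_cov", "er_prec", "ar1", "ar1_corr")
  if (!kind %in% kinds) gk_stop("unknown covariance kind: ", kind)
  if (p < 1) gk_stop("p must be positive")
  params <- list(...)
  if (kind == "ar1") {
    rho <- if (is.null(params$rho)) 0.5 else params$rho
    if (abs(rho) >= 1) gk_stop("ar1 rho must lie in (-1, 1)")
  }
  if (kind %in% c("er_cov", "er_prec")) {
    q <- if (is.null(params$q_er)) 0.1 else params$q_er
    if (q <= 0 || q >= 1) gk_stop("q_er must lie in (0, 1)")
  }
  structure(list(kind = kind, p = as.integer(p), seed = as.integer(seed),
                 params = params),
            class = "covariance_spec")
}

#' Generate a synthetic correlation matrix
#'
#' Draws a covariance matrix from the family described by `spec`, rescales it
#' to unit diagonal, and wraps it as a [correlation_model()]. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [covariance_spec()].
#' @return A `correlation_model` (apply [regularize()] before solving).
#' @export
make_covariance <- function(spec) {
  stopifnot(inherits(spec, "covariance_spec"))
  p <- spec$p
  pr <- spec$params
  sig <- with_seed(spec$seed, switch(
    spec$kind,
    block = {
      b <- if (is.null(pr$b)) 5L else as.integer(pr$b)
      rr <- if (is.null(pr$rho_range)) c(0.3, 0.9) else pr$rho_range
      sizes <- rep(b, p %/% b)
      if (p %% b) sizes <- c(sizes, p %% b)
      rho_b <- runif(length(sizes), rr[1], rr[2])
      blocks <- lapply(seq_along(sizes), function(k) {
        m <- matrix(rho_b[k], sizes[k], sizes[k]); diag(m) <- 1; m
      })
      block_diag(blocks)
    },
    er_cov = er_matrix(p, pr),
    er_prec = {
      prec <- er_matrix(p, pr)
      chol2inv(chol(prec))
    },
    ar1 = {
      rho <- if (is.null(pr$rho)) 0.5 else pr$rho
      if (abs(rho) >= 1) gk_stop("ar1 rho must lie in (-1, 1)")
      rho^abs(outer(seq_len(p), seq_len(p), "-"))
    },
    ar1_corr = {
      rr <- if (is.null(pr$rho_range)) c(0.2, 0.8) else pr$rho_range
      rho_j <- runif(max(p - 1, 0), rr[1], rr[2])
      # Sigma_ij = prod of adjacent correlations between i and j
      lcum <- c(0, cumsum(log(rho_j)))
      exp(-abs(outer(lcum, lcum, "-")))
    }
  ))
  d <- sqrt(diag(sig))
  sig <- sig / tcrossprod(d)
  sig <- (sig + t(sig)) / 2
  diag(sig) <- 1
  correlation_model(sig)
}

# Sparse symmetric Erdos-Renyi matrix with the diagonal loaded so that the
# smallest eigenvalue is >= 0.1 (used as covariance or precision).
er_matrix <- function(p, pr) {
  q <- if (is.null(pr$q_er)) 0.1 else pr$q_er
  if (q <= 0 || q >= 1) gk_stop("q_er must lie in (0, 1)")
  wr <- if (is.null(pr$w_range)) c(0.2, 0.6) else pr$w_range
  a <- matrix(0, p, p)
  up <- upper.tri(a)
  edges <- runif(sum(up)) < q
  w <- runif(sum(up), wr[1], wr[2]) * sign(runif(sum(up)) - 0.5)
  a[up] <- ifelse(edges, w, 0)
  a <- a + t(a)
  lam <- min(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  diag(a) <- max(0.1 - lam, 0.1)
  a
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  p <- sum(sizes)
  out <- matrix(0, p, p)
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}
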