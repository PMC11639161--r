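#' Group importance from a Lasso on originals and knockoffs
#'
#' Fits an L1-penalized linear regression of `y` on the augmented matrix
#' `[X, X~_1, ..., X~_m]` and sums absolute coefficients within groups:
#' `Z_g = sum_{i in A_g} |beta_i|` for the originals and
#' `Z~_g^(l) = sum_{i in A_g} |beta~_i^(l)|` for each knockoff copy. The
#' penalty is chosen by 10-fold cross-validation (seed-fixed folds) unless a
#' fixed `lambda` is supplied.
#'
#' @param X n x p design (standardized columns).
#' @param knockoffs a `knockoff_sample` or an n x (m p) copy-major matrix
#'   aligned with the columns of `X`.
#' @param y response vector.
#' @param groups list of column index sets (need not be contiguous), or a
#'   `group_partition` whose `assignment` matches the columns of `X`.
#' @param lambda optional fixed penalty; `NULL` (default) cross-validates.
#' @param nfolds CV folds (default 10).
#' @param seed seed fixing the CV fold assignment.
#' @return List with `Z` (length g), `Zt` (g x m matrix) and `beta`
#'   (length `(m+1)p`, for representative-variant reporting).
#' @export
group_importance_lasso <- function(X, knockoffs, y, groups, lambda = NULL,
                                   nfolds = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) gk_stop("need at least 2 samples")
  if (any(!is.finite(y))) gk_stop("non-finite response")
  Kt <- if (inherits(knockoffs, "knockoff_sample")) knockoffs$values else knockoffs
  Kt <- as.matrix(Kt)
  if (ncol(Kt) %% p != 0) gk_stop("knockoff matrix width is not a multiple of p")
  m <- ncol(Kt) / p
  groups <- as_group_list(groups, p)
  XX <- cbind(X, Kt)
  beta <- with_seed(seed, {
    if (is.null(lambda)) {
      foldid <- sample(rep_len(seq_len(nfolds), n))
      fit <- glmnet::cv.glmnet(XX, y, foldid = foldid, standardize = FALSE,
                               nlambda = 100)
      as.numeric(coef(fit, s = "lambda.min"))[-1]
    } else {
      fit <- glmnet::glmnet(XX, y, lambda = lambda, standardize = FALSE)
      as.numeric(coef(fit))[-1]
    }
  })
  group_sums(beta, groups, p, m)
}

#' Group importance from summary statistics (ridge surrogate)
#'
#' A lightweight summary-statistic importance measure: solves the joint ridge
#' system `beta = (G_S + ridge I)^-1 (z, z~)` over originals and knockoff
#' copies and sums `|beta|` within groups, exactly as the Lasso-based
#' importance does. This is a simple surrogate for a full summary-statistic
#' Lasso, adequate for the filter's arithmetic; it is not a penalized
#' regression.
#'
#' @param z length-p Z-score vector.
#' @param ztilde a ghost `knockoff_sample` or length-`m p` vector.
#' @param sigma LD matrix.
#' @param S the knockoff S matrix used to generate `ztilde`.
#' @param groups as in [group_importance_lasso()].
#' @param ridge nonnegative ridge parameter (default 0.01).
#' @return List with `Z`, `Zt`, `beta`.
#' @export
group_importance_ghost <- function(z, ztilde, sigma, S, groups, ridge = 0.01) {
  p <- length(z)
  zt <- if (inherits(ztilde, "knockoff_sample")) ztilde$values else ztilde
  zt <- as.numeric(zt)
  if (length(zt) %% p != 0) gk_stop("ztilde length is not a multiple of p")
  m <- length(zt) / p
  groups <- as_group_list(groups, p)
  G <- assemble_joint_cov(sigma, S, m)
  beta <- solve(G + diag(ridge, nrow(G)), c(z, zt))
  group_sums(beta, groups, p, m)
}

as_group_list <- function(groups, p) {
  if (inherits(groups, "group_partition")) {
    groups <- split(seq_len(p), groups$assignment)
    names(groups) <- NULL
  }
  groups
}

group_sums <- function(beta, groups, p, m) {
  g <- length(groups)
  Z <- vapply(groups, function(idx) sum(abs(beta[idx])), numeric(1))
  Zt <- matrix(0, g, m)
  for (l in seq_len(m)) {
    Zt[, l] <- vapply(groups, function(idx) sum(abs(beta[l * p + idx])),
                      numeric(1))
  }
  list(Z = Z, Zt = Zt, beta = beta)
}

#' Per-group multiple-knockoff scores
#'
#' For each group, compares the original importance `Z_g` with its `m`
#' knockoff importances: `kappa_g = 0` when the original wins
#' (`Z_g >= max_l Z~_g^(l)`, ties favoring the original), otherwise the index
#' of the winning copy; `tau_g` is the winner's margin, the largest of the
#' `m + 1` values minus the median of the remaining `m`; and
#' `W_g = tau_g * 1(kappa_g = 0)`, which on winning groups equals
#' `(Z_g - median(Z~_g^(1..m))) * 1(Z_g >= max Z~_g)`.
#'
#' @param Z length-g original importances (>= 0).
#' @param Zt g x m matrix of knockoff importances.
#' @return data.frame with columns `kappa`, `tau`, `W`.
#' @export
knockoff_scores <- function(Z, Zt) {
  Zt <- as.matrix(Zt)
  g <- length(Z)
  kappa <- integer(g)
  tau <- numeric(g)
  for (i in seq_len(g)) {
    vals <- c(Z[i], Zt[i, ])
    kappa[i] <- if (Z[i] >= max(Zt[i, ])) 0L else which.max(Zt[i, ])
    tau[i] <- vals[kappa[i] + 1] - median(vals[-(kappa[i] + 1)])
  }
  data.frame(kappa = kappa, tau = tau, W = tau * (kappa == 0))
}

#' Multiple-knockoff selection threshold
#'
#' Selects the smallest threshold `t` among the positive margins such that
#' the estimated false discovery proportion
#' `(1/m + (1/m) #\{g: kappa_g >= 1, tau_g >= t\}) /
#'  max(1, #\{g: kappa_g = 0, tau_g >= t\})`
#' is at most `q`; groups with `kappa_g = 0` and `tau_g >= T` are selected.
#' With no qualifying `t` the threshold is `+Inf` and nothing is selected.
#'
#' @param kappa,tau per-group scores from [knockoff_scores()].
#' @param q target FDR level in (0, 1).
#' @param m number of knockoff copies.
#' @return List with `threshold` and `selected` (integer group indices).
#' @export
multiple_knockoff_threshold <- function(kappa, tau, q, m) {
  if (q <= 0 || q >= 1) gk_stop("q must lie in (0, 1)")
  if (length(kappa) != length(tau)) gk_stop("kappa and tau lengths differ")
  cand <- sort(unique(tau[tau > 0]))
  threshold <- Inf
  for (t in cand) {
    fdp <- (1 / m + (1 / m) * sum(kappa >= 1 & tau >= t)) /
      max(1, sum(kappa == 0 & tau >= t))
    if (fdp <= q) {
      threshold <- t
      break
    }
  }
  list(threshold = threshold,
       selected = which(kappa == 0 & tau >= threshold))
}

#' Run the knockoff filter on computed importances
#'
#' Convenience wrapper chaining [knockoff_scores()] and
#' [multiple_knockoff_threshold()].
#'
#' @param Z,Zt importances as in [knockoff_scores()].
#' @param q target FDR level.
#' @return An object of class `filter_result`: the scores data.frame plus
#'   `threshold`, `selected` and `q`.
#' @export
knockoff_filter <- function(Z, Zt, q = 0.1) {
  sc <- knockoff_scores(Z, Zt)
  th <- multiple_knockoff_threshold(sc$kappa, sc$tau, q, ncol(as.matrix(Zt)))
  structure(list(scores = sc, threshold = th$threshold,
                 selected = th$selected, q = q),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %d of %d groups selected at q = %g (T = %g)\n",
              length(x$selected), nrow(x$scores), x$q, x$threshold))
  invisible(x)
}
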