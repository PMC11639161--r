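#' Simulate a standardized Gaussian design
#'
#' Draws `n` independent rows from `N(0, Sigma)` and standardizes each column
#' to mean 0, variance 1.
#'
#' @param sigma covariance (or a [correlation_model()]).
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return n x p matrix.
#' @export
simulate_design <- function(sigma, n, seed = 1L) {
  if (inherits(sigma, "correlation_model")) sigma <- sigma$sigma
  if (n < 1) gk_stop("n must be >= 1")
  p <- nrow(sigma)
  R <- chol(sigma)
  X <- with_seed(seed, matrix(rnorm(n * p), n, p) %*% R)
  if (n > 1) X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Simulate a sparse linear response
#'
#' Chooses `k` causal indices uniformly without replacement, draws their
#' effects from `N(0, effect_sd^2)`, and sets `y = X beta + eps` with
#' standard normal per-sample noise.
#'
#' @param X design matrix.
#' @param k number of causal variables.
#' @param effect_sd causal effect standard deviation.
#' @param seed integer seed.
#' @return List with `y`, `beta`, `causal_idx`.
#' @export
simulate_response <- function(X, k, effect_sd = 1, seed = 1L) {
  p <- ncol(X)
  if (k > p) gk_stop("k must not exceed p")
  with_seed(seed, {
    causal <- if (k > 0) sort(sample.int(p, k)) else integer(0)
    beta <- numeric(p)
    beta[causal] <- rnorm(k, sd = effect_sd)
    y <- as.numeric(X %*% beta) + rnorm(nrow(X))
    list(y = y, beta = beta, causal_idx = causal)
  })
}

#' Group-level power and FDR of a selection
#'
#' A group is causal when it contains at least one causal index; power is the
#' fraction of causal groups selected (0 when there are none), and FDR the
#' fraction of selected groups containing no causal index (0 when nothing is
#' selected).
#'
#' @param selected integer vector of selected group labels.
#' @param partition a `group_partition` (or an assignment vector).
#' @param causal_idx causal variable indices (same order as the assignment).
#' @return `c(power, fdr)`.
#' @export
evaluate_power_fdr <- function(selected, partition, causal_idx) {
  assignment <- if (inherits(partition, "group_partition")) {
    partition$assignment
  } else {
    as.integer(partition)
  }
  causal_groups <- unique(assignment[causal_idx])
  power <- if (length(causal_groups) == 0) 0 else {
    length(intersect(selected, causal_groups)) / length(causal_groups)
  }
  fdr <- length(setdiff(selected, causal_groups)) / max(1, length(selected))
  c(power = power, fdr = fdr)
}

#' Configuration of a power/FDR simulation experiment
#'
#' @param cov_spec a [covariance_spec()] (its seed is re-drawn per replicate
#'   so each replicate sees a fresh covariance from the family).
#' @param n samples per replicate.
#' @param k causal variables per replicate.
#' @param effect_sd causal effect standard deviation (default 1).
#' @param m knockoff copies (default 5).
#' @param method solver objective (default `"maxent"`).
#' @param q target FDR level (default 0.1).
#' @param cutoff clustering correlation cutoff (default 0.5).
#' @param c key-variable explained-variance fraction; 1 (default) disables
#'   the conditional-independence shortcut.
#' @param reps number of replicates.
#' @param seed master seed; per-replicate seeds are spawned from it.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cov_spec, n, k, effect_sd = 1, m = 5L,
                              method = "maxent", q = 0.1, cutoff = 0.5,
                              c = 1, reps = 10L, seed = 1L) {
  stopifnot(inherits(cov_spec, "covariance_spec"))
  if (k > cov_spec$p) gk_stop("k must not exceed p")
  if (q <= 0 || q >= 1) gk_stop("q must lie in (0, 1)")
  if (reps < 1) gk_stop("reps must be >= 1")
  structure(list(cov_spec = cov_spec, n = as.integer(n), k = as.integer(k),
                 effect_sd = effect_sd, m = as.integer(m), method = method,
                 q = q, cutoff = cutoff, c = c, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# One replicate of the pipeline: covariance -> design -> response -> groups
# (from the sample correlation of X) -> S -> knockoffs -> Lasso -> filter.
run_replicate <- function(config, rep_seed) {
  spec <- config$cov_spec
  spec$seed <- spawn_seed(rep_seed, 1L)
  truth <- regularize(make_covariance(spec))
  X <- simulate_design(truth, config$n, spawn_seed(rep_seed, 2L))
  resp <- simulate_response(X, config$k, config$effect_sd,
                            spawn_seed(rep_seed, 3L))
  emp <- correlation_model(stats::cor(X))
  partition <- hierarchical_cluster_groups(emp, config$cutoff)
  opts <- solver_options(method = config$method, m = config$m)
  inv <- order(partition$perm)
  p <- truth$p

  if (config$c < 1) {
    keys <- select_key_variables(truth, partition, config$c)
    regs <- conditional_regressions(truth, keys)
    key_all <- sort(unlist(keys$star))
    sig <- canonical_sigma(truth, partition)
    star_model <- correlation_model(sig[key_all, key_all, drop = FALSE])
    star_part <- key_subpartition(keys, key_all)
    sol_star <- solve_group_knockoff(star_model, star_part, opts)
    kt <- sample_knockoffs_group_key(X, truth, keys, regs, sol_star,
                                     config$m, spawn_seed(rep_seed, 4L))
    Kt <- kt$values  # original order
  } else {
    sol <- solve_group_knockoff(truth, partition, opts)
    Xc <- X[, partition$perm, drop = FALSE]
    kt <- sample_knockoffs_gaussian(Xc, sol$sigma, sol$S, config$m,
                                    spawn_seed(rep_seed, 4L))
    # back to original column order within each copy
    Kt <- do.call(cbind, lapply(seq_len(config$m), function(k) {
      kt$values[, (k - 1) * p + inv, drop = FALSE]
    }))
  }
  imp <- group_importance_lasso(X, Kt, resp$y, partition,
                                seed = spawn_seed(rep_seed, 5L))
  res <- knockoff_filter(imp$Z, imp$Zt, config$q)
  pf <- evaluate_power_fdr(res$selected, partition, resp$causal_idx)
  c(pf, n_selected = length(res$selected))
}

# Partition of the key submatrix (canonical order restricted to keys):
# groups stay contiguous because keys are sorted within contiguous groups.
key_subpartition <- function(keys, key_all = sort(unlist(keys$star))) {
  lab <- rep(seq_along(keys$star), lengths(keys$star))[order(unlist(keys$star))]
  new_group_partition(lab, length(key_all))
}

#' Run a group-knockoff power/FDR experiment
#'
#' Runs `reps` replicates of the full pipeline (fresh covariance, design and
#' response each time; groups defined from the sample correlation of the
#' observed design; knockoffs constructed from the generating covariance) and
#' aggregates group-level power and FDR. Failed replicates are recorded and
#' skipped with a message.
#'
#' @param config an [experiment_config()].
#' @return A `simulation_result`: data.frame `per_rep` plus means and
#'   Monte-Carlo standard errors of power and FDR.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- vector("list", config$reps)
  for (r in seq_len(config$reps)) {
    rep_seed <- spawn_seed(config$seed, 1000L + r)
    out <- tryCatch(run_replicate(config, rep_seed), error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      c(power = NA_real_, fdr = NA_real_, n_selected = NA_real_)
    })
    rows[[r]] <- data.frame(rep = r, power = out[["power"]],
                            fdr = out[["fdr"]],
                            n_selected = out[["n_selected"]])
  }
  per_rep <- do.call(rbind, rows)
  ok <- !is.na(per_rep$power)
  agg <- list(
    per_rep = per_rep,
    reps = sum(ok),
    power_mean = mean(per_rep$power[ok]),
    power_se = sd(per_rep$power[ok]) / sqrt(max(1, sum(ok))),
    fdr_mean = mean(per_rep$fdr[ok]),
    fdr_se = sd(per_rep$fdr[ok]) / sqrt(max(1, sum(ok)))
  )
  structure(agg, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d replicates\n  power = %.3f (se %.3f)\n  fdr   = %.3f (se %.3f)\n",
    x$reps, x$power_mean, x$power_se, x$fdr_mean, x$fdr_se))
  invisible(x)
}
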