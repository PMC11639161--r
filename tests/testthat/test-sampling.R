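test_that("conditional law reproduces G_S exactly", {
  # degenerate boundary: S = 0 gives exact copies
  sig <- make_covariance(covariance_spec("ar1", 3, rho = 0.4))$sigma
  law0 <- conditional_knockoff_law(sig, matrix(0, 3, 3), 2)
  expect_equal(law0$P, diag(3))
  expect_equal(law0$V, matrix(0, 6, 6))
  # Sigma = S = I: knockoffs independent standard normal
  law1 <- conditional_knockoff_law(diag(2), diag(2), 1)
  expect_equal(law1$P, matrix(0, 2, 2))
  expect_equal(law1$V, diag(2))
  # random feasible (Sigma, S, m = 3): assembled joint covariance equals G_S
  mod <- random_model(4, seed = 2)
  part <- new_group_partition(c(1, 1, 2, 2))
  sol <- solve_group_knockoff(mod, part, solver_options("maxent", m = 3))
  law <- conditional_knockoff_law(sol$sigma, sol$S, 3)
  p <- 4; m <- 3
  G <- assemble_joint_cov(sol$sigma, sol$S, m)
  PS <- law$P %*% sol$sigma
  Gimp <- G * 0
  Gimp[1:p, 1:p] <- sol$sigma
  for (k in 1:m) {
    rk <- k * p + 1:p
    Gimp[rk, 1:p] <- PS
    Gimp[1:p, rk] <- t(PS)
    for (l in 1:m) {
      rl <- l * p + 1:p
      Gimp[rk, rl] <- law$P %*% sol$sigma %*% t(law$P) +
        law$V[(k - 1) * p + 1:p, (l - 1) * p + 1:p]
    }
  }
  expect_lt(max(abs(G - Gimp)), 1e-10)
})

test_that("individual-level sampling is reproducible and matches boundaries", {
  sig <- make_covariance(covariance_spec("ar1", 3, rho = 0.4))$sigma
  X <- simulate_design(sig, 50, seed = 1)
  # S = 0: exact copies
  kt0 <- sample_knockoffs_gaussian(X, sig, matrix(0, 3, 3), m = 2, seed = 9)
  expect_equal(kt0$values, cbind(X, X), ignore_attr = TRUE)
  # determinism
  kt1 <- sample_knockoffs_gaussian(X, sig, 0.3 * diag(3), m = 2, seed = 5)
  kt2 <- sample_knockoffs_gaussian(X, sig, 0.3 * diag(3), m = 2, seed = 5)
  expect_identical(kt1$values, kt2$values)
  expect_false(identical(
    kt1$values,
    sample_knockoffs_gaussian(X, sig, 0.3 * diag(3), m = 2, seed = 6)$values))
})

test_that("empirical second moments converge to G_S", {
  n <- 2e5
  # Sigma = S = I, m = 1: Cov(X, X~) = 0
  X <- simulate_design(diag(2), n, seed = 2)
  kt <- sample_knockoffs_gaussian(X, diag(2), diag(2), m = 1, seed = 3)
  expect_lt(max(abs(crossprod(X, kt$values) / n)), 0.02)
  # random feasible S, m = 2: all blocks of G_S within 0.02
  mod <- random_model(5, seed = 6)
  part <- new_group_partition(c(1, 1, 1, 2, 2))
  sol <- solve_group_knockoff(mod, part, solver_options("maxent", m = 2))
  X2 <- simulate_design(sol$sigma, n, seed = 7)
  kt2 <- sample_knockoffs_gaussian(X2, sol$sigma, sol$S, m = 2, seed = 8)
  emp <- crossprod(cbind(X2, kt2$values)) / n
  G <- assemble_joint_cov(sol$sigma, sol$S, 2)
  expect_lt(max(abs(emp - G)), 0.02)
  # group-swap exchangeability of second moments: swapping the columns of
  # group 1 with its knockoffs leaves the covariance structure unchanged
  swp <- cbind(kt2$values[, 1:3], X2[, 4:5], X2[, 1:3], kt2$values[, 4:5],
               kt2$values[, 5 + 1:5])
  emp_swp <- crossprod(swp) / n
  expect_lt(max(abs(emp_swp - G)), 0.02)
})

test_that("ghost z-score sampling has the right degenerate and null laws", {
  z <- c(1.5, -2, 0.3)
  sig <- make_covariance(covariance_spec("ar1", 3, rho = 0.4))$sigma
  # S = 0: m exact copies of z
  g0 <- sample_ghost_zscores(z, sig, matrix(0, 3, 3), m = 3, seed = 1)
  expect_equal(g0$values, rep(z, 3))
  # determinism
  g1 <- sample_ghost_zscores(z, sig, 0.4 * diag(3), m = 2, seed = 4)
  g2 <- sample_ghost_zscores(z, sig, 0.4 * diag(3), m = 2, seed = 4)
  expect_identical(g1$values, g2$values)
  # Sigma = S = I: knockoffs are N(0, I) independent of z and across copies
  p <- 3; m <- 5; reps <- 4e3
  draws <- vapply(seq_len(reps), function(r) {
    sample_ghost_zscores(z, diag(p), diag(p), m = m, seed = 1000 + r)$values
  }, numeric(m * p))
  cors <- cor(t(draws))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.06)
  expect_lt(max(abs(rowMeans(draws))), 0.06)
})

test_that("group-key sampler reduces to the full sampler when c = 1", {
  mod <- random_model(6, seed = 11)
  part <- new_group_partition(c(1, 1, 1, 2, 2, 2))
  keys <- new_key_selection(part, star = part$groups)
  regs <- conditional_regressions(mod, keys)
  sol <- solve_group_knockoff(mod, part, solver_options("maxent", m = 2))
  X <- simulate_design(mod, 30, seed = 1)
  kt_key <- sample_knockoffs_group_key(X, mod, keys, regs, sol, m = 2,
                                       seed = 42)
  kt_full <- sample_knockoffs_gaussian(X, mod$sigma, sol$S, m = 2, seed = 42)
  expect_equal(kt_key$values, kt_full$values, tolerance = 1e-10)
})

test_that("group-key sampler reproduces the full maxent joint law under
           group-key conditional independence", {
  base <- regularize(make_covariance(covariance_spec("ar1", 12, rho = 0.6)))
  part <- new_group_partition(rep(1:3, each = 4))
  keys <- new_key_selection(part, star = list(1:2, 5:6, 9:10))
  mod <- regularize(ci_implied_sigma(base, keys))
  full <- solve_group_knockoff(mod, part,
                               solver_options("maxent", tol_obj = 1e-8,
                                              max_sweeps = 300))
  G_full <- assemble_joint_cov(full$sigma, full$S, 1)
  regs <- conditional_regressions(mod, keys)
  key_all <- sort(unlist(keys$star))
  star_model <- correlation_model(mod$sigma[key_all, key_all])
  star_part <- new_group_partition(rep(1:3, each = 2))
  sol_star <- solve_group_knockoff(star_model, star_part,
                                   solver_options("maxent", tol_obj = 1e-8,
                                                  max_sweeps = 300))
  n <- 2e5
  X <- simulate_design(mod, n, seed = 6)
  kt <- sample_knockoffs_group_key(X, mod, keys, regs, sol_star, m = 1,
                                   seed = 7)
  emp <- crossprod(cbind(X, kt$values)) / n
  expect_lt(max(abs(emp - G_full)), 0.02)
})
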