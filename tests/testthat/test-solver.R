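test_that("objectives evaluate to hand-computed values", {
  I2 <- diag(2)
  part <- list(1L, 2L)
  expect_equal(knockoff_objective(I2, I2, 1, "sdp", part), 0)
  # p = 1 maximum entropy: -(log s + log(2 - s)), minimized at s = 1
  s_grid <- c(0.5, 1, 1.5)
  vals <- vapply(s_grid, function(s) {
    knockoff_objective(matrix(s), matrix(1), 1, "maxent")
  }, numeric(1))
  expect_equal(vals, -(log(s_grid) + log(2 - s_grid)))
  expect_equal(which.min(vals), 2L)
  # MVR at Sigma = S = I, m = 1: Tr(G^-1) with G = I4
  expect_equal(knockoff_objective(I2, I2, 1, "mvr"), 4)
})

test_that("maxent and MVR objectives agree with direct (m+1)p computation", {
  for (m in c(1, 3)) {
    mod <- random_model(6, seed = 10 + m)
    part <- new_group_partition(c(1, 1, 1, 2, 2, 2))
    sol <- solve_group_knockoff(mod, part, solver_options("maxent", m = m))
    G <- assemble_joint_cov(sol$sigma, sol$S, m)
    # logdet identity: logdet G = m logdet S + logdet D + p log m
    direct <- determinant(G, logarithm = TRUE)$modulus[1]
    viaS <- -knockoff_objective(sol$S, sol$sigma, m, "maxent") + 6 * log(m)
    expect_equal(viaS, direct, tolerance = 1e-8)
    # trace identity
    expect_equal(knockoff_objective(sol$S, sol$sigma, m, "mvr"),
                 sum(diag(solve(G))), tolerance = 1e-8)
  }
})

test_that("equivariant solution has the closed-form tau", {
  # identity: tau = 1, S = I
  eq <- solve_equi(correlation_model(diag(4)), singleton_partition(4),
                   m = 1, eps_boundary = 0)
  expect_equal(eq$gamma_equi, 1)
  expect_equal(eq$S, diag(4))
  # equicorrelated rho = 0.75, singletons: tau = min(1, 2(1 - rho)) = 0.5
  eq2 <- solve_equi(equicorrelated(6, 0.75), singleton_partition(6),
                    m = 1, eps_boundary = 0)
  expect_equal(eq2$gamma_equi, 0.5)
  expect_equal(eq2$S, 0.5 * diag(6))
  # one group spanning everything: B Sigma B = I, tau = 1, S = Sigma
  mod <- random_model(5, seed = 2)
  eq3 <- solve_equi(mod, new_group_partition(rep(1, 5)), m = 1,
                    eps_boundary = 0)
  expect_equal(eq3$gamma_equi, 1)
  expect_equal(eq3$S, mod$sigma, tolerance = 1e-10)
})

test_that("feasible intervals match the printed quadratic forms", {
  I2 <- diag(2)
  st <- solver_state(I2, list(1:2), 0.5 * I2, m = 1, eps_boundary = 0)
  expect_equal(feasible_interval(st, 1, 1), c(-0.5, 1.5))
  expect_equal(feasible_interval(st, 1, 2), c(-0.5, 1.5))
  # interval always contains 0
  mod <- random_model(6, seed = 5)
  sol <- solve_group_knockoff(mod, new_group_partition(c(1, 1, 1, 2, 2, 2)),
                              solver_options("maxent"))
  st2 <- solver_state(sol$sigma, sol$partition$groups, sol$S, m = 1)
  for (i in 1:3) for (j in i:3) {
    iv <- feasible_interval(st2, i, j)
    expect_lt(iv[1], 0)
    expect_gt(iv[2], 0)
  }
  expect_error(feasible_interval(st2, 1, 4), class = "gk_validation_error")
})

test_that("maxent coordinate updates match closed forms and a grid oracle", {
  I2 <- diag(2)
  st <- solver_state(I2, list(1:2), 0.5 * I2, m = 1, eps_boundary = 0)
  # diagonal: (m s - d)/((m+1) s d) with s = 2, d = 2/3
  expect_equal(as.numeric(me_coordinate_update(st, 1, 1)), 0.5)
  # grid-search oracle on the scalar gain
  grid <- seq(-0.49, 1.49, by = 1e-4)
  gain <- log(1 + grid * 2) * 1 + log(1 - grid * 2 / 3)
  expect_equal(grid[which.max(gain)], 0.5, tolerance = 1e-3)
  # at the optimum S = I both diagonal and off-diagonal steps vanish
  st_opt <- solver_state(I2, list(1:2), I2 * (1 - 1e-9), m = 1,
                         eps_boundary = 0)
  expect_lt(abs(as.numeric(me_coordinate_update(st_opt, 1, 1))), 1e-8)
  expect_lt(abs(as.numeric(me_coordinate_update(st_opt, 1, 2))), 1e-6)
})

test_that("mvr and sdp coordinate updates match small closed forms", {
  I2 <- diag(2)
  st <- solver_state(I2, list(1:2), 0.5 * I2, m = 1, eps_boundary = 0)
  # sdp: drive |S_11 - 1| to zero
  expect_equal(as.numeric(generic_coordinate_update(st, 1, 1, "sdp")), 0.5)
  # mvr on p = 1: minimized at s = 1, so delta = 0.5 from s = 0.5
  st1 <- solver_state(matrix(1), list(1L), matrix(0.5), m = 1,
                      eps_boundary = 1e-9)
  expect_equal(as.numeric(generic_coordinate_update(st1, 1, 1, "mvr")), 0.5,
               tolerance = 1e-6)
  # at a constrained optimum the step is ~0 for both
  sol <- solve_group_knockoff(random_model(4, seed = 7),
                              new_group_partition(c(1, 1, 2, 2)),
                              solver_options("mvr", tol_obj = 1e-10,
                                             max_sweeps = 300))
  st2 <- solver_state(sol$sigma, sol$partition$groups, sol$S, m = 1)
  d <- generic_coordinate_update(st2, 1, 2, "mvr")
  expect_lt(abs(attr(d, "dobj")), 1e-8)
})

test_that("PCA updates use the closed form and stay feasible", {
  I2 <- diag(2)
  st <- solver_state(I2, list(1:2), 0.5 * I2, m = 1, eps_boundary = 0)
  e1 <- c(1, 0)
  expect_equal(as.numeric(pca_update(st, e1, "maxent")), 0.5)
  st_opt <- solver_state(I2, list(1:2), I2 * (1 - 1e-9), m = 1,
                         eps_boundary = 0)
  expect_lt(abs(as.numeric(pca_update(st_opt, e1, "maxent"))), 1e-8)
  # diagonal coordinate update equals the PCA update at v = e_i
  mod <- random_model(6, seed = 12)
  sol0 <- solve_equi(mod, new_group_partition(c(1, 1, 1, 2, 2, 2)), m = 2)
  st2 <- solver_state(sol0$sigma, sol0$partition$groups,
                      0.5 * sol0$S, m = 2)
  e3 <- numeric(6); e3[3] <- 1
  expect_equal(as.numeric(me_coordinate_update(st2, 3, 3)),
               as.numeric(pca_update(st2, e3, "maxent")), tolerance = 1e-12)
  # step always inside the rank-one feasible range
  uS <- forwardsolve(st2$C, e3); uD <- forwardsolve(st2$L, e3)
  d <- as.numeric(pca_update(st2, e3, "maxent"))
  expect_gt(d, -1 / sum(uS^2))
  expect_lt(d, 1 / sum(uD^2))
  # direction crossing groups is rejected
  expect_error(pca_update(st2, rep(1, 6) / sqrt(6), "maxent"),
               class = "gk_validation_error")
})

test_that("rank-one/two Cholesky maintenance matches refactorization", {
  # worked 2x2 case
  I2 <- diag(2)
  st <- solver_state(I2, list(1L, 2L), 0.5 * I2, m = 1)
  apply_update(st, 0.5, 1, 1)
  expect_equal(st$C, t(chol(diag(c(1, 0.5)))), tolerance = 1e-12)
  expect_equal(st$L, t(chol(diag(c(1, 1.5)))), tolerance = 1e-12)
  # zero step is a no-op
  C_before <- st$C + 0
  apply_update(st, 0, 1, 2)
  expect_identical(st$C, C_before)
})

test_that("solver returns S = Sigma-scaled solutions on canonical instances", {
  # identity covariance, singleton groups: S = I for every method and m
  model <- correlation_model(diag(8))
  part <- singleton_partition(8)
  for (meth in c("maxent", "mvr", "sdp")) {
    for (m in c(1, 5)) {
      sol <- solve_group_knockoff(model, part, solver_options(meth, m = m))
      expect_lt(max(abs(sol$S - diag(8))), 1e-6)
    }
  }
  # single all-spanning group: S converges to Sigma
  mod <- random_model(6, seed = 3)
  part1 <- new_group_partition(rep(1, 6))
  for (meth in c("maxent", "mvr", "sdp")) {
    sol <- solve_group_knockoff(mod, part1,
                                solver_options(meth, tol_obj = 1e-10,
                                               max_sweeps = 500))
    expect_lt(max(abs(sol$S - mod$sigma)), 1e-4)
  }
})

test_that("objective traces are monotone and feasibility slack holds", {
  for (seed in 1:4) {
    mod <- random_model(8, seed = 20 + seed)
    part <- new_group_partition(rep(1:2, each = 4))
    for (meth in c("maxent", "mvr", "sdp")) {
      sol <- solve_group_knockoff(mod, part, solver_options(meth, m = 2))
      expect_true(all(diff(sol$objective_trace) <= 1e-8))
      expect_gte(sol$slack[["lambda_min_S"]], -1e-8)
      expect_gte(sol$slack[["lambda_min_D"]], -1e-8)
      # coordinate solutions are at least as good as the equivariant point
      eqv <- solve_equi(mod, part, m = 2)
      obj_cd <- knockoff_objective(sol$S, sol$sigma, 2, meth, part$groups)
      obj_eq <- knockoff_objective(eqv$S, eqv$sigma, 2, meth, part$groups)
      expect_lte(obj_cd, obj_eq + 1e-8)
    }
  }
})
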