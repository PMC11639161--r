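test_that("clustering matches hand-computable merges and keeps the cut strict", {
  # identity: all dissimilarities 1, six singletons
  part <- hierarchical_cluster_groups(correlation_model(diag(6)), 0.5)
  expect_equal(part$g, 6)
  # one strong pair merges
  sig <- diag(2); sig[1, 2] <- sig[2, 1] <- 0.9
  expect_equal(hierarchical_cluster_groups(correlation_model(sig), 0.5)$g, 1)
  # exactly-at-cutoff correlation does not merge (strict cut)
  sig[1, 2] <- sig[2, 1] <- 0.5
  expect_equal(hierarchical_cluster_groups(correlation_model(sig), 0.5)$g, 2)
  # two rho = 0.8 blocks of 3 with zero cross-correlation: exactly 2 groups
  b <- matrix(0.8, 3, 3); diag(b) <- 1
  sig2 <- rbind(cbind(b, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), b))
  part2 <- hierarchical_cluster_groups(correlation_model(sig2), 0.5)
  expect_equal(part2$g, 2)
  expect_equal(lengths(part2$groups), c(3L, 3L))
})

test_that("groups are contiguous after the canonical permutation", {
  mod <- random_model(15, seed = 4)
  part <- hierarchical_cluster_groups(mod, 0.5)
  lab_canon <- part$assignment[part$perm]
  expect_true(all(diff(lab_canon) >= 0))       # contiguous blocks
  expect_setequal(unlist(part$groups), seq_len(15))
})

test_that("clustering is invariant to variable permutation up to relabeling", {
  mod <- random_model(12, seed = 8)
  part <- hierarchical_cluster_groups(mod, 0.5)
  set.seed(1)
  pi <- sample(12)
  mod2 <- correlation_model(mod$sigma[pi, pi])
  part2 <- hierarchical_cluster_groups(mod2, 0.5)
  # co-membership must agree: variable k of mod2 is variable pi[k] of mod
  co1 <- outer(part$assignment[pi], part$assignment[pi], "==")
  co2 <- outer(part2$assignment, part2$assignment, "==")
  expect_identical(co1, co2)
})

test_that("key selection satisfies the explained-variance contract", {
  # singleton groups: the variable is always key
  mod <- correlation_model(diag(3))
  keys <- select_key_variables(mod, singleton_partition(3), c = 0.3)
  expect_equal(lengths(keys$star), rep(1L, 3))
  # duplicated variable (r = 1): one key explains everything at c = 0.5
  sig <- matrix(c(1, 1, 1, 1), 2, 2)
  mod2 <- regularize(correlation_model(sig))
  part2 <- new_group_partition(c(1, 1))
  keys2 <- select_key_variables(mod2, part2, c = 0.5)
  expect_equal(lengths(keys2$star), 1L)
  # c = 1 means every variable is key, for every group
  mod3 <- random_model(10, seed = 2)
  part3 <- hierarchical_cluster_groups(mod3, 0.3)
  keys3 <- select_key_variables(mod3, part3, c = 1)
  expect_equal(lengths(keys3$dagger), rep(0L, part3$g))
  expect_identical(keys3$star, part3$groups)
})

test_that("key sets grow monotonically in c", {
  mod <- random_model(12, seed = 6)
  part <- new_group_partition(rep(1:2, each = 6))
  sizes <- vapply(c(0.25, 0.5, 0.75, 1), function(cc) {
    sum(lengths(select_key_variables(mod, part, cc)$star))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("conditional regressions reproduce scalar Gaussian conditioning", {
  rho <- 0.7
  sig <- matrix(c(1, rho, rho, 1), 2, 2)
  mod <- correlation_model(sig)
  part <- new_group_partition(c(1, 1))
  keys <- new_key_selection(part, star = list(1L))
  reg <- conditional_regressions(mod, keys)
  expect_equal(reg$B[[1]], matrix(rho, 1, 1))
  expect_equal(reg$R[[1]], matrix(1 - rho^2, 1, 1))
  # empty dagger: empty matrices
  keys_all <- new_key_selection(part, star = list(c(1L, 2L)))
  reg2 <- conditional_regressions(mod, keys_all)
  expect_equal(dim(reg2$B[[1]]), c(0L, 2L))
})

test_that("residual covariances are PSD for random inputs", {
  for (seed in 1:5) {
    mod <- random_model(12, seed = seed)
    part <- new_group_partition(rep(1:3, each = 4))
    keys <- select_key_variables(mod, part, c = 0.5)
    reg <- conditional_regressions(mod, keys)
    for (R in reg$R) {
      if (nrow(R) > 0) {
        expect_gte(min(eigen(R, TRUE, TRUE)$values), -1e-10)
      }
    }
  }
})

test_that("ci_implied_sigma preserves structure and is idempotent", {
  mod <- random_model(12, seed = 3)
  part <- new_group_partition(rep(1:3, each = 4))
  keys <- new_key_selection(part, star = list(1:2, 5:6, 9:10))
  ci <- ci_implied_sigma(mod, keys)
  # symmetric, unit diagonal, within-group blocks preserved
  expect_lt(max(abs(ci$sigma - t(ci$sigma))), 1e-12)
  expect_equal(diag(ci$sigma), rep(1, 12))
  for (idx in part$groups) {
    expect_equal(ci$sigma[idx, idx], mod$sigma[idx, idx])
  }
  # c = 1: unchanged
  keys1 <- new_key_selection(part, star = part$groups)
  expect_equal(ci_implied_sigma(mod, keys1)$sigma, mod$sigma)
  # idempotent / round-trip: a matrix already satisfying the property
  ci2 <- ci_implied_sigma(ci, keys)
  expect_lt(max(abs(ci2$sigma - ci$sigma)), 1e-10)
})
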