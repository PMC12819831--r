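test_that("by-person correlation matches hand arithmetic", {
  g11 <- q_grid(-5:5, rep(1, 11))
  a <- c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4, 5)
  b <- rev(a)
  qs <- cbind(i1 = a, i2 = a, i3 = b)
  R <- q_correlate(qs)
  expect_equal(R["i1", "i2"], 1)
  expect_equal(R["i1", "i3"], -1) # negation under a symmetric grid
  expect_equal(diag(R), setNames(rep(1, 3), colnames(qs)))

  # two hand-made sorts: r computed by explicit covariance arithmetic
  set.seed(2)
  c2 <- sample(a)
  r_hand <- sum((a - mean(a)) * (c2 - mean(c2))) /
    sqrt(sum((a - mean(a))^2) * sum((c2 - mean(c2))^2))
  expect_equal(q_correlate(cbind(a, c2))[1, 2], r_hand, tolerance = 1e-12)
  expect_error(q_correlate(matrix(a, ncol = 1)), class = "qorient_dim_error")
})

test_that("extraction reproduces closed-form eigenstructure", {
  sol <- q_extract(diag(4), max_factors = 4, n_statements = 54)
  expect_equal(sol$eigenvalues, rep(1, 4))
  expect_equal(sol$explained_pct, rep(25, 4))

  R2 <- matrix(1, 2, 2)
  sol2 <- q_extract(R2, max_factors = 2, n_statements = 54)
  expect_equal(sol2$all_eigenvalues, c(2, 0))
  expect_error(q_extract(matrix(c(1, 0.5, 0.2, 1), 2), max_factors = 1,
                         n_statements = 10),
               class = "qorient_dim_error")
})

test_that("published eigenvalues give the published explained-variance row", {
  # printed unrotated eigenvalues for 389 sorts
  ev <- c(187.302, 92.909, 39.265, 15.6638, 9.240, 8.362, 5.242, 4.747)
  pct <- 100 * ev / 389
  expect_equal(round(pct[1:4]), c(48, 24, 10, 4))
  expect_equal(round(cumsum(pct))[1:4], c(48, 72, 82, 86))
  expect_equal(round(sum(pct[1:4])), 86) # four-factor cumulative
})

test_that("loading significance threshold matches the printed conventions", {
  expect_equal(round(significance_threshold(54, 2.58), 3), 0.351)
  expect_equal(significance_threshold(36, 2.58), 0.43)
  expect_equal(significance_threshold(25, 1.96), 0.392)
})

test_that("Kaiser-Guttman screen handles degenerate and clone structures", {
  # identity correlation: eigenvalues exactly 1.0 fail the strict > 1.0 rule
  sol_id <- q_extract(diag(6), max_factors = 6, n_statements = 54)
  expect_equal(kaiser_guttman_screen(sol_id), 0)

  # one perfect clone group of 3 sorts among noise-free singletons
  R <- diag(5)
  R[1:3, 1:3] <- 1
  sol <- q_extract(R, max_factors = 5, n_statements = 54)
  expect_equal(sol$eigenvalues[1], 3)
  expect_equal(kaiser_guttman_screen(sol), 1)
})

test_that("varimax leaves single factors alone and preserves communality", {
  set.seed(9)
  L1 <- matrix(rnorm(8), 8, 1, dimnames = list(NULL, "F1"))
  sol <- structure(list(loadings = L1, eigenvalues = 2, explained_pct = 25,
                        cumulative_pct = 25, rotation_log = list(),
                        n_statements = 54, threshold = 0.351,
                        n_institutions = 8),
                   class = "q_factor_solution")
  rot <- rotate_varimax(sol)
  expect_equal(abs(rot$loadings[, 1]), abs(L1[, 1]))

  L <- matrix(rnorm(24), 8, 3)
  Lr <- rotate_varimax(L)
  expect_equal(rowSums(Lr^2), rowSums(L^2), tolerance = 1e-9)
})

test_that("varimax reaches the brute-force planar maximum on 2-factor matrices", {
  # subset of random matrices here; the full 50-matrix sweep runs in the
  # acceptance suite
  for (seed in 1:8) {
    L <- withr::with_seed(seed, matrix(rnorm(16), 8, 2))
    Lr <- rotate_varimax(L, normalize = TRUE)
    expect_equal(varimax_crit(Lr, normalize = TRUE),
                 varimax_planar_oracle(L, normalize = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("varimax agrees with the reference implementation in stats", {
  for (seed in c(3, 14)) {
    L <- withr::with_seed(seed, matrix(rnorm(40), 10, 4))
    Lr <- rotate_varimax(L, normalize = TRUE)
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
    expect_equal(varimax_crit(Lr), varimax_crit(unclass(ref$loadings)),
                 tolerance = 1e-6)
  }
})

test_that("manual rotation is an exact Givens rotation with a log", {
  set.seed(4)
  base <- q_extract(cov2cor(crossprod(matrix(rnorm(60), 10, 6))),
                    max_factors = 4, n_statements = 54)
  same <- manual_rotate(base, 1, 4, 0)
  expect_equal(same$loadings, base$loadings)

  fwd <- manual_rotate(base, 1, 4, 2)
  back <- manual_rotate(fwd, 1, 4, 2, direction = "clockwise")
  expect_equal(back$loadings, base$loadings, tolerance = 1e-12)
  expect_equal(length(back$rotation_log), 2)
  expect_equal(back$rotation_log[[2]]$degrees, -2)

  arb <- manual_rotate(base, 2, 3, 37.5)
  expect_equal(rowSums(arb$loadings^2), rowSums(base$loadings^2),
               tolerance = 1e-12)
  expect_error(manual_rotate(base, 1, 9, 2), class = "qorient_config_error")
  expect_error(manual_rotate(base, 2, 2, 2), class = "qorient_config_error")
})

test_that("defining-sort flags follow the strict majority-communality rule", {
  L <- rbind(c(0.8, 0.1), c(0.5, 0.5), c(0.2, 0.3), c(-0.7, 0.2))
  colnames(L) <- c("F1", "F2")
  sol <- structure(list(loadings = L, threshold = 0.351),
                   class = "q_factor_solution")
  flags <- flag_defining(sol)
  expect_true(flags[1, "F1"]) # 0.64 > 0.65/2
  expect_false(any(flags[2, ])) # 0.25 not > 0.25: strict boundary
  expect_false(any(flags[3, ])) # below threshold
  expect_true(flags[4, "F1"]) # sign-symmetric
  expect_true(all(rowSums(flags) <= 1))
  expect_error(flag_defining(sol, threshold = 0), class = "qorient_config_error")
})

test_that("factor z-scores reduce to the standardized sort for one definer", {
  qs <- random_qsorts(n_inst = 4)
  L <- matrix(c(0.9, 0.1, 0.1, 0.1), 4, 1,
              dimnames = list(colnames(qs), "F1"))
  sol <- structure(list(loadings = L, threshold = 0.351),
                   class = "q_factor_solution")
  flags <- flag_defining(sol)
  expect_equal(sum(flags), 1)
  z <- factor_zscores(qs, sol, flags)
  raw <- unclass(qs)[, 1]
  expect_equal(z[, 1], (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  expect_equal(mean(z[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(z[, 1]), 1, tolerance = 1e-12)

  # two defining sorts with identical columns: same as the single-sort case
  qs2 <- unclass(qs)
  qs2[, 2] <- qs2[, 1]
  L2 <- matrix(c(0.9, 0.8, 0.1, 0.1), 4, 1,
               dimnames = list(colnames(qs), "F1"))
  sol2 <- structure(list(loadings = L2, threshold = 0.351),
                    class = "q_factor_solution")
  z2 <- factor_zscores(qs2, sol2, flag_defining(sol2))
  expect_equal(z2[, 1], z[, 1], tolerance = 1e-12)

  # the Brown weight at f = 0.707: w = f / (1 - f^2) ~ 1.414
  f <- 0.707
  expect_equal(f / (1 - f^2), 1.4142, tolerance = 1e-3)

  sol_none <- structure(list(loadings = L * 0.1, threshold = 0.351),
                        class = "q_factor_solution")
  expect_error(factor_zscores(qs, sol_none,
                              matrix(FALSE, 4, 1,
                                     dimnames = list(colnames(qs), "F1"))),
               regexp = "F1", class = "qorient_flag_error")
})

test_that("factor arrays re-impose the grid with stable ties", {
  g <- q_grid()
  z <- matrix(seq(54, 1) / 10, 54, 1,
              dimnames = list(sprintf("S%02d", 1:54), "F1"))
  arr <- factor_arrays(z, g)
  expect_equal(arr[1, 1], 5L)
  expect_equal(as.integer(table(factor(arr[, 1], levels = -5:5))),
               g$column_counts)

  # equal z for adjacent statements: index order decides, matching a stable
  # descending sort
  z2 <- z
  z2[2, 1] <- z2[1, 1]
  arr2 <- factor_arrays(z2, g)
  expect_equal(arr2[1, 1], 5L)
  expect_equal(arr2[2, 1], 5L)
})

test_that("composite reliability reproduces the published factor table", {
  rel <- q_reliability(c(F1 = 180, F2 = 135, F3 = 40, F4 = 5))
  expect_equal(round(rel$composite_reliability, 3),
               c(0.999, 0.998, 0.994, 0.952))
  expect_equal(round(rel$se_zscores, 3), c(0.032, 0.045, 0.077, 0.219))

  rel1 <- q_reliability(c(F1 = 1))
  expect_equal(rel1$composite_reliability, 0.8)
  expect_equal(rel1$se_zscores, sqrt(0.2))

  # strict monotonicity in p
  rel_mono <- q_reliability(setNames(1:50, paste0("F", 1:50)))
  expect_true(all(diff(rel_mono$composite_reliability) > 0))
  expect_true(all(diff(sqrt(1 - rel_mono$composite_reliability)) < 0))
  expect_error(q_reliability(c(F1 = 0)), class = "qorient_flag_error")
})

test_that("distinguishing statements use the SED inequality per comparison", {
  # two factors with printed z-score SEs of 0.032 each:
  # SED = sqrt(0.032^2 + 0.032^2) = 0.04525
  rel <- tibble::tibble(factor = c("F1", "F2"), p = c(180L, 180L),
                        avg_rel_coef = 0.8, composite_reliability = 0.999,
                        se_zscores = 0.032)
  sed <- sqrt(sum(rel$se_zscores^2))
  expect_equal(sed, 0.04525, tolerance = 1e-3)

  z <- matrix(0, 3, 2, dimnames = list(c("S01", "S02", "S03"), c("F1", "F2")))
  z[1, ] <- c(0.10, 0) # 0.10 > 1.96 * 0.04525 but < 2.58 * 0.04525
  z[2, ] <- c(0.20, 0) # clears both levels
  d <- distinguishing_statements(z, rel)
  d1 <- d[d$statement_id == "S01" & d$factor == "F1", ]
  expect_equal(d1$mark, "D")
  expect_equal(d1$level, 0.05)
  d2 <- d[d$statement_id == "S02" & d$factor == "F1", ]
  expect_equal(d2$mark, "D*")
  expect_false("S03" %in% d$statement_id)

  # identical z columns: nothing distinguishes, everything is consensus
  z0 <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("S", 1:3), NULL))
  z0[, 2] <- z0[, 1]
  expect_equal(nrow(distinguishing_statements(z0, rel)), 0)
  expect_equal(consensus_statements(z0, rel), paste0("S", 1:3))

  cons <- consensus_statements(z, rel)
  expect_false("S01" %in% cons)
  expect_true("S03" %in% cons)
  expect_error(consensus_statements(z[, 1, drop = FALSE], rel),
               class = "qorient_config_error")
})

test_that("eigenvalues agree with characteristic-polynomial roots", {
  skip_if_not_installed("pracma")
  withr::with_seed(17, {
    for (d in 3:5) {
      A <- matrix(rnorm(d * d), d)
      S <- (A + t(A)) / 2
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      roots <- sort(Re(polyroot(rev(pracma::charpoly(S)))), decreasing = TRUE)
      expect_equal(ev, roots, tolerance = 1e-8)
    }
  })
})

test_that("trace conservation holds for generated correlation matrices", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      qs <- random_qsorts(n_inst = 8, seed = 100 + rep)
      R <- q_correlate(qs)
      sol <- q_extract(R, max_factors = 8, n_statements = 54)
      expect_equal(sum(sol$all_eigenvalues), 8, tolerance = 1e-9)
      expect_lte(sum(sol$explained_pct[1:4]), 100 + 1e-9)
    }
  })
})

test_that("rotations preserve communality and explained variance of the block", {
  qs <- random_qsorts(n_inst = 10, seed = 55)
  sol <- retain_factors(q_extract(q_correlate(qs), max_factors = 4,
                                  n_statements = 54), 3)
  h2 <- rowSums(sol$loadings^2)
  total <- sum(sol$loadings^2)
  rot <- rotate_varimax(sol)
  expect_equal(rowSums(rot$loadings^2), h2, tolerance = 1e-9)
  expect_equal(sum(rot$loadings^2), total, tolerance = 1e-9)
  man <- manual_rotate(rot, 1, 3, 11)
  expect_equal(rowSums(man$loadings^2), h2, tolerance = 1e-9)
})
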