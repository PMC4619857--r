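test_that("fit_vertexwise matches a normal-equations oracle on random instances", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 12; nv <- 5
    X <- design_matrix(x1 = rnorm(n), x2 = rnorm(n))
    Y <- matrix(rnorm(n * nv), n, nv)
    sm <- fit_vertexwise(Y, X, "x1")
    for (v in seq_len(nv)) {
      o <- ols_oracle(Y[, v], X, "x1")
      expect_equal(sm$beta[v], o$beta, tolerance = 1e-9)
      expect_equal(sm$t[v], o$t, tolerance = 1e-9)
      expect_identical(sm$df, o$df)
    }
  }
})

test_that("noiseless data recovers beta exactly with flagged infinite t", {
  set.seed(5)
  n <- 10
  X <- design_matrix(x = rnorm(n))
  beta_true <- c(1.5, -0.7)
  Y <- X %*% cbind(beta_true, 2 * beta_true)
  sm <- fit_vertexwise(Y, X, "x")
  expect_equal(sm$beta, c(-0.7, -1.4), tolerance = 1e-9)
  expect_true(all(sm$flagged))
  expect_identical(sm$t, c(-Inf, -Inf))
})

test_that("row permutation invariance and design-error reporting", {
  set.seed(6)
  n <- 15
  X <- design_matrix(a = rnorm(n), b = rnorm(n))
  Y <- matrix(rnorm(n * 4), n)
  perm <- sample(n)
  s1 <- fit_vertexwise(Y, X, "a")
  s2 <- fit_vertexwise(Y[perm, ], X[perm, ], "a")
  expect_equal(s1$beta, s2$beta, tolerance = 1e-12)
  expect_equal(s1$t, s2$t, tolerance = 1e-12)

  Xbad <- design_matrix(a = rnorm(n), twice_a = NA)
  Xbad[, "twice_a"] <- 2 * Xbad[, "a"]
  expect_error(fit_vertexwise(Y, Xbad, "a"), "collinear.*twice_a")
  expect_error(fit_vertexwise(Y, X, "zzz"), "not a design column")
})

test_that("residualize_covariates is an idempotent projection orthogonal to covariates", {
  set.seed(7)
  n <- 20; nv <- 10
  cov <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.4))
  Y <- matrix(rnorm(n * nv, 2.5, 0.3), n, nv)
  A <- residualize_covariates(Y, cov)
  expect_equal(residualize_covariates(A, cov), A, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(A))), 1e-8)
  expect_lt(max(abs(crossprod(cov$age, A))), 1e-8 * sqrt(sum(cov$age^2)))
  expect_lt(max(abs(crossprod(cov$sex, A))), 1e-8)
  # brute-force per-vertex lm oracle
  for (v in 1:3) {
    o <- residuals(lm(Y[, v] ~ cov$age + cov$sex))
    expect_equal(unname(A[, v]), unname(o), tolerance = 1e-9)
  }
  expect_error(residualize_covariates(Y, data.frame(age = rep(1, n),
                                                    sex = cov$sex)),
               "constant")
})

test_that("seed_mean equals a naive summation oracle and handles edge cases", {
  set.seed(8)
  Y <- matrix(rnorm(6 * 12), 6, 12)
  s <- seed_region("S", c(2L, 5L, 11L))
  expected <- sapply(1:6, function(i) sum(Y[i, c(2, 5, 11)]) / 3)
  expect_equal(seed_mean(Y, s), expected, tolerance = 1e-12)
  expect_equal(seed_mean(Y, seed_region("one", 4L)), Y[, 4], tolerance = 1e-15)
  const <- matrix(rep(1:6, 12), 6, 12)
  expect_equal(seed_mean(const, seed_region("all", 1:12)), as.numeric(1:6))
  expect_error(seed_mean(Y, seed_region("far", 99L)), "exceed")
})

test_that("scn_map: t relates to Pearson r algebraically; self-correlation flags", {
  set.seed(9)
  n <- 25
  sv <- rnorm(n)
  Y <- cbind(sv, matrix(rnorm(n * 6), n))
  sm <- scn_map(Y, sv)
  expect_identical(sm$df, as.integer(n - 2))
  for (v in 2:7) {
    r <- cor(Y[, v], sv)
    expect_equal(sm$t[v], r * sqrt((n - 2) / (1 - r^2)), tolerance = 1e-9)
    expect_equal(sm$r[v], r, tolerance = 1e-9)
  }
  # vertex identical to the seed: perfect correlation, flagged
  expect_true(sm$flagged[1])
  expect_identical(sm$t[1], Inf)
  expect_identical(sm$r[1], 1)
  expect_error(scn_map(Y, rep(1, n)), "zero variance|degenerate")
  expect_error(scn_map(Y[1:3, ], sv[1:3]), "at least 4")
})

test_that("interaction coefficient equals the difference of per-group slopes exactly", {
  set.seed(10)
  for (rep in 1:20) {
    n <- 2 * sample(10:25, 1)
    g <- rep(0:1, each = n / 2)
    sv <- rnorm(n)
    Y <- matrix(rnorm(n * 4), n)
    im <- interaction_map(Y, sv, g, "group")
    expect_identical(im$df, as.integer(n - 4))
    for (v in 1:4) {
      s_hc <- coef(lm(Y[g == 0, v] ~ sv[g == 0]))[2]
      s_pi <- coef(lm(Y[g == 1, v] ~ sv[g == 1]))[2]
      expect_equal(im$beta[v], unname(s_pi - s_hc), tolerance = 1e-9)
    }
  }
})

test_that("identical groups give a zero interaction with zero t", {
  set.seed(11)
  half <- matrix(rnorm(10 * 5), 10)
  Y <- rbind(half, half)
  sv <- rep(rnorm(10), 2)
  g <- rep(0:1, each = 10)
  im <- interaction_map(Y, sv, g, "group")
  expect_lt(max(abs(im$beta)), 1e-12)
  expect_lt(max(abs(im$t[!im$flagged])), 1e-9)
  expect_error(interaction_map(Y, sv, rep(1, 20)), "constant")
})

test_that("interaction slope difference is recovered in simulation at study size", {
  set.seed(16)
  seedreg <- seed_region("SEED", 1:3, ico2)
  target <- 100L
  db <- numeric(nrow(ico2$vertices)); db[target] <- 0.4
  b3 <- replicate(15, {
    i <- sample.int(1e6, 1)
    sp <- simulation_spec(ico2, n_per_group = 35, seed_region = seedreg,
                          seed_signal_sd = 0.3, coupling_delta = db,
                          noise_sd = 0.1, rng_seed = i)
    coh <- sample_cohort(sp)
    ds <- generate_thickness(ico2, coh, sp)
    Yadj <- residualize_covariates(ds$thickness, coh)
    sv <- seed_mean(Yadj, seedreg)
    im <- interaction_map(Yadj, sv, coh$group, "group")
    im$beta[target]
  })
  expect_equal(mean(b3), 0.4, tolerance = 0.06)
})

test_that("group map is antisymmetric in labels; PSQI map matches a partial-correlation oracle", {
  set.seed(12)
  n <- 30; nv <- 8
  coh <- data.frame(group = rep(0:1, each = n / 2), age = rnorm(n, 40, 8),
                    sex = rbinom(n, 1, 0.3),
                    psqi = sample(0:21, n, replace = TRUE))
  Y <- matrix(rnorm(n * nv, 2.5, 0.2), n, nv)
  gm <- thickness_group_map(Y, coh)
  expect_identical(gm$df, as.integer(n - 5))
  coh_sw <- coh; coh_sw$group <- 1L - coh$group
  gm_sw <- thickness_group_map(Y, coh_sw)
  expect_equal(gm$t, -gm_sw$t, tolerance = 1e-9)

  pm <- thickness_psqi_map(Y, coh)
  meanct <- rowMeans(Y)
  for (v in 1:nv) {
    ry <- residuals(lm(Y[, v] ~ coh$age + coh$sex + meanct))
    rx <- residuals(lm(coh$psqi ~ coh$age + coh$sex + meanct))
    expect_equal(pm$r[v], cor(ry, rx), tolerance = 1e-9)
  }
})

test_that("t maps are invariant to affine rescaling of covariates", {
  set.seed(13)
  n <- 26
  coh <- data.frame(group = rep(0:1, each = 13), age = rnorm(n, 45, 9),
                    sex = rbinom(n, 1, 0.5),
                    psqi = sample(0:21, n, replace = TRUE))
  Y <- matrix(rnorm(n * 6, 2.5, 0.2), n)
  coh2 <- coh
  coh2$age <- (coh$age - 45) / 9
  expect_equal(thickness_group_map(Y, coh)$t,
               thickness_group_map(Y, coh2)$t, tolerance = 1e-8)
  expect_equal(residualize_covariates(Y, coh) -
               residualize_covariates(Y, coh2),
               matrix(0, n, 6), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two_sample_t reproduces the demographics-table p values", {
  # PSQI: pooled variance reproduces the printed order of magnitude;
  # Welch is orders of magnitude off, identifying pooled as the convention
  pooled <- two_sample_t(12.57, 3.93, 35, 2.26, 1.36, 35, tails = 1,
                         variance = "pooled")
  expect_identical(pooled$df, 68)
  expect_lt(abs(log10(pooled$p) - log10(4.52e-23)), 0.1)
  welch <- two_sample_t(12.57, 3.93, 35, 2.26, 1.36, 35, tails = 1,
                        variance = "welch")
  expect_gt(welch$p, 1e-20)

  age <- two_sample_t(39.3, 8.6, 35, 34.9, 10.7, 35, tails = 2)
  expect_equal(age$p, 0.067, tolerance = 0.1)

  same <- two_sample_t(5, 2, 20, 5, 2, 20, tails = 2)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  expect_error(two_sample_t(1, 1, 20, 0, 1, 20, tails = 3), "tails")
  expect_error(two_sample_t(1, 0, 20, 0, 1, 20), "positive")
})

test_that("chi_square_2x2 reproduces the gender-split p and matches a permutation null", {
  sex <- chi_square_2x2(5, 30, 9, 26)
  expect_equal(round(sex$p, 2), 0.23)
  prop <- chi_square_2x2(10, 20, 5, 10)
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")

  # permutation oracle: the uncorrected Pearson p approximates the
  # label-permutation mid-p (half the mass at the observed table)
  set.seed(14)
  a <- 30; b <- 25; c <- 20; d <- 35
  obs <- chi_square_2x2(a, b, c, d)
  grp <- rep(0:1, c(a + b, c + d))
  out <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  perm_chi <- replicate(10000, {
    g <- sample(grp)
    chi_square_2x2(sum(g == 0 & out == 1), sum(g == 0 & out == 0),
                   sum(g == 1 & out == 1), sum(g == 1 & out == 0))$chi2
  })
  p_perm <- mean(perm_chi > obs$chi2 + 1e-9) +
    0.5 * mean(abs(perm_chi - obs$chi2) < 1e-9)
  expect_lt(abs(p_perm - obs$p), 3 * sqrt(obs$p * (1 - obs$p) / 10000) + 0.01)
})

test_that("a focal group thickness offset survives cluster correction in most runs", {
  el <- mean(mesh_metrics(ico3)$edge_lengths)
  patch <- seed_patch(ico3, 50L, 18, "PATCH")$vertex_indices
  survived <- logical(20)
  for (i in 1:20) {
    spec <- simulation_spec(ico3, n_per_group = 35, a_age = -0.005,
                            seed_signal_sd = 0, noise_sd = 0.1,
                            noise_fwhm = 3 * el, rng_seed = 900L + i)
    coh <- sample_cohort(spec)
    ds <- generate_thickness(ico3, coh, spec)
    Y <- ds$thickness
    Y[coh$group == 1, patch] <- Y[coh$group == 1, patch] + 0.2
    gm <- thickness_group_map(Y, coh)
    sth <- estimate_smoothness(residuals(gm), ico3, exclude = gm$flagged,
                               n_effective = gm$df)
    tab <- cluster_fwe(gm, sth, ico3, 0.001, "positive")
    memb <- attr(tab, "members")
    sig <- which(tab$p_fwe < 0.05)
    survived[i] <- length(sig) > 0 &&
      any(vapply(sig, function(k) length(intersect(memb[[k]], patch)) > 0,
                 logical(1)))
  }
  expect_gte(mean(survived), 0.8)
})

test_that("null simulations keep vertex-wise type-I error near nominal", {
  set.seed(15)
  n <- 35
  frac_scn <- replicate(20, {
    Y <- matrix(rnorm(n * 200), n)
    sv <- rnorm(n)
    sm <- scn_map(Y, sv)
    mean(abs(sm$t) > qt(0.975, sm$df))
  })
  expect_lt(abs(mean(frac_scn) - 0.05), 0.01)

  frac_int <- replicate(20, {
    Y <- matrix(rnorm(2 * n * 150), 2 * n)
    sv <- rnorm(2 * n)
    g <- rep(0:1, each = n)
    im <- interaction_map(Y, sv, g, "group")
    mean(abs(im$t) > qt(0.975, im$df))
  })
  expect_lt(abs(mean(frac_int) - 0.05), 0.01)
})
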