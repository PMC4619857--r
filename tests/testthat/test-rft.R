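test_that("EC densities: definitional rho0, Gaussian limit, dual-transcription rho2 value", {
  expect_equal(ec_density_t(2.3, 17, 0), pt(2.3, 17, lower.tail = FALSE),
               tolerance = 1e-12)
  # frozen value from an independent beta-function transcription of the
  # 2-D t-field density at t = 3, df = 68
  expect_equal(ec_density_t(3, 68, 2), 8.179929743529e-03, tolerance = 1e-10)
  # large-df convergence to the Gaussian-field densities
  for (t in c(2, 3, 4.5)) {
    g1 <- sqrt(4 * log(2)) / (2 * pi) * exp(-t^2 / 2)
    g2 <- (4 * log(2)) / (2 * pi)^1.5 * t * exp(-t^2 / 2)
    expect_lt(abs(ec_density_t(t, 1e6, 1) - g1) / g1, 1e-3)
    expect_lt(abs(ec_density_t(t, 1e6, 2) - g2) / g2, 1e-3)
  }
  expect_error(ec_density_t(2, 10, 3), "surface")
  expect_error(ec_density_t(2, 0.5, 2), ">= 1")
})

test_that("smoothness estimation is scale equivariant and rejects degenerate fields", {
  set.seed(20)
  R <- matrix(rnorm(30 * nrow(ico2$vertices)), 30)
  Rs <- smooth_field(ico2, R, 10)
  s1 <- estimate_smoothness(Rs, ico2)
  big <- surface_mesh(ico2$vertices * 2, ico2$triangles)
  s2 <- estimate_smoothness(Rs, big)
  expect_equal(s2$fwhm, 2 * s1$fwhm, tolerance = 1e-9)
  expect_equal(s2$resels[3], s1$resels[3], tolerance = 1e-9)
  expect_identical(s1$resels[1], 2)
  expect_identical(s1$resels[2], 0)  # closed surface: no boundary resels
  expect_equal(s1$resels[3], sum(ico2$triangle_areas) / s1$fwhm^2,
               tolerance = 1e-9)

  const <- matrix(rep(rnorm(30), nrow(ico2$vertices)), 30)
  expect_error(estimate_smoothness(const, ico2), "roughness|constant")
  expect_error(estimate_smoothness(matrix(0, 30, nrow(ico2$vertices)), ico2),
               "degenerate")
})

test_that("smoothness estimation recovers the generator-imposed FWHM", {
  el <- mean(mesh_metrics(ico3)$edge_lengths)
  target <- 4 * el
  set.seed(21)
  est <- replicate(5, {
    E <- smooth_field(ico3, matrix(rnorm(30 * nrow(ico3$vertices)), 30), target)
    estimate_smoothness(E, ico3)$fwhm
  })
  expect_lt(abs(mean(est) - target) / target, 0.2)
})

test_that("peak FWE p-values are monotone, dominate uncorrected p, and respect resel ordering", {
  tgrid <- seq(-3, 8, by = 0.25)
  fake <- structure(list(t = tgrid, df = 40L,
                         flagged = rep(FALSE, length(tgrid))),
                    class = "statmap")
  smooth <- structure(list(fwhm = 10, resels = c(2, 0, 150)),
                      class = "smoothness_estimate")
  p <- peak_fwe(fake, smooth, "positive")
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  punc <- pt(tgrid, 40, lower.tail = FALSE)
  expect_true(all(p >= punc - 1e-12))
  # fewer resels (smoother field) never increases the corrected p
  smoother <- structure(list(fwhm = 20, resels = c(2, 0, 40)),
                        class = "smoothness_estimate")
  expect_true(all(peak_fwe(fake, smoother, "positive") <= p + 1e-12))
  # flagged infinite peaks get p = 0 in their tail
  fake$t[1] <- Inf; fake$flagged[1] <- TRUE
  expect_identical(peak_fwe(fake, smooth, "positive")[1], 0)
  expect_identical(peak_fwe(fake, smooth, "negative")[1], 1)
})

test_that("cluster extraction equals an independent flood-fill oracle", {
  set.seed(22)
  smooth <- estimate_smoothness(
    smooth_field(ico2, matrix(rnorm(20 * nrow(ico2$vertices)), 20), 15), ico2)
  for (rep in 1:100) {
    tv <- rnorm(nrow(ico2$vertices), sd = 2)
    fake <- structure(list(t = tv, df = 30L, contrast = "x",
                           flagged = rep(FALSE, length(tv))),
                      class = "statmap")
    tab <- cluster_fwe(fake, smooth, ico2, cluster_forming_p = 0.02,
                       tail = "positive")
    tc <- qt(0.98, 30)
    supra <- which(tv > tc)
    oracle <- flood_fill_oracle(ico2, supra)
    got <- normalize_components(attr(tab, "members"))
    expect_identical(got, oracle)
    expect_identical(sort(tab$n_vertices),
                     sort(vapply(oracle, length, integer(1))))
    # every reported peak is the component maximum and suprathreshold
    for (k in seq_len(nrow(tab)))
      expect_identical(tab$peak_t[k],
                       max(tv[attr(tab, "members")[[tab$cluster_id[k]]]]))
  }
})

test_that("cluster table: empty case, single-blob case, p_fwe in (0, 1], sorted", {
  smooth <- structure(list(fwhm = 12, resels = c(2, 0, 100)),
                      class = "smoothness_estimate")
  nv <- nrow(ico2$vertices)
  fake <- structure(list(t = rep(0, nv), df = 30L, contrast = "x",
                         flagged = rep(FALSE, nv)),
                    class = "statmap")
  tab <- cluster_fwe(fake, smooth, ico2, 0.001, "positive")
  expect_identical(nrow(tab), 0L)

  blob <- seed_patch(ico2, 7L, 20)$vertex_indices
  fake$t[blob] <- 10
  tab1 <- cluster_fwe(fake, smooth, ico2, 0.001, "positive")
  expect_identical(nrow(tab1), 1L)
  expect_identical(tab1$n_vertices, length(blob))
  expect_identical(sort(attr(tab1, "members")[[1]]), blob)
  expect_true(all(tab1$p_fwe > 0 & tab1$p_fwe <= 1))

  # several blobs: table sorted by p_fwe, ids renumbered
  fake$t[seed_patch(ico2, 120L, 8)$vertex_indices] <- 5
  tab2 <- cluster_fwe(fake, smooth, ico2, 0.001, "positive")
  expect_identical(tab2$cluster_id, seq_len(nrow(tab2)))
  expect_true(!is.unsorted(tab2$p_fwe))
  expect_error(cluster_fwe(fake, smooth, ico2, 1.5), "0, 1")
})

test_that("FWE calibration approaches nominal as smoothness grows relative to mesh spacing", {
  # at 8 mean-edge-lengths of smoothness the lattice samples the field
  # densely and the continuum EC approximation should be accurate
  mesh <- ico3
  el <- mean(mesh_metrics(mesh)$edge_lengths)
  fw <- 8 * el
  nv <- nrow(mesh$vertices)
  n <- 35
  set.seed(24)
  nsim <- 200
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    E <- smooth_field(mesh, matrix(rnorm(n * nv), n), fw)
    sm <- scn_map(E, rnorm(n))
    sth <- estimate_smoothness(residuals(sm), mesh, exclude = sm$flagged,
                               n_effective = sm$df)
    rej[i] <- min(peak_fwe(sm, sth, "positive")) < 0.05
  }
  # 0.05 +/- 3 binomial standard errors at 200 simulations
  expect_gte(mean(rej), 0.05 - 3 * sqrt(0.05 * 0.95 / nsim))
  expect_lte(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / nsim))
})

test_that("uncorrected masks are calibrated and tails are disjoint", {
  set.seed(23)
  n <- 40; nv <- 500
  frac <- replicate(20, {
    sm <- scn_map(matrix(rnorm(n * nv), n), rnorm(n))
    mean(uncorrected_mask(sm, 0.05, "positive"))
  })
  expect_lt(abs(mean(frac) - 0.05), 0.01)
  sm <- scn_map(matrix(rnorm(n * nv), n), rnorm(n))
  for (p in c(0.05, 0.2, 0.5)) {
    pos <- uncorrected_mask(sm, p, "positive")
    neg <- uncorrected_mask(sm, p, "negative")
    expect_identical(sum(pos & neg), 0L)
  }
  expect_true(all(uncorrected_mask(sm, 1, "positive") |
                  uncorrected_mask(sm, 1, "negative") |
                  sm$t == 0))
  expect_error(uncorrected_mask(sm, 0), "in \\(0, 1")
})
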