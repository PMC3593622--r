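test_that("whitening produces uncorrelated unit-variance rows", {
  set.seed(5)
  data <- matrix(rnorm(15 * 500), 15, 500)
  wh <- whiten(data, 5)
  cov_w <- tcrossprod(wh$whitened) / 500
  expect_equal(cov_w, diag(5), tolerance = 1e-8)
  # dewhitening reconstructs the dominant subspace of the row-centered data
  xc <- data - rowMeans(data)
  recon <- wh$dewhitening %*% wh$whitened
  # residual variance equals the discarded eigenvalues
  expect_lt(sum((xc - recon)^2), sum(xc^2))
  expect_equal(wh$whitening %*% wh$dewhitening, diag(5), tolerance = 1e-8)
})

test_that("whitening rejects rank-deficient data", {
  rank2 <- matrix(rnorm(2 * 100), 2, 100)
  data <- rbind(rank2, rank2[1, ] + rank2[2, ])
  expect_error(whiten(data, 3), "rank")
  expect_silent(whiten(data, 2))
})

test_that("symmetric decorrelation matches its eigen-decomposition oracle", {
  set.seed(11)
  for (i in 1:5) {
    W <- matrix(rnorm(25), 5, 5)
    R <- symmetric_decorrelation(W)
    expect_equal(tcrossprod(R), diag(5), tolerance = 1e-8)
    # closed-form oracle computed independently
    e <- eigen(W %*% t(W), symmetric = TRUE)
    oracle <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors) %*% W
    expect_equal(R, oracle, tolerance = 1e-8)
    # the iterative scheme agrees with the closed form
    expect_equal(symmetric_decorrelation(W, method = "iterative"), R,
                 tolerance = 1e-8)
  }
})

test_that("symmetric decorrelation is idempotent and removes scaling", {
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(symmetric_decorrelation(q), q, tolerance = 1e-10)
  expect_equal(symmetric_decorrelation(2 * diag(3)), diag(3), tolerance = 1e-10)
  W <- matrix(rnorm(25), 5, 5)
  f1 <- symmetric_decorrelation(W)
  expect_equal(symmetric_decorrelation(f1), f1, tolerance = 1e-10)
  expect_error(symmetric_decorrelation(matrix(0, 3, 3)), "singular")
})

test_that("fastica recovers independent Laplacian maps under identity mixing", {
  lap <- laplacian_mix()
  # t = n here, so voxel centering would cost a rank; whitening row-centers
  dec <- fastica(lap$data, ica_config(5, tolerance = 1e-6, seed = 2),
                 center_voxels = FALSE)
  m <- match_components(dec, lap$maps)
  expect_true(all(m$abs_r >= 0.99))
  expect_true(dec$converged)
})

test_that("a decomposition is self-consistent: X = W Yc, A = pinv(W)", {
  sub <- fix_subject()
  dec <- fastica(sub$series$data, ica_config(5, seed = 9))
  yc <- sweep(sub$series$data, 2, dec$voxel_means) - dec$row_means
  expect_lt(max(abs(dec$sources - dec$unmixing %*% yc)), 1e-6)
  pinv <- t(dec$unmixing) %*% solve(dec$unmixing %*% t(dec$unmixing))
  expect_equal(dec$mixing, pinv, tolerance = 1e-8)
  # rows of X standardized with non-negative skewness
  expect_equal(rowMeans(dec$sources), rep(0, 5), tolerance = 1e-10)
  expect_equal(rowMeans(dec$sources^2), rep(1, 5), tolerance = 1e-10)
  sk <- rowMeans(dec$sources^3)
  expect_true(all(sk >= -1e-8))
})

test_that("fastica is bitwise deterministic given data, config and seed", {
  sub <- fix_subject()
  d1 <- fastica(sub$series$data, ica_config(5, seed = 123))
  d2 <- fastica(sub$series$data, ica_config(5, seed = 123))
  expect_identical(d1$sources, d2$sources)
  expect_identical(d1$mixing, d2$mixing)
})

test_that("pure Gaussian sources do not raise", {
  set.seed(21)
  data <- matrix(rnorm(30 * 400), 30, 400)
  expect_no_error(dec <- fastica(data, ica_config(3, seed = 1,
                                                  max_iterations = 50)))
  expect_s3_class(dec, "ica_decomposition")
})

test_that("the localizer block exposes a task-locked component", {
  sub <- fix_subject()
  dec <- fastica(sub$series$data[1:60, ], ica_config(5, seed = 4))
  reg <- sub$truth$regressors[1:60, "RVMT"]
  best <- max(abs(apply(dec$mixing, 2, cor, y = reg)))
  expect_gte(best, 0.8)
})

test_that("course-seeded fits keep the prior component in the decomposition", {
  sub <- fix_subject(noise_sd = 0)
  w <- sub$series$data[101:115, ]
  a_n <- sub$truth$true_courses[101:115, "RVMT"]
  dec <- fastica(w, ica_config(5, tolerance = 1e-8, seed = 5),
                 init_courses = matrix(a_n, ncol = 1))
  # source dependence (blob maps overlap mildly) biases recovery slightly
  # away from the generating map, so the bound is a little below 1
  best <- max(abs(apply(dec$sources, 1, cor, y = sub$truth$true_maps["RVMT", ])))
  expect_gte(best, 0.98)
})

test_that("pseudo-projection reproduces least-squares amplitudes", {
  set.seed(31)
  v <- 300
  x1 <- standardize_test(rnorm(v)); x2 <- standardize_test(rnorm(v))
  # orthogonalize x2 against x1
  x2 <- standardize_test(x2 - sum(x2 * x1) / sum(x1^2) * x1)
  expect_equal(pseudo_project(2 * x1, x1), 2, tolerance = 1e-12)
  expect_equal(pseudo_project(x2, x1), 0, tolerance = 1e-12)
  e <- rnorm(v)
  e <- e - sum(e * x1) / sum(x1^2) * x1
  e <- e - sum(e * x2) / sum(x2^2) * x2
  y <- 3 * x1 - 1 * x2 + e
  expect_equal(pseudo_project(y, rbind(x1, x2)), c(3, -1), tolerance = 1e-8)
  # against an independent lm() oracle with correlated maps
  m1 <- rnorm(v); m2 <- 0.5 * m1 + rnorm(v)
  y2 <- rnorm(v)
  fit <- unname(coef(lm(y2 ~ 0 + m1 + m2)))
  expect_equal(pseudo_project(y2, rbind(m1, m2)), fit, tolerance = 1e-8)
  expect_error(pseudo_project(y2, rbind(m1, m1)), "degenerate")
})

test_that("pseudo-projection is linear in the volume", {
  set.seed(33)
  maps <- matrix(rnorm(3 * 200), 3, 200)
  y1 <- rnorm(200); y2 <- rnorm(200)
  lhs <- pseudo_project(2.5 * y1 - 4 * y2, maps)
  rhs <- 2.5 * pseudo_project(y1, maps) - 4 * pseudo_project(y2, maps)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("constrained extraction recovers a reference source present in the window", {
  lap <- laplacian_mix(n = 4, v = 1500, seed = 13)
  set.seed(14)
  courses <- matrix(rnorm(15 * 4), 15, 4)
  window <- courses %*% lap$maps
  ce <- constrained_extract(window, lap$maps[2, ], ica_config(4, seed = 3))
  expect_gte(cor(ce$map, lap$maps[2, ]), 0.99)
  expect_true(ce$converged)
  # at least as close to the reference as any unconstrained component
  dec <- fastica(window, ica_config(4, seed = 3))
  best_unconstrained <- max(abs(apply(dec$sources, 1, cor, y = lap$maps[2, ])))
  expect_gte(cor(ce$map, lap$maps[2, ]), best_unconstrained - 1e-6)
})

test_that("an infeasible spatial constraint is flagged, not raised", {
  lap <- laplacian_mix(n = 4, v = 1500, seed = 13)
  set.seed(15)
  courses <- matrix(rnorm(15 * 3), 15, 3)
  window <- courses %*% lap$maps[1:3, ]
  # make the reference exactly orthogonal to the span of the window's
  # source rows (plus the constant direction introduced by centering)
  ref <- unname(residuals(lm(lap$maps[4, ] ~ t(lap$maps[1:3, ]))))
  ce <- constrained_extract(window, ref, ica_config(3, seed = 3))
  expect_false(ce$converged)
  expect_length(ce$map, 1500)
})

test_that("constrained extraction is stable across seeds", {
  sub <- fix_subject()
  w <- sub$series$data[100:114, ]
  ref <- sub$truth$true_maps["RVMT", ]
  ce1 <- constrained_extract(w, ref, ica_config(5, seed = 1))
  ce2 <- constrained_extract(w, ref, ica_config(5, seed = 999))
  expect_gte(cor(ce1$map, ce2$map), 0.95)
})
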