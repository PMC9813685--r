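test_that("three-cosine synthesis matches the analytic Fourier series", {
  refl <- p_cosine_set(n = 16)
  g <- density_from_factors(refl)
  fr <- seq_len(16) / 16 - 1 / 16
  expected <- 2 * (outer(outer(cos(2 * pi * fr), rep(1, 16)), rep(1, 16)) +
                   outer(outer(rep(1, 16), cos(2 * pi * fr)), rep(1, 16)) +
                   outer(outer(rep(1, 16), rep(1, 16)), cos(2 * pi * fr)))
  expect_equal(g$values, expected, tolerance = 1e-12)
  expect_equal(which.max(g$values), 1L)     # maximum at the origin voxel
  expect_equal(mean(g$values), 0, tolerance = 1e-14)
})

test_that("synthesis-analysis round trip is the identity on H_obs", {
  cell <- unit_cell(10, grid = 16)
  set.seed(7)
  hkl <- rbind(c(1, 0, 0), c(0, 2, 1), c(-1, 1, 3), c(2, 2, -2), c(3, 1, 0))
  r <- reflection_set(cell, hkl, runif(5, 0.2, 2), runif(5, -3, 3))
  g <- density_from_factors(r)
  back <- factors_from_density(g, r$hkl)
  expect_equal(back$amplitude, r$amplitude, tolerance = 1e-10)
  expect_equal(back$phase, r$phase, tolerance = 1e-10)
})

test_that("pure cos(2 pi z) has only the (0,0,1) coefficient", {
  cell <- unit_cell(1, grid = 16)
  z <- rep((seq_len(16) - 1) / 16, each = 256)
  g <- density_grid(cell, cos(2 * pi * z))
  all_hkl <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -3:3))
  all_hkl <- all_hkl[rowSums(abs(all_hkl)) > 0, ]
  f <- factors_from_density(g, all_hkl)
  big <- f$amplitude > 1e-12
  expect_equal(unname(f$hkl[big, , drop = FALSE]),
               matrix(c(0L, 0L, 1L), 1))   # Friedel mate is implicit
  expect_equal(f$amplitude[big], 0.5)      # cos = (e^i + e^-i)/2
})

test_that("flipping scatters intensity outside H_obs", {
  refl <- p_cosine_set(n = 16)
  g <- density_from_factors(refl)
  flipped <- flip_modify(g, k_f = 1, t_plus = 2, t_minus = -2)
  # the pointwise flip is odd under the body-centring translation of the
  # cosine sum, so new intensity appears on odd index sums only
  out <- factors_from_density(flipped, rbind(c(2, 1, 0), c(1, 1, 1)))
  expect_true(any(out$amplitude > 1e-6))
  even <- factors_from_density(flipped, rbind(c(1, 1, 0), c(2, 0, 0)))
  expect_lt(max(even$amplitude), 1e-10)
})

test_that("Parseval holds over the Hermitian-expanded coefficient set", {
  cell <- unit_cell(10, grid = 16)
  set.seed(11)
  hkl <- rbind(c(1, 0, 0), c(0, 2, 1), c(-1, 1, 3))
  r <- reflection_set(cell, hkl, runif(3, 0.2, 2), runif(3, -3, 3))
  g <- density_from_factors(r)
  expect_equal(sum(g$values^2) / prod(cell$grid),
               2 * sum(r$amplitude^2), tolerance = 1e-10)
})

test_that("synthesis is linear in the amplitudes", {
  r <- p_cosine_set()
  r3 <- r; r3$amplitude <- 3 * r$amplitude
  expect_equal(density_from_factors(r3)$values,
               3 * density_from_factors(r)$values)
})

test_that("missing phases and aliased indices are rejected", {
  r <- p_cosine_set(n = 8)
  expect_error(density_from_factors(strip_phases(r)), "no phases")
  bad <- reflection_set(unit_cell(1, grid = 32), c(5, 0, 0), 1, 0)
  bad$cell$grid <- c(8L, 8L, 8L)             # force a too-coarse grid
  expect_error(density_from_factors(bad), "aliasing")
})

test_that("spectral Hessian matches analytic second derivatives", {
  cell <- unit_cell(1, grid = 16)
  x <- rep((seq_len(16) - 1) / 16, times = 256)
  g <- density_grid(cell, cos(2 * pi * x))
  H <- hessian_fields(g)
  expect_equal(H$xx$values, array(-4 * pi^2 * cos(2 * pi * x), dim = g$cell$grid),
               tolerance = 1e-10)
  for (nm in c("yy", "zz", "xy", "xz", "yz"))
    expect_lt(max(abs(H[[nm]]$values)), 1e-10)

  # constant grid: all six fields vanish
  H0 <- hessian_fields(density_grid(cell, rep(0, 16^3)))
  expect_true(all(vapply(H0, function(h) max(abs(h$values)) < 1e-12, TRUE)))
})

test_that("P-nodal Hessian is diagonal with cosine entries", {
  refl <- p_cosine_set(n = 16)        # density 2(cos X + cos Y + cos Z)
  g <- density_from_factors(refl)
  H <- hessian_fields(g)
  fr <- (seq_len(16) - 1) / 16
  cx <- -4 * pi^2 * 2 * cos(2 * pi * fr)
  expect_equal(H$xx$values[, 1, 1], cx, tolerance = 1e-10)
  expect_equal(H$yy$values[1, , 1], cx, tolerance = 1e-10)
  expect_equal(H$zz$values[1, 1, ], cx, tolerance = 1e-10)
  expect_lt(max(abs(H$xy$values)), 1e-10)
})

test_that("Hessian cell scaling enters as 1/a^2", {
  r1 <- p_cosine_set(n = 8, a = 1)
  r2 <- p_cosine_set(n = 8, a = 10)
  H1 <- hessian_fields(density_from_factors(r1))
  H2 <- hessian_fields(density_from_factors(r2))
  expect_equal(H2$xx$values, H1$xx$values / 100, tolerance = 1e-10)
})
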