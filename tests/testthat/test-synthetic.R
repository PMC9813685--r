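test_that("nodal densities are zero-mean with the requested side fraction", {
  cell <- unit_cell(10)
  for (surf in c("P", "G", "D")) {
    g <- nodal_density(surf, cell, 0.4, "type_I", softness = 0)
    expect_equal(mean(g$values), 0, tolerance = 1e-12)
    # type I: the high-density (positive) region is the TPMS side.  The
    # threshold excludes whole tie plateaus of the symmetric nodal grid,
    # so the achieved fraction can sit a plateau short of the request.
    expect_lt(abs(mean(g$values > 0) - 0.4), 0.02)
    g2 <- nodal_density(surf, cell, 0.4, "type_II", softness = 0)
    expect_lt(abs(mean(g2$values > 0) - 0.6), 0.02)
  }
})

test_that("the labyrinth partition thresholds at the nodal level", {
  # the P nodal value distribution is symmetric, so a half-volume
  # labyrinth corresponds to the zero level set
  cell <- unit_cell(10)
  g <- nodal_density("P", cell, 0.5, "type_I", softness = 0,
                     partition = "labyrinth")
  fr <- (seq_len(32) - 1) / 32
  f <- outer(outer(cos(2 * pi * fr), cos(2 * pi * fr), `+`),
             cos(2 * pi * fr), `+`)
  # away from the (tie-broken) zero plateau the split is the sign of f
  clear <- abs(f) > 1e-6
  expect_equal(unname(g$values[clear] > 0), unname(f[clear] > 0))
})

test_that("surface-partition G and P densities are centrosymmetric", {
  for (surf in c("P", "G")) {
    g <- nodal_density(surf, unit_cell(10), 0.6, "type_II", softness = 1)
    v <- g$values
    idx <- c(1, 32:2)
    expect_equal(v, v[idx, idx, idx], tolerance = 1e-12)
  }
})

test_that("impossible volume fractions are rejected", {
  cell <- unit_cell(10)
  expect_error(nodal_density("P", cell, 1e-7), "volume fraction")
  expect_error(nodal_density("P", cell, 0.5, softness = -1), "softness")
})

test_that("blob fields are reproducible and demeaned", {
  cell <- unit_cell(10, grid = 16)
  b1 <- blob_density(cell, 4, 2, seed = 3)
  b2 <- blob_density(cell, 4, 2, seed = 3)
  expect_identical(b1$values, b2$values)
  expect_equal(mean(b1$values), 0, tolerance = 1e-12)
  expect_false(identical(b1$values, blob_density(cell, 4, 2, seed = 4)$values))
})

test_that("a pure cosine sum yields exactly the {100} family", {
  cell <- unit_cell(10)
  fr <- (seq_len(32) - 1) / 32
  f <- outer(outer(cos(2 * pi * fr), cos(2 * pi * fr), `+`),
             cos(2 * pi * fr), `+`)
  dr <- derive_reflections(density_grid(cell, f), d_min = 5)
  expect_equal(n_reflections(dr$truth), 3L)
  expect_true(all(rowSums(dr$truth$hkl^2) == 1))
  expect_equal(dr$truth$amplitude, rep(0.5, 3), tolerance = 1e-12)
  expect_null(dr$observed$phase)
  expect_error(derive_reflections(density_grid(cell, f), d_min = 20),
               "largest available")
})

test_that("derived truth reproduces the band-limited density", {
  den <- get_bench("g_mid")$density
  dr <- derive_reflections(den, d_min = 3.0)    # complete shell, no floor
  synth <- density_from_factors(dr$truth)
  # band-limit the input to the same index sphere by round trip
  full <- derive_reflections(den, d_min = 3.0, amp_floor = 0)
  band <- density_from_factors(full$truth)
  expect_gt(stats::cor(as.vector(synth$values), as.vector(band$values)),
            0.99)
})

test_that("amplitude noise perturbs only the observed view", {
  den <- get_bench("g_mid")$density
  clean <- derive_reflections(den, 3.0, amp_floor = 0.02)
  noisy <- derive_reflections(den, 3.0, amp_floor = 0.02,
                              amp_noise = 0.1, seed = 5)
  expect_identical(noisy$truth$amplitude, clean$truth$amplitude)
  expect_false(identical(noisy$observed$amplitude,
                         clean$observed$amplitude))
  # mean-one noise: amplitudes stay in the right ballpark
  ratio <- noisy$observed$amplitude / clean$observed$amplitude
  expect_true(all(ratio > 0.5 & ratio < 2))
  again <- derive_reflections(den, 3.0, amp_floor = 0.02,
                              amp_noise = 0.1, seed = 5)
  expect_identical(again$observed$amplitude, noisy$observed$amplitude)
})

test_that("benchmarks are deterministic and in the documented regimes", {
  for (nm in c("p_small", "g_mid", "d_mid", "blob_control")) {
    b1 <- make_benchmark(nm)
    b2 <- make_benchmark(nm)
    expect_identical(b1$truth$amplitude, b2$truth$amplitude)
    expect_identical(b1$density$values, b2$density$values)
    m <- n_reflections(b1$observed)
    expect_gte(m, 7L); expect_lte(m, 50L)
    expect_null(b1$observed$phase)
    expect_false(is.null(b1$truth$phase))
  }
  expect_lte(n_reflections(make_benchmark("p_small")$observed), 12L)
  expect_equal(n_reflections(make_benchmark("g_mid")$observed), 18L)
  expect_error(make_benchmark("nonesuch"))
})

test_that("p_small is centrosymmetric with truth phases in {0, pi}", {
  b <- get_bench("p_small")
  expect_true(all(abs(sin(b$truth$phase)) < 1e-10))
})
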