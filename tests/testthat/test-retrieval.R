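test_that("a wide-threshold iteration is the identity on phases", {
  # thresholds beyond the density range leave the map untouched, so the
  # recomputed factors equal the input factors
  refl <- p_cosine_set(n = 16)
  out <- flip_iterate(refl, k_f = 0, k_t = 50)
  expect_equal(out$refl$phase, refl$phase, tolerance = 1e-10)
  expect_equal(out$refl$amplitude, refl$amplitude)
  expect_equal(out$i_rho, i_rho(density_from_factors(refl)))
})

test_that("an all-zero amplitude set is a silent fixed point", {
  cell <- unit_cell(10, grid = 8)
  refl <- reflection_set(cell, rbind(c(1, 0, 0), c(0, 1, 1)), c(0, 0),
                         c(0.3, -1.2))
  out <- flip_iterate(refl, k_f = 1, k_t = 0.8)
  expect_equal(out$i_rho, 0)
  expect_equal(out$refl$phase, refl$phase)
})

test_that("retrieval is deterministic in the seed", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 30, kf = c(0.5, 0.5, 17),
                       kt = c(0.75, 0.25, 13))
  f1 <- charge_flip(b$observed, ctrl, seed = 3)
  f2 <- charge_flip(b$observed, ctrl, seed = 3)
  expect_identical(f1$phases, f2$phases)
  expect_identical(f1$trace, f2$trace)
  f3 <- charge_flip(b$observed, ctrl, seed = 4)
  expect_false(identical(f1$trace$i_rho, f3$trace$i_rho))
})

test_that("the reported best is the earliest trace minimum", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 40, kf = c(0.5, 0.5, 17),
                       kt = c(0.75, 0.25, 13))
  fit <- charge_flip(b$observed, ctrl, seed = 9)
  expect_equal(fit$i_rho, min(fit$trace$i_rho))
  expect_equal(fit$iteration, fit$trace$iteration[which.min(fit$trace$i_rho)])
  expect_equal(nrow(fit$trace), 40L)
  # the stored density belongs to the stored phases
  expect_equal(i_rho(fit$density), fit$i_rho)
  expect_equal(density_from_factors(fitted_phases(fit))$values,
               fit$density$values, tolerance = 1e-12)
})

test_that("a single-iteration run returns its only iterate", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 1, kf = c(0.5, 0.5, 17),
                       kt = c(0.75, 0.25, 13))
  fit <- charge_flip(b$observed, ctrl, seed = 2)
  expect_equal(fit$iteration, 0L)
  expect_equal(nrow(fit$trace), 1L)
})

test_that("real-F runs keep phases in {0, pi} throughout", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 25, kf = c(0.25, 0.25, 17),
                       kt = c(0.6, 0.4, 13), real_f = TRUE)
  state <- init_phases(b$observed, seed = 6, real_f = TRUE)
  for (j in 0:24) {
    out <- flip_iterate(state, schedule_value(ctrl$kf, j),
                        schedule_value(ctrl$kt, j), real_f = TRUE)
    state <- out$refl
    expect_true(all(state$phase %in% c(0, pi)))
  }
})

test_that("retrieval is scale covariant", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 20, kf = c(0.5, 0.5, 17),
                       kt = c(0.75, 0.25, 13))
  f1 <- charge_flip(b$observed, ctrl, seed = 8)
  scaled <- b$observed
  scaled$amplitude <- scaled$amplitude * 100
  f2 <- charge_flip(scaled, ctrl, seed = 8)
  expect_equal(f2$trace$i_rho, 100 * f1$trace$i_rho, tolerance = 1e-10)
  expect_equal(f2$phases, f1$phases, tolerance = 1e-10)
})

test_that("multi-run driver is sorted, seeded and reproducible", {
  b <- get_bench("p_small")
  ctrl <- flip_control(iterations = 15, kf = c(0.5, 0.5, 17),
                       kt = c(0.75, 0.25, 13))
  one <- charge_flip_runs(b$observed, ctrl, runs = 1, seed = 5)
  expect_length(one$results, 1L)
  many <- charge_flip_runs(b$observed, ctrl, runs = 5, seed = 5)
  ir <- vapply(many$results, `[[`, 0, "i_rho")
  expect_true(all(diff(ir) >= 0))
  expect_setequal(vapply(many$results, `[[`, 0L, "seed"), 5:9)
  again <- charge_flip_runs(b$observed, ctrl, runs = 5, seed = 5)
  expect_identical(vapply(again$results, `[[`, 0, "i_rho"), ir)
})

test_that("mismatched schedule periods are flagged", {
  expect_warning(flip_control(kf = c(0.5, 0.5, 19), kt = c(0.75, 0.25, 19)),
                 "share a period")
})

test_that("sign enumeration counts and deduplicates Babinet twins", {
  refl <- strip_phases(p_cosine_set(n = 16))
  sr <- exhaustive_sign_search(refl, compute_ik = FALSE)
  expect_equal(nrow(sr$signs), 4L)             # 2^(m-1), first sign fixed
  expect_true(all(sr$signs[, 1] == 1L))
  full <- exhaustive_sign_search(refl, fix_first = FALSE, compute_ik = FALSE)
  expect_equal(nrow(full$signs), 8L)
  # every assignment and its global inversion give the same I_rho
  key <- apply(full$signs, 1, paste, collapse = "")
  inv_key <- apply(-full$signs, 1, paste, collapse = "")
  expect_equal(full$i_rho[match(inv_key, key)], full$i_rho, tolerance = 1e-12)
  expect_error(exhaustive_sign_search(refl, max_bits = 2), "max_bits")
})

test_that("the three-cosine sign problem is shift-degenerate", {
  # flipping any cosine sign is a half-cell translation, so all sign
  # assignments are equivalent: equal I_rho and R_p = 0 to the truth
  refl <- p_cosine_set(n = 16)
  sr <- exhaustive_sign_search(strip_phases(refl), compute_ik = FALSE)
  expect_equal(diff(range(sr$i_rho)), 0, tolerance = 1e-10)
  worst <- set_phases(strip_phases(refl),
                      ifelse(sr$signs[nrow(sr$signs), ] > 0, 0, pi))
  expect_lt(r_p(worst, refl)$r_p, 1e-12)
})

test_that("enumeration reports I_K alongside I_rho when asked", {
  b <- get_bench("p_small")
  small <- reflection_set(b$observed$cell, b$observed$hkl[1:4, ],
                          b$observed$amplitude[1:4])
  sr <- exhaustive_sign_search(small, compute_ik = TRUE)
  expect_length(sr$i_k, 8L)
  expect_true(all(is.finite(sr$i_k)))
  expect_true(all(sr$i_k >= 0 & sr$i_k <= 1))
  expect_true(all(diff(sr$i_rho) >= 0))
})
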