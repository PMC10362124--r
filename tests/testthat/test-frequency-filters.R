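test_that("distance map is the centred |di|^n3 + |dj|^n3 grid", {
  g <- distance_map(8, 8, n3 = 2)
  expect_equal(g$m1, 4L)
  expect_equal(g$n1_half, 4L)
  expect_equal(g$D[5, 5], 0)          # centre, 0-based (4, 4)
  expect_equal(g$D[5, 6], 1)          # one step right of centre
  expect_equal(g$D[1, 1], 32)         # corner: 16 + 16
  expect_equal(sum(g$D == 0), 1L)     # exactly one zero
  expect_true(all(g$D >= 0))
  expect_equal(g$d0, 0.05 * 4)        # default reference distance
  # odd n3 still yields a nonnegative distance
  g3 <- distance_map(9, 7, n3 = 3)
  expect_true(all(g3$D >= 0))
  expect_error(distance_map(8, 8, n3 = 0), "n3")
})

test_that("chebyshev_cosh matches the recurrence-evaluated polynomial T_N", {
  expect_equal(chebyshev_cosh(5, 1), 1)       # acosh(1) = 0
  expect_equal(chebyshev_cosh(1, 0.5), 0.5)   # identity at order 1
  expect_equal(chebyshev_cosh(3, 2), 26)      # T_3(2) = 4*8 - 6
  u <- seq(0, 3, length.out = 301)
  for (N in 1:5) {
    expect_lt(max(abs(chebyshev_cosh(N, u) - ref_chebyshev_T(N, u))), 1e-9)
  }
  expect_error(chebyshev_cosh(2, -0.1), "nonnegative")
  expect_error(chebyshev_cosh(0, 1), "order")
})

test_that("cosh-acosh transfer matches its closed form and limits", {
  h <- w <- 32
  grid <- distance_map(h, w, d0 = 9)  # offset (3, 0) from centre has D = 9
  for (eps in c(0.5, 1, 2)) {
    H <- cosh_acosh_transfer(h, w, cosh_acosh_params(eps = eps), grid)
    expect_equal(H[17, 20], 1 / (1 + eps^2))  # D = D0 -> CNx = 1
    expect_true(all(H > 0 & H <= 1))
  }
  # eps = 0 is the all-pass
  H0 <- cosh_acosh_transfer(h, w, cosh_acosh_params(eps = 0), grid)
  expect_equal(unclass(H0), matrix(1, h, w), ignore_attr = TRUE)
  # DC region is suppressed
  H <- cosh_acosh_transfer(h, w, cosh_acosh_params(), grid)
  expect_lt(H[17, 17], 1e-12)
  # rotation symmetry about the centre
  expect_equal(strip_mat(H), rotate180_centered(H))
})

test_that("sech-asech transfer matches its closed form and limits", {
  h <- w <- 64
  grid <- distance_map(h, w, d0 = 4)
  for (eps in c(0.5, 1)) {
    H <- sech_asech_transfer(h, w, sech_asech_params(eps = eps), grid)
    expect_equal(H[33, 35], 1 / (1 + eps^2))  # offset (0, 2): D = 4 = D0
    expect_true(all(H > 0 & H <= 1))
    expect_equal(strip_mat(H), rotate180_centered(H))
  }
  # far from the centre (u -> 0) high frequencies pass: H -> 1
  H <- sech_asech_transfer(h, w, sech_asech_params(lam = 4, nn = 24), grid)
  expect_gt(H[1, 1], 0.999)
  H0 <- sech_asech_transfer(h, w, sech_asech_params(eps = 0), grid)
  expect_equal(unclass(H0), matrix(1, h, w), ignore_attr = TRUE)
})

test_that("sech-asech radial profile ripples inside D < D0", {
  d0 <- 6.4
  D <- seq(d0 * 1e-3, d0, length.out = 400)
  prof <- transfer_radial_profile(sech_asech_params(lam = 3, nn = 2, eps = 1),
                                  D, d0)
  expect_gte(n_derivative_sign_changes(prof$H), 2L)
  # the cosh branch (D <= D0) of the cosh-acosh transfer is monotone
  prof_c <- transfer_radial_profile(cosh_acosh_params(order = 4), D, d0)
  expect_equal(n_derivative_sign_changes(prof_c$H), 0L)
  expect_true(all(diff(prof_c$H) >= 0))  # gain rises towards the cutoff
})

test_that("frequency application is the shifted pointwise spectral product", {
  img <- random_image(16, 12, seed = 31)
  # all-pass identity
  out <- apply_frequency_filter(img, transfer_function_identity(16, 12))
  expect_lt(max(abs(out - img)), 1e-10)
  # annihilator
  H0 <- matrix(0, 16, 12)
  expect_equal(max(abs(apply_frequency_filter(img, H0))), 0)
  # DC-only indicator extracts the mean
  Hdc <- matrix(0, 16, 12); Hdc[9, 7] <- 1  # centre at (floor(h/2), floor(w/2))
  out_dc <- apply_frequency_filter(img, Hdc)
  expect_lt(max(abs(out_dc - mean(img))), 1e-10)
  # linearity
  A <- random_image(16, 12, seed = 32)
  B <- random_image(16, 12, seed = 33)
  H <- unclass(cosh_acosh_transfer(16, 12, cosh_acosh_params()))
  lhs <- apply_frequency_filter(gray_image(2 * unclass(A) + 3 * unclass(B)), H)
  rhs <- 2 * apply_frequency_filter(A, H) + 3 * apply_frequency_filter(B, H)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # shape mismatch
  expect_error(apply_frequency_filter(img, matrix(1, 8, 8)), "shape")
})

test_that("eps = 0 reproduces the input end to end for both filters", {
  img <- random_image(33, 48, seed = 41)  # odd height on purpose
  out_c <- cosh_acosh_filter(img, cosh_acosh_params(eps = 0))
  out_s <- sech_asech_filter(img, sech_asech_params(eps = 0))
  expect_lt(max(abs(out_c - img)), 1e-8)
  expect_lt(max(abs(out_s - img)), 1e-8)
})

test_that("random parameter draws keep both transfers bounded, symmetric, real", {
  img <- random_image(24, 24, seed = 51)
  withr::with_seed(52, {
    for (k in 1:10) {
      pc <- cosh_acosh_params(order = runif(1, 0.5, 8), n5 = runif(1, 0.1, 3),
                              n4 = runif(1, 0.5, 3), eps = runif(1, 0.1, 3))
      ps <- sech_asech_params(lam = runif(1, 0.5, 8), nn = runif(1, 0.5, 40),
                              eps = runif(1, 0.1, 3))
      for (H in list(cosh_acosh_transfer(24, 24, pc),
                     sech_asech_transfer(24, 24, ps))) {
        expect_true(all(H > 0 & H <= 1))
        expect_equal(strip_mat(H), rotate180_centered(H))
        expect_true(all(is.finite(apply_frequency_filter(img, H))))
      }
    }
  })
})

test_that("transfer functions export as float TIFF grids", {
  H <- cosh_acosh_transfer(16, 16, cosh_acosh_params())
  f <- withr::local_tempfile(fileext = ".tiff")
  save_transfer_function(H, f)
  expect_lt(max(abs(tiff::readTIFF(f) - unclass(H))), 1e-6)
})
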