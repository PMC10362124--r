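test_that("exp filter evaluates its closed form", {
  # tt = b collapses the exponent, any n2
  img <- gray_image(matrix(0.3, 4, 4))
  for (n2 in c(1L, 2L, 9L)) {
    out <- exp_filter(img, exp_params(a = 2.5, q = 3, b = 0.3, n2 = n2))
    expect_equal(as.vector(out), rep(2.5, 16))
  }
  # direct scalar evaluation
  img <- gray_image(matrix(0.2, 3, 3))
  out <- exp_filter(img, exp_params(a = 1, q = 2, b = 0.5, n2 = 2L, c = 1))
  expect_equal(out[1, 1], exp(-0.18))
})

test_that("pointwise filters agree with a per-pixel scalar reference loop", {
  img <- random_image(16, 16, seed = 21)
  cases <- list(
    list(a = 1, q = 2, b = 0.5, n2 = 8L, c = 1),
    list(a = 0.7, q = 5, b = 0.2, n2 = 3L, c = 0.4)
  )
  for (p in cases) {
    got <- exp_filter(img, do.call(exp_params, p))
    want <- ref_exp_filter(unclass(img), p$a, p$q, p$b, p$n2, p$c)
    expect_lt(max(abs(got - want)), 1e-12)
  }
  scases <- list(
    list(eta = 1, a1 = 1, a2 = 0.1, a3 = 2, a4 = 1),
    list(eta = 0.5, a1 = 2, a2 = -0.3, a3 = 1.5, a4 = 0.7)
  )
  for (p in scases) {
    got <- sinh_asinh_r_filter(img, do.call(sinh_asinh_params, p))
    want <- ref_sinh_filter(unclass(img), p$eta, p$a1, p$a2, p$a3, p$a4)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("even-n2 exp output is a band selector: bounded by a, peak at tt = b", {
  img <- random_image(16, 16, seed = 3)
  img[5, 5] <- 0.5  # ensure the band centre is attained
  out <- exp_filter(img, exp_params(a = 1.3, q = 2, b = 0.5, n2 = 8L))
  expect_true(all(out > 0))
  expect_true(all(out <= 1.3 + 1e-15))
  expect_equal(max(out), 1.3)
  # the global maximum a is attained where tt = b (ties only from pixels so
  # close to b that the 8th power underflows)
  argmax <- which(unclass(out) == max(out))
  expect_true(which(unclass(img) == 0.5) %in% argmax)
  expect_true(all(abs(unclass(img)[argmax] - 0.5) < 0.01))
})

test_that("odd n2 brightens relative to the adjacent even n2 (parity claim)", {
  ph <- make_shapes_phantom(128, 128, seed = 1)
  for (pair in list(c(8L, 9L), c(28L, 29L))) {
    m_even <- mean_brightness(exp_filter(ph$image, exp_params(n2 = pair[1])))
    m_odd <- mean_brightness(exp_filter(ph$image, exp_params(n2 = pair[2])))
    expect_gt(m_odd, m_even)
  }
})

test_that("exp output is pointwise non-increasing in q for even n2", {
  img <- random_image(12, 12, seed = 9)
  u2 <- exp_filter(img, exp_params(q = 2, n2 = 8L))
  u3 <- exp_filter(img, exp_params(q = 3, n2 = 8L))
  expect_true(all(u3 <= u2))
  # strictly decreasing wherever the 8th power is above double round-off
  off_centre <- abs(unclass(img) - 0.5) > 0.1
  expect_true(any(off_centre))
  expect_true(all(u3[off_centre] < u2[off_centre]))
})

test_that("overflowing exponents saturate with a warning instead of Inf/NaN", {
  img <- gray_image(matrix(c(-500, 0.5, 0.2), 3, 3))
  expect_warning(
    out <- exp_filter(img, exp_params(b = 0.5, n2 = 3L, q = 2)),
    "saturated"
  )
  expect_true(all(is.finite(out)))
  expect_equal(max(out), .Machine$double.xmax)
})

test_that("paper_loop leaves the literal border untouched", {
  img <- random_image(10, 12, seed = 5)
  out <- exp_filter(img, exp_params(), paper_loop = TRUE)
  full <- exp_filter(img, exp_params())
  expect_equal(out[3:9, 3:11], full[3:9, 3:11])
  expect_equal(out[c(1, 2, 10), ], img[c(1, 2, 10), ])
  expect_equal(out[, c(1, 2, 12)], img[, c(1, 2, 12)])
})

test_that("sinh-asinh-r filter evaluates its composition", {
  img <- gray_image(matrix(0, 3, 3))
  out <- sinh_asinh_r_filter(img, sinh_asinh_params(a2 = 0.7, a3 = 2))
  expect_equal(as.vector(out), rep(0, 9))  # r = 0 annihilates the product

  img1 <- gray_image(matrix(1, 3, 3))
  out1 <- sinh_asinh_r_filter(img1,
                              sinh_asinh_params(eta = 1, a1 = 1, a2 = 0,
                                                a3 = 1, a4 = 1))
  expect_equal(as.vector(out1), rep(1, 9))  # sinh(asinh(1)) = 1

  img2 <- gray_image(matrix(0.3, 3, 3))
  out2 <- sinh_asinh_r_filter(img2,
                              sinh_asinh_params(eta = 0.5, a1 = 2, a2 = 0.1,
                                                a3 = 2, a4 = 1))
  expect_equal(out2[1, 1], sinh(2 * asinh(0.7) * 0.36))

  # negative intensities with fractional a3 stay real (sign-preserving power)
  img3 <- gray_image(matrix(-0.3, 3, 3))
  out3 <- sinh_asinh_r_filter(img3,
                              sinh_asinh_params(a1 = 1, a2 = 0, a3 = 2.5,
                                                a4 = 0.5))
  expect_true(all(is.finite(out3)))
  expect_equal(out3[1, 1],
               {
                 z <- sinh(asinh(-0.3) * (-(0.3^2.5)))
                 sign(z) * abs(z)^0.5
               })
})

test_that("pointwise filters are permutation-equivariant", {
  img <- random_image(8, 8, seed = 14)
  perm <- withr::with_seed(15, sample(64))
  shuffled <- gray_image(matrix(as.vector(img)[perm], 8, 8))
  for (f in list(function(x) exp_filter(x, exp_params()),
                 function(x) sinh_asinh_r_filter(x, sinh_asinh_params()))) {
    expect_equal(as.vector(f(shuffled)), as.vector(f(img))[perm])
  }
})

test_that("parameter records validate and round-trip through lists", {
  expect_error(exp_params(n2 = 2.5), "positive integer")
  expect_error(exp_params(n2 = 0), "positive integer")
  expect_error(exp_params(c = 0), "non-zero")
  expect_error(exp_params(q = -1), "> 0")
  expect_error(sinh_asinh_params(eta = 0), "non-zero")
  expect_error(sinh_asinh_params(a3 = 0), "> 0")
  expect_error(filter_params_from_list("exp", list(bogus = 1)), "bogus")
  expect_error(filter_params_from_list("watershed"), "unknown filter")

  p <- filter_params_from_list("exp", list(q = 7, n2 = 9))
  expect_s3_class(p, "exp_params")
  expect_equal(p$q, 7)
  expect_equal(p$n2, 9L)
  expect_equal(p$b, 0.5)  # untouched default

  # YAML round-trip of a config block keyed by filter name
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(sech_asech = list(lam = 3, nn = 2, eps = 1)), f)
  blk <- yaml::read_yaml(f)
  p2 <- filter_params_from_list("sech_asech", blk$sech_asech)
  expect_equal(p2$lam, 3)
  expect_equal(p2$nn, 2)
})
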