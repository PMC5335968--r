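test_that("Volterra expansion has the documented dimension and order", {
  expect_length(volterra_expand(rnorm(10), 5, 2), 9)  # 3 linear + 6 products
  expect_equal(volterra_expand(rep(0, 10), 5, 2), rep(0, 9))
  expect_equal(volterra_expand(c(1, 2), 2, 0), c(2, 4))
  # explicit order for memory = 1: a(i), a(i-1), a(i)^2, a(i)a(i-1), a(i-1)^2
  expect_equal(volterra_expand(c(3, 5), 2, 1), c(5, 3, 25, 15, 9))
  # history before the first sample is zero-padded
  expect_equal(volterra_expand(c(7, 1), 1, 1), c(7, 0, 49, 0, 0))
})

test_that("reference shifting delays by the configured lag", {
  a <- 1:20
  expect_equal(shift_reference(a, 0.08, 125), c(rep(0, 10), 1:10))
  expect_equal(shift_reference(a, 2 / 125, 125), c(0, 0, 1:18))
  expect_equal(shift_reference(a, 2 / 125, 125, lead = FALSE),
               c(3:20, 0, 0))
  expect_equal(shift_reference(a, 0, 125), a)
})

test_that("RLS is the identity when the reference is silent", {
  set.seed(5)
  x <- rnorm(300)
  out <- rls_denoise(x, rep(0, 300), pp_config())
  expect_equal(out$s_hat, x)
  expect_equal(out$D, 77L)  # memory 10: 11 linear + 66 quadratic terms
})

test_that("recursive coefficients match the explicit weighted least-squares
          solution on small instances", {
  cfg <- pp_config(memory = 1L, lambda = 1, init_diag = 1e8)
  for (seed in 1:5) {
    set.seed(seed)
    M <- 50
    a <- rnorm(M)
    x <- 0.8 * a + 0.3 * c(0, a[-M]) + 0.2 * a^2 + 0.01 * rnorm(M)
    res <- rls_denoise(x, a, cfg)
    Phi <- t(vapply(seq_len(M), function(i) volterra_expand(a, i, 1L),
                    numeric(5)))
    w_ls <- solve(crossprod(Phi), crossprod(Phi, x))
    expect_equal(res$w, as.numeric(w_ls), tolerance = 1e-6)
    expect_equal(res$s_hat[M], x[M] - sum(w_ls * Phi[M, ]),
                 tolerance = 1e-6)
  }
})

test_that("RLS converges on purely linear noise and spares the pulse tone", {
  set.seed(6)
  fs <- 125
  a <- make_tone(2.1, n = 1000, fs = fs) + 0.1 * rnorm(1000)
  x <- 0.5 * a
  cfg <- pp_config(memory = 0L, lambda = 0.999)
  s_hat <- rls_denoise(x, a, cfg)$s_hat
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(rms(s_hat[501:1000]), 0.05 * rms(x))

  pulse <- make_tone(1.7, n = 1000, fs = fs)
  x2 <- pulse + 1.5 * a + 0.5 * a^2
  s2 <- rls_denoise(x2, a, pp_config())$s_hat
  amp_at <- function(sig, f) {
    sp <- periodogram_spectrum(sig, fs, 4096)
    b <- hz_to_bin(f, fs, 4096)
    max(sp$amp[(b - 1):(b + 1)])
  }
  expect_gt(amp_at(s2, 1.7), 0.5 * amp_at(pulse, 1.7))
})

test_that("non-finite inputs raise a numeric error", {
  expect_error(rls_denoise(c(1, NA, 3), rep(1, 3), pp_config()), "finite")
})
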