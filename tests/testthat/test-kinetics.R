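test_that("total density is the pointwise sum of the four cell types", {
  st <- make_state(P = matrix(0.1, 2, 2), I = matrix(0.2, 2, 2),
                   B = matrix(0.5, 2, 2), N = matrix(0, 2, 2))
  expect_equal(total_density(st), matrix(0.8, 2, 2))
  zero <- make_state(P = matrix(0, 3, 3))
  expect_equal(total_density(zero), matrix(0, 3, 3))

  withr::with_seed(42, {
    f <- function() matrix(runif(12), 3, 4)
    st <- make_state(P = f(), I = f(), B = f(), N = f())
  })
  # brute-force per-cell loop oracle
  want <- st$P
  for (r in 1:3) for (cc in 1:4) {
    want[r, cc] <- st$P[r, cc] + st$I[r, cc] + st$B[r, cc] + st$N[r, cc]
  }
  expect_equal(total_density(st), want)

  bad <- make_state(P = matrix(0, 2, 2))
  bad$I <- matrix(0, 3, 3)
  expect_error(total_density(bad), "shape")
})

test_that("hypoxic state is a clamped linear function of total density", {
  p <- gbm_params()
  expect_equal(hypoxic_state(matrix(0, 2, 2), p), matrix(0, 2, 2))
  expect_equal(hypoxic_state(matrix(p$c_ref, 1, 1), p), matrix(1, 1, 1))
  expect_equal(hypoxic_state(matrix(2 * p$c_ref, 1, 1), p), matrix(1, 1, 1))
  expect_equal(hypoxic_state(matrix(0.5 * p$c_ref, 1, 1), p),
               matrix(0.5, 1, 1))
  # monotone in C
  C <- matrix(seq(0, 2, length.out = 11), 1)
  expect_true(all(diff(as.vector(hypoxic_state(C, p))) >= 0))
  p_bad <- unclass(p); p_bad$c_ref <- -1
  expect_error(hypoxic_state(matrix(0.5, 1, 1), p_bad), "c_ref")
})

test_that("rate functions hit their endpoint values and stated examples", {
  th <- matrix(0.5, 1, 1); tl <- matrix(0.9, 1, 1)

  p <- gbm_params(m_max = 1, mitosis_form = "banded")
  expect_equal(mitotic_coefficient(matrix(0, 1, 1), th, tl, p)[1], 1)
  expect_equal(mitotic_coefficient(tl, th, tl, p)[1], 0)
  expect_equal(mitotic_coefficient(matrix(0.7, 1, 1), th, tl, p)[1], 0.5)

  p_sat <- gbm_params(m_max = 1, mitosis_form = "saturating")
  expect_equal(mitotic_coefficient(matrix(0, 1, 1), th, tl, p_sat)[1], 1)
  expect_equal(mitotic_coefficient(matrix(1, 1, 1), th, tl, p_sat)[1], 0)
  expect_gt(mitotic_coefficient(tl, th, tl, p_sat)[1], 0)

  expect_error(mitotic_coefficient(matrix(0.5, 1, 1), tl, th, p),
               "ordering")

  p_mu <- gbm_params(mu_max = 0.2, death_form = "gradual")
  tl8 <- matrix(0.8, 1, 1)
  expect_equal(necrotic_rate(matrix(0.5, 1, 1), tl8, p_mu)[1], 0)
  expect_equal(necrotic_rate(matrix(1, 1, 1), tl8, p_mu)[1], 0.2)
  expect_equal(necrotic_rate(matrix(0.9, 1, 1), tl8, p_mu)[1], 0.1)

  p_st <- gbm_params(mu_max = 2, lethal_width = 0.02)
  expect_equal(necrotic_rate(matrix(0.85, 1, 1), matrix(0.85, 1, 1), p_st)[1], 0)
  expect_equal(necrotic_rate(matrix(0.87, 1, 1), matrix(0.85, 1, 1), p_st)[1], 2)
  expect_equal(necrotic_rate(matrix(1, 1, 1), matrix(0.85, 1, 1), p_st)[1], 2)

  p_pi <- gbm_params(beta_pi = 0.4)
  th6 <- matrix(0.6, 1, 1)
  expect_equal(switch_rate_pi(matrix(0, 1, 1), th6, p_pi)[1], 0)
  expect_equal(switch_rate_pi(matrix(1, 1, 1), th6, p_pi)[1], 0.4)
  expect_equal(switch_rate_pi(matrix(0.8, 1, 1), th6, p_pi)[1], 0.2)

  p_ip <- gbm_params(beta_ip = 0.3)
  th5 <- matrix(0.5, 1, 1)
  expect_equal(switch_rate_ip(matrix(0, 1, 1), th5, tl, p_ip)[1], 0.3)
  expect_equal(switch_rate_ip(matrix(0.95, 1, 1), th5, tl, p_ip)[1], 0)
  expect_equal(switch_rate_ip(matrix(0.7, 1, 1), th5, tl, p_ip)[1], 0.15)
})

test_that("piecewise rate functions are continuous across both thresholds", {
  p <- gbm_params()
  th <- matrix(p$tau_h0, 1, 1); tl <- matrix(p$tau_l0, 1, 1)
  eps <- 1e-9
  near <- function(f, at) {
    lo <- f(matrix(at - eps, 1, 1))
    hi <- f(matrix(at + eps, 1, 1))
    abs(hi - lo)
  }
  fns <- list(
    function(H) mitotic_coefficient(H, th, tl, p),
    function(H) necrotic_rate(H, tl, p),
    function(H) switch_rate_pi(H, th, p),
    function(H) switch_rate_ip(H, th, tl, p)
  )
  for (f in fns) {
    expect_lt(near(f, p$tau_h0), 1e-6)
    expect_lt(near(f, p$tau_l0), 1e-6)
  }
})

test_that("threshold dynamics follow the angiogenic Euler step and AA reset", {
  p <- gbm_params(alpha = 1, tau_h0 = 0.7, tau_l0 = 0.85,
                  tau_h_cap = 0.9, tau_l_cap = 0.97, dt = 0.1)
  st <- make_state(P = matrix(0, 2, 2))
  unchanged <- update_thresholds(st, p, aa_active = FALSE)
  expect_equal(unchanged$tau_h, st$tau_h)   # no P, no angiogenesis
  expect_equal(unchanged$tau_l, st$tau_l)

  st2 <- make_state(P = matrix(0.5, 1, 1))
  up <- update_thresholds(st2, p, aa_active = FALSE, dt = 0.1)
  expect_equal(up$tau_h[1], 0.7 + 0.1 * 1 * 0.5 * (0.9 - 0.7))   # 0.71
  expect_equal(up$tau_l[1], 0.85 + 0.1 * 1 * 0.5 * (0.97 - 0.85))

  # AA with infinite relaxation resets in one call
  st3 <- make_state(P = matrix(0.5, 1, 1), tau_h = 0.88, tau_l = 0.95)
  back <- update_thresholds(st3, p, aa_active = TRUE)
  expect_equal(back$tau_h[1], 0.7)
  expect_equal(back$tau_l[1], 0.85)

  # finite relaxation moves towards baseline without overshooting
  p_slow <- gbm_params(relax_rate = 2, dt = 0.1)
  part <- update_thresholds(st3, p_slow, aa_active = TRUE)
  expect_true(part$tau_h[1] < 0.88 && part$tau_h[1] > 0.7)

  # ordering tau_h < tau_l survives repeated random updates
  withr::with_seed(7, {
    st4 <- make_state(P = matrix(runif(16), 4, 4))
    for (k in 1:50) {
      st4 <- update_thresholds(st4, p, aa_active = (k %% 7 == 0))
      expect_true(all(st4$tau_h < st4$tau_l))
    }
  })
})

test_that("reaction step matches a scalar Euler oracle and conserves mass", {
  p <- gbm_params(m_max = 1, mu_max = 0.3, beta_pi = 0.2, beta_ip = 0.25,
                  dt = 0.1)
  # single forced Euler step: pure mitosis
  st <- make_state(P = matrix(0.1, 1, 1))
  out <- reaction_step(st, p, dt = 0.1)
  expect_equal(out$P[1], 0.11)

  # randomized single-cell states vs the independent scalar oracle
  withr::with_seed(11, {
    for (k in 1:25) {
      v <- runif(4, 0, 0.45)
      st <- make_state(P = matrix(v[1], 1, 1), I = matrix(v[2], 1, 1),
                       B = matrix(v[3], 1, 1), N = matrix(v[4], 1, 1))
      got <- reaction_step(st, p, dt = 0.1)
      want <- scalar_reaction_oracle(v[1], v[2], v[3], v[4],
                                     0.7, 0.85, p, 0.1)
      expect_equal(c(got$P[1], got$I[1], got$B[1], got$N[1]),
                   unname(want), tolerance = 1e-12)
    }
  })

  # with mitosis off, switching and death conserve total mass exactly
  p0 <- gbm_params(m_max = 0, mu_max = 0.4, beta_pi = 0.3, beta_ip = 0.3)
  withr::with_seed(3, {
    st <- make_state(P = matrix(runif(25, 0, 0.5), 5, 5),
                     I = matrix(runif(25, 0, 0.5), 5, 5),
                     B = matrix(runif(25, 0, 0.5), 5, 5))
  })
  m0 <- sum(total_density(st))
  for (k in 1:200) st <- reaction_step(st, p0)
  expect_equal(sum(total_density(st)), m0, tolerance = 1e-13)
  expect_true(all(st$P >= 0 & st$I >= 0 & st$B >= 0 & st$N >= 0))
})

test_that("necrotic mass never decreases and outflow capping warns", {
  p <- gbm_params()
  withr::with_seed(5, {
    st <- make_state(P = matrix(runif(16, 0, 0.6), 4, 4),
                     I = matrix(runif(16, 0, 0.3), 4, 4),
                     B = matrix(0.5, 4, 4))
  })
  n_prev <- sum(st$N)
  for (k in 1:100) {
    st <- reaction_step(st, p)
    expect_gte(sum(st$N), n_prev - 1e-14)
    n_prev <- sum(st$N)
  }

  # dt far too large for the configured rates: capped, warned, non-negative
  p_big <- gbm_params(mu_max = 30, dt = 0.1)
  st <- make_state(P = matrix(0.4, 1, 1), B = matrix(0.61, 1, 1))
  expect_warning(out <- reaction_step(st, p_big), "capped")
  expect_true(all(out$P >= 0 & out$B >= 0))
  expect_equal(sum(total_density(out)), 0.4 + 0.61, tolerance = 1e-13)
})

test_that("normoxic uniform growth follows the exact exponential closed form", {
  p <- gbm_params(m_max = 0.1, dt = 0.1)
  st <- make_state(P = matrix(0.01, 3, 3))
  n <- 40
  for (k in seq_len(n)) st <- reaction_step(st, p)
  expect_equal(st$P, matrix(0.01 * (1 + 0.1 * 0.1)^n, 3, 3),
               tolerance = 1e-12)
})
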