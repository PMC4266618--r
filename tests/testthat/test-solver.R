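test_that("diffusion field reflects white matter and excludes dead tissue", {
  p <- gbm_params(d0 = 0.1, kappa_wm = 5)
  dom <- open_domain(3)
  dom$wm[1, 1] <- 1
  st <- make_state(P = matrix(0, 3, 3), B = dom$b_init)
  D <- diffusion_field(dom, st, p)
  expect_equal(D[1, 1], 0.5)          # w = 1 -> kappa * d0
  expect_equal(D[2, 2], 0.1)          # w = 0 -> d0
  # a cell whose brain density fell to 5% of initial (>= 90% dead)
  st$B[3, 3] <- 0.05 * dom$b_init[3, 3]
  D <- diffusion_field(dom, st, p)
  expect_equal(D[3, 3], 0)
})

test_that("passive diffusion reproduces the 3-cell toy and conserves mass", {
  dom <- open_domain(1, 3)
  I <- matrix(c(0, 1, 0), 1, 3)
  D <- matrix(1, 1, 3)
  out <- passive_diffusion_step(I, D, dom, dt = 0.1)  # dt*D/h^2 = 0.1
  expect_equal(out, matrix(c(0.1, 0.8, 0.1), 1, 3))

  # uniform field is a fixed point
  u <- matrix(0.3, 1, 3)
  expect_equal(passive_diffusion_step(u, D, dom, dt = 0.1), u)

  # conservation and oracle equivalence on random 5x5 fields with a mask
  withr::with_seed(21, {
    for (k in 1:10) {
      dom5 <- disc_domain(5, radius = 2.6)
      I5 <- matrix(runif(25), 5, 5) * dom5$mask
      D5 <- matrix(runif(25, 0, 0.5), 5, 5)
      open <- dom5$mask
      got <- passive_diffusion_step(I5, D5, dom5, dt = 0.3, open = open)
      want <- scalar_diffusion_oracle(I5, D5, open, dt = 0.3, h = 1)
      expect_equal(got[open], want[open], tolerance = 1e-12)
      expect_equal(sum(got[open]), sum(I5[open]), tolerance = 1e-10)
      expect_true(all(got[open] >= -1e-15))
    }
  })

  expect_error(passive_diffusion_step(I, 10 * D, dom, dt = 0.1), "CFL")
})

test_that("active transport reproduces the 2-cell toy and conserves mass", {
  dom <- open_domain(1, 2)
  p <- gbm_params(gamma = 0.2)
  I <- matrix(c(1, 0), 1, 2)
  B <- matrix(c(0, 1), 1, 2)
  out <- active_transport_step(I, B, dom, p, dt = 1)  # gamma*dB*dt/h^2 = 0.2
  expect_equal(out, matrix(c(0.8, 0.2), 1, 2))

  # uniform B -> no gradient -> no movement
  expect_equal(active_transport_step(I, matrix(0.5, 1, 2), dom, p, dt = 1), I)

  withr::with_seed(33, {
    for (k in 1:10) {
      dom5 <- disc_domain(5, radius = 2.6)
      I5 <- matrix(runif(25), 5, 5) * dom5$mask
      B5 <- matrix(runif(25, 0, 0.5), 5, 5)
      p5 <- gbm_params(gamma = 0.4)
      got <- active_transport_step(I5, B5, dom5, p5, dt = 0.2,
                                   open = dom5$mask)
      want <- scalar_advection_oracle(I5, B5, dom5$mask, gamma = 0.4,
                                      dt = 0.2, h = 1)
      expect_equal(got[dom5$mask], want[dom5$mask], tolerance = 1e-12)
      expect_equal(sum(got[dom5$mask]), sum(I5[dom5$mask]),
                   tolerance = 1e-10)
    }
  })

  expect_error(
    active_transport_step(I, B, dom, gbm_params(gamma = 20), dt = 1),
    "CFL"
  )
})

test_that("upwind advection moves a pulse up a healthy-brain ramp", {
  dom <- open_domain(1, 20)
  p <- gbm_params(gamma = 1)
  B <- matrix(seq(0, 0.5, length.out = 20), 1, 20)
  I <- matrix(0, 1, 20); I[1, 5] <- 1
  com0 <- sum(seq_len(20) * I) / sum(I)
  for (k in 1:30) I <- active_transport_step(I, B, dom, p, dt = 0.5)
  com <- sum(seq_len(20) * I) / sum(I)
  expect_gt(com, com0)          # displaced towards higher B
  expect_equal(sum(I), 1, tolerance = 1e-10)
  expect_true(all(I >= 0))
})

test_that("stable_dt takes the binding stability bound", {
  p <- gbm_params(gamma = 0, dt = 0.5)
  expect_equal(stable_dt(p, d_max = 0, grad_b_max = 0, h = 1), 0.5)
  expect_equal(stable_dt(p, d_max = 1, grad_b_max = 1, h = 1), 0.225)
  p2 <- gbm_params(gamma = 2, dt = 100)
  withr::with_seed(9, {
    for (k in 1:20) {
      d <- runif(1, 0, 2); g <- runif(1, 0, 2); h <- runif(1, 0.5, 2)
      got <- stable_dt(p2, d, g, h)
      if (d > 0) expect_lte(got, h^2 / (4 * d) + 1e-12)
      if (g > 0) expect_lte(got, h / (2 * g) + 1e-12)
      expect_lte(got, 100)
    }
  })
})

test_that("a full solver step composes the operators in the documented order", {
  dom <- disc_domain(7, radius = 3.2)
  p <- gbm_params(d0 = 0.05, gamma = 0.5)
  st <- seed_tumor(dom, p)
  st$P[4, 4] <- 0.4; st$I[4, 4] <- 0.2   # make transport non-trivial
  got <- simulate_step(st, dom, p, make_schedule("full"), step_index = 0)

  want <- reaction_step(st, p)
  want <- update_thresholds(want, p, aa_active = FALSE)
  open <- dom$mask & !necrotic_region(want, dom, p)
  want$I <- active_transport_step(want$I, want$B, dom, p, p$dt, open = open)
  D <- p$d0 * (1 + dom$wm * (p$kappa_wm - 1)); D[!open] <- 0
  want$I <- passive_diffusion_step(want$I, D, dom, p$dt, open = open)
  for (f in c("P", "I", "B", "N", "tau_h", "tau_l")) {
    expect_equal(got[[f]], want[[f]], tolerance = 1e-14)
  }

  # with transport off the step reduces to the reaction-threshold update
  p0 <- gbm_params(d0 = 0, gamma = 0)
  st0 <- seed_tumor(dom, p0)
  got0 <- simulate_step(st0, dom, p0, make_schedule("full"), 0)
  want0 <- update_thresholds(reaction_step(st0, p0), p0, aa_active = FALSE)
  expect_equal(got0$P, want0$P)
  expect_equal(got0$I, want0$I)
})

test_that("total density is conserved through full steps with mitosis off", {
  dom <- disc_domain(9, radius = 4)
  p <- gbm_params(m_max = 0, mu_max = 0, d0 = 0.05, gamma = 0.5)
  st <- seed_tumor(dom, p)
  m0 <- sum(total_density(st))
  for (k in 1:50) st <- simulate_step(st, dom, p, make_schedule("full"), k - 1)
  expect_equal(sum(total_density(st)), m0, tolerance = 1e-10)
})

test_that("run_simulation records seeding, is deterministic, handles 0 steps", {
  dom <- disc_domain(15, radius = 6)
  p <- gbm_params()
  sim0 <- run_simulation(dom, p, make_schedule("full"), n_steps = 0)
  expect_equal(nrow(sim0$series), 1L)
  expect_equal(sim0$series$P_mass[1], p$p_seed * dom$h^2)
  expect_equal(sim0$series$I_mass[1], p$i_seed * dom$h^2)

  a <- run_simulation(dom, p, make_schedule("full"), 60, record_every = 20)
  b <- run_simulation(dom, p, make_schedule("full"), 60, record_every = 20)
  expect_identical(a$series, b$series)   # bit-identical observables
  expect_true(all(a$final$I >= 0) && all(a$final$P >= 0))
})

test_that("symmetric brain with centred seed stays symmetric", {
  n <- 33
  dom <- disc_domain(n, radius = 14)
  p <- gbm_params(d0 = 0.05, gamma = 1, m_max = 0.3)
  sim <- run_simulation(dom, p, make_schedule("full"), 150,
                        record_every = 150)
  rot90 <- function(m) t(m)[, nrow(m):1]
  for (f in c("P", "I", "B", "N")) {
    m <- sim$final[[f]]
    expect_lt(max(abs(m - rot90(m))), 1e-8)            # 90-degree rotation
    expect_lt(max(abs(m - m[n:1, ])), 1e-8)            # mirror
  }
})
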