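# Kinetic simulators: priming rate, calcium decay, P_r recursion, resting
# states, train simulation and recovery protocols.

test_that("priming rate reproduces rest, half-saturation and the asymptote", {
  expect_equal(priming_rate(50, 0.3, sigma = 10, k_half = 2), 0.3)
  # elevation equal to K0.5: (rest + sigma*K)/2
  expect_equal(priming_rate(50 + 2000, 0.3, sigma = 10, k_half = 2),
               (0.3 + 10 * 2) / 2)
  # far above K0.5 the rate approaches sigma * k_half
  lim <- priming_rate(50 + 1e4 * 2 * 1000, 0.3, sigma = 10, k_half = 2)
  expect_lt(abs(lim / (10 * 2) - 1), 1e-3)
  # monotone increasing in ca
  ca <- seq(50, 5000, length.out = 50)
  expect_true(all(diff(priming_rate(ca, 0.3, 10, 2)) > 0))
  expect_error(priming_rate(100, 0.3, sigma = 10, k_half = -1), "k_half")
  expect_error(priming_rate(100, 0.3, sigma = -5, k_half = 2), "sigma")
})

test_that("calcium decay follows the closed exponential form", {
  dyn <- calcium_dynamics(ca_rest = 50, delta_ca_ap = 150, k_ca = 20)
  expect_equal(ca_after(500, 0, dyn), 500)
  expect_equal(ca_after(50, 3.7, dyn), 50)
  expect_equal(ca_after(1050, 1 / 20, dyn), 50 + 1000 / exp(1))
  expect_error(ca_after(500, -1, dyn), "dt")
})

test_that("P_r recursion matches the scalar hand computation", {
  prot <- gen_regular_protocol(5, 500)
  # first AP always pr1; disabled dynamics give a constant sequence
  ps <- pr_sequence(prot, pr_dynamics(pr1 = 0.37))
  expect_equal(ps$pr, rep(0.37, 5))
  # facilitation-only recursion with negligible relaxation: P2 = p1 * 1.5^4.5
  dyn <- pr_dynamics(pr1 = 0.1, y_inc1 = 0.5, y_max = 2, k_y = 1e-9, k_z = 1)
  ps <- suppressWarnings(pr_sequence(prot, dyn))  # product form can exceed 1
  expect_equal(ps$pr[1], 0.1)
  expect_equal(ps$pr[2], 0.1 * 1.5^4.5, tolerance = 1e-4)
  # independent scalar recursion over the full sequence
  y <- 1
  expected <- numeric(5)
  for (j in 1:5) {
    expected[j] <- 0.1 * y^4.5
    y <- y + 0.5 * (2 - y)
    y <- 1 + (y - 1) * exp(-1e-9 * 0.002)
  }
  expect_equal(ps$pr, pmin(expected, 1), tolerance = 1e-12)
  # clipping warns when the product form can exceed 1
  expect_warning(pr_sequence(prot, pr_dynamics(0.9, y_inc1 = 0.9, y_max = 2,
                                               k_y = 1, k_z = 1)),
                 "clip")
})

test_that("analytic resting states match long-time ODE integration", {
  ca <- static_calcium()
  # symmetric single pool: half occupancy
  p <- single_pool_params(1000, kf_rest = 0.2, sigma = 5, k_half = 2, kb = 0.2)
  expect_equal(resting_state(p, ca)$occupancy[["n_o"]], 500)
  # irreversible two-step chain: everything tightly docked
  p2 <- two_step_params(900, k1_rest = 1, sigma1 = 0, k1_half = 1, b1 = 0,
                        k2_rest = 1, sigma2 = 0, k2_half = 1, b2 = 0)
  expect_equal(resting_state(p2, ca)$occupancy[["ts"]], 900)
  # arbitrary rates: oracle = integrate the ODEs from empty for >> max tau
  p3 <- two_step_params(2000, k1_rest = 0.8, sigma1 = 0, k1_half = 1, b1 = 0.3,
                        k2_rest = 1.7, sigma2 = 0, k2_half = 1, b2 = 0.9)
  analytic <- resting_state(p3, ca)$occupancy
  start <- model_state(c(es = 2000, ls = 0, ts = 0))
  long <- evolve_state(start, 500, p3, ca, static_pr(0.1))$occupancy
  expect_equal(unname(long / analytic), rep(1, 3), tolerance = 1e-6)
  # single pool equally
  an1 <- resting_state(p, ca)$occupancy
  lg1 <- evolve_state(model_state(c(n_e = 1000, n_o = 0)), 200, p, ca,
                      static_pr(0.1))$occupancy
  expect_equal(unname(lg1 / an1), c(1, 1), tolerance = 1e-6)
})

test_that("pure depletion trains follow the geometric closed form", {
  tr <- geom_depletion_train(pr = 0.2, pool = 1000, n_stim = 50)
  expect_equal(tr$amplitude_nA, geom_amplitudes(0.2, 1000, 50),
               tolerance = 1e-12)
  expect_equal(tr$m_j * attr(tr, "q"), tr$amplitude_nA)
})

test_that("site counts are conserved by both simulators", {
  cfg <- demo_single_pool()
  tr <- simulate_train(gen_regular_protocol(50, 500), cfg$params, cfg$calcium,
                       cfg$pr_dyn)
  expect_lt(max_conservation_error(tr, cfg$params$n_total),
            1e-6 * cfg$params$n_total)
  cfg2 <- demo_two_step()
  tr2 <- simulate_train(gen_regular_protocol(50, 500), cfg2$params,
                        cfg2$calcium, cfg2$pr_dyn)
  expect_lt(max_conservation_error(tr2, cfg2$params$n_total),
            1e-6 * cfg2$params$n_total)
})

test_that("effective calcium in the trajectory matches the superposition closed form", {
  cfg <- demo_single_pool()
  prot <- gen_regular_protocol(20, 500)
  tr <- simulate_train(prot, cfg$params, cfg$calcium, cfg$pr_dyn)
  traj <- attr(tr, "trajectory")
  pre <- traj[traj$phase == "pre", ]
  t_ap <- prot$ap_time_s
  expected <- vapply(seq_along(t_ap), function(j) {
    if (j == 1) return(cfg$calcium$ca_rest)
    cfg$calcium$ca_rest + sum(cfg$calcium$delta_ca_ap *
                                exp(-cfg$calcium$k_ca * (t_ap[j] - t_ap[seq_len(j - 1)])))
  }, 0)
  expect_equal(pre$ca_nM, expected, tolerance = 1e-9)
})

test_that("stochastic release has the right binomial mean at a single AP", {
  pool <- 2532; pr <- 0.165
  params <- single_pool_params(n_total = pool, kf_rest = 0, sigma = 0,
                               k_half = 1, kb = 0)
  prot <- gen_regular_protocol(1, 500)
  m1 <- vapply(seq_len(2000), function(i) {
    simulate_train(prot, params, static_calcium(), static_pr(pr),
                   mode = "stochastic", seed = 5000 + i,
                   init_state = model_state(c(n_e = 0, n_o = pool)))$m_j[1]
  }, 0)
  se <- sqrt(pool * pr * (1 - pr)) / sqrt(2000)
  expect_lt(abs(mean(m1) - pool * pr), 3 * se)
})

test_that("stochastic means track the deterministic train at every stimulus", {
  cfg <- demo_single_pool()
  prot <- gen_regular_protocol(15, 500)
  det <- simulate_train(prot, cfg$params, cfg$calcium, cfg$pr_dyn)
  n_rep <- 1000
  m <- vapply(seq_len(n_rep), function(i) {
    simulate_train(prot, cfg$params, cfg$calcium, cfg$pr_dyn,
                   mode = "stochastic", seed = i)$m_j
  }, numeric(15))
  mu <- rowMeans(m)
  se <- apply(m, 1, sd) / sqrt(n_rep)
  expect_true(all(abs(mu - det$m_j) <= 3 * se + 0.5))  # 0.5 covers pool rounding
})

test_that("a very large tight->loose backward rate empties the TS pool", {
  p <- two_step_params(1000, k1_rest = 1, sigma1 = 10, k1_half = 2, b1 = 0.5,
                       k2_rest = 1, sigma2 = 10, k2_half = 2, b2 = 1e5)
  st <- resting_state(p, static_calcium())
  expect_lt(st$occupancy[["ts"]] / 1000, 1e-3)
})

test_that("recovery curves interpolate between full depression and full recovery", {
  cfg <- demo_single_pool()
  cond <- gen_regular_protocol(40, 500)
  test <- gen_regular_protocol(5, 500)
  rec <- recovery_curve(cfg$params, cfg$calcium, cfg$pr_dyn, cond,
                        intervals = c(0.002, 0.02, 0.1, 1, 1000), test)
  # infinite interval: back to the resting response
  expect_equal(rec$points$epsc_test1[5], rec$cond_epsc1, tolerance = 1e-3)
  # interval equal to the conditioning ISI: the test train continues the
  # conditioning steady state seamlessly
  last_cond <- tail(rec$cond_train$amplitude_nA, 1)
  expect_equal(rec$points$epsc_test1[1], last_cond, tolerance = 0.02)
  expect_error(recovery_curve(cfg$params, cfg$calcium, cfg$pr_dyn, cond,
                              intervals = c(-1), test),
               "> 0")
})

test_that("recovery is monotone in the interval for a static-P_r single pool", {
  params <- single_pool_params(2000, kf_rest = 0.3, sigma = 10, k_half = 2,
                               kb = 0.1, q = 0.01)
  rec <- recovery_curve(params, calcium_dynamics(50, 150, 20), static_pr(0.2),
                        gen_regular_protocol(30, 500),
                        intervals = recovery_intervals(20),
                        gen_regular_protocol(2, 500))
  expect_true(all(diff(rec$points$epsc_test1) >= -1e-9))
})

test_that("simulation guards reject bad input", {
  cfg <- demo_single_pool()
  expect_error(stim_protocol(numeric(0)), "non-empty")
  expect_error(stim_protocol(c(0, 0.1, 0.1)), "increasing")
  expect_error(simulate_train(gen_regular_protocol(3, 100), cfg$params,
                              cfg$calcium, cfg$pr_dyn, mode = "stochastic"),
               "seed")
})
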