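# Shared fixtures, all generated in code.

# calcium/pr settings with every dynamic switched off
static_calcium <- function() calcium_dynamics(ca_rest = 50, delta_ca_ap = 0, k_ca = 20)
static_pr <- function(pr1) pr_dynamics(pr1 = pr1)

# pure geometric depletion train: replenishment and P_r dynamics off,
# explicit initial pool, q in nA/SV
geom_depletion_train <- function(pr, pool, n_stim = 40, rate_hz = 500, q = 1) {
  params <- single_pool_params(n_total = pool, kf_rest = 0, sigma = 0,
                               k_half = 1, kb = 0, q = q)
  simulate_train(gen_regular_protocol(n_stim, rate_hz), params,
                 static_calcium(), static_pr(pr),
                 init_state = model_state(c(n_e = 0, n_o = pool)))
}

# closed-form geometric depletion amplitudes
geom_amplitudes <- function(pr, pool, n_stim, q = 1) {
  q * pr * pool * (1 - pr)^(seq_len(n_stim) - 1)
}

# a full-featured single-pool configuration (all dynamics on)
demo_single_pool <- function() {
  list(params = single_pool_params(n_total = 2500, kf_rest = 0.25, sigma = 15,
                                   k_half = 2, kb = 0.12, q = 0.012),
       calcium = calcium_dynamics(50, 150, 20),
       pr_dyn = pr_dynamics(0.1, y_inc1 = 0.035, y_max = 2, z_dec1 = 0.04,
                            z_min = 0.4, k_y = 40, k_z = 2))
}

demo_two_step <- function() {
  list(params = two_step_params(n_total = 2000, k1_rest = 0.6, sigma1 = 20,
                                k1_half = 2, b1 = 0.5, k2_rest = 1.2,
                                sigma2 = 300, k2_half = 0.3, b2 = 2, q = 0.012),
       calcium = calcium_dynamics(50, 150, 20),
       pr_dyn = pr_dynamics(0.2, y_inc1 = 0.035, y_max = 2, z_dec1 = 0.04,
                            z_min = 0.4, k_y = 40, k_z = 2))
}

# trajectory conservation check: max |sum(occupancy) - n_total|
max_conservation_error <- function(train, n_total) {
  traj <- attr(train, "trajectory")
  occ_cols <- setdiff(names(traj), c("t_s", "ca_nM", "y", "z", "phase"))
  max(abs(rowSums(traj[occ_cols]) - n_total))
}

# noiseless Boltzmann EPSC-like trace (negative-going), 100 kHz sampling
boltzmann_trace <- function(A = 1, t50 = 1, k = 0.1, t_end = 3, dt = 0.01,
                            shift = 0) {
  t <- seq(0, t_end, by = dt)
  tibble::tibble(time_ms = t + shift,
                 current_nA = -A / (1 + exp((t50 - t) / k)))
}
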