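#' Shipped model calibrations for the Rac1 deletion study conditions
#'
#' Default parameter sets for the two kinetic schemes, calibrated against the
#' qualitative behaviour of mature calyx of Held synapses with and without
#' presynaptic Rac1: larger first-EPSC amplitude and loss of 500 Hz
#' paired-pulse facilitation after Rac1 deletion, a larger 50 Hz steady state,
#' a similar 500 Hz steady state, and bi-phasic recovery after pool-depleting
#' 500 Hz trains. The hard anchors are the published operating points: for the
#' single-pool scheme a release probability of 0.08 (control) vs 0.165
#' (knockout) with resting occupied pools of 2150 vs 2532 vesicles; for the
#' two-step scheme a shared release probability and total site count with 691
#' (control) vs 1666 (knockout) tightly docked vesicles at rest. Rate
#' constants are derived from those anchors so the resting states hold exactly
#' by construction; effective-calcium and P_r dynamics are shared between
#' genotypes. All remaining values are calibration products of this package,
#' not measurements.
#'
#' @param model `"single_pool"` or `"two_step"`.
#' @param genotype `"control"` (Rac1 present) or `"mutant"` (Rac1 deleted).
#' @return A list with `model`, `params`, `calcium`, `pr_dyn`.
#' @examples
#' cfg <- rac1_calibration("single_pool", "control")
#' resting_state(cfg$params, cfg$calcium)$occupancy[["n_o"]]  # 2150
#' @export
rac1_calibration <- function(model = c("single_pool", "two_step"),
                             genotype = c("control", "mutant")) {
  model <- match.arg(model)
  genotype <- match.arg(genotype)
  q <- 0.012  # nA per SV; mEPSC amplitude is genotype-independent
  calcium <- calcium_dynamics(ca_rest = 50, delta_ca_ap = 150, k_ca = 20)

  pr_common <- list(y_inc1 = 0.035, y_max = 2, z_dec1 = 0.04, z_min = 0.4,
                    k_y = 40, k_z = 2)

  if (model == "single_pool") {
    pr_dyn <- do.call(pr_dynamics,
                      c(list(pr1 = if (genotype == "control") 0.08 else 0.165),
                        pr_common))
    n_total <- 3000
    if (genotype == "control") {
      pool <- 2150; rate_sum <- 1 / 2.7  # resting priming equilibration rate
      sigma <- 10; k_half <- 4
    } else {
      pool <- 2532; rate_sum <- 1 / 2.3
      sigma <- 28; k_half <- 0.7
    }
    kf_rest <- rate_sum * pool / n_total
    params <- single_pool_params(n_total = n_total, kf_rest = kf_rest,
                                 sigma = sigma, k_half = k_half,
                                 kb = rate_sum - kf_rest, q = q)
  } else {
    pr_dyn <- do.call(pr_dynamics, c(list(pr1 = 0.25), pr_common))
    n_total <- 3000
    # the loose->tight maturation step (sigma2, k2_half) is shared; genotypes
    # differ in the Ca2+-dependence of initial docking/priming (step 1) and in
    # the resting loose/tight balance
    sigma2 <- 1000; k2_half <- 0.15; b1 <- 0.5; b2 <- 1.5
    if (genotype == "control") {
      ts <- 691; r1 <- 1; sigma1 <- 10; k1_half <- 4
    } else {
      ts <- 1666; r1 <- 2; sigma1 <- 28; k1_half <- 0.7
    }
    r2 <- ts * (1 + r1) / (r1 * (n_total - ts))
    params <- two_step_params(n_total = n_total, k1_rest = r1 * b1,
                              sigma1 = sigma1, k1_half = k1_half, b1 = b1,
                              k2_rest = r2 * b2, sigma2 = sigma2,
                              k2_half = k2_half, b2 = b2, q = q)
  }
  list(model = model, params = params, calcium = calcium, pr_dyn = pr_dyn)
}
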