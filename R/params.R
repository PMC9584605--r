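#' Effective calcium dynamics parameters
#'
#' Spatially averaged ("effective") presynaptic \[Ca2+\] is modelled as a
#' jump-and-decay process: it increases instantaneously by `delta_ca_ap` at
#' each action potential (AP) and relaxes mono-exponentially back to the
#' resting concentration `ca_rest` with rate constant `k_ca`.
#'
#' @param ca_rest Resting \[Ca2+\] in nM (default 50 nM).
#' @param delta_ca_ap Instantaneous \[Ca2+\] increment per AP, nM.
#' @param k_ca Decay rate constant of the elevation, 1/s.
#' @return An object of class `calcium_dynamics` (named list).
#' @examples
#' ca <- calcium_dynamics(delta_ca_ap = 150, k_ca = 20)
#' ca_after(ca$ca_rest + 1000, dt = 1 / ca$k_ca, dyn = ca)
#' @export
calcium_dynamics <- function(ca_rest = 50, delta_ca_ap = 0, k_ca = 20) {
  if (!is.numeric(ca_rest) || ca_rest <= 0) abort("`ca_rest` must be > 0 (nM).")
  if (delta_ca_ap < 0) abort("`delta_ca_ap` must be >= 0 (nM).")
  if (k_ca <= 0) abort("`k_ca` must be > 0 (1/s).")
  structure(list(ca_rest = ca_rest, delta_ca_ap = delta_ca_ap, k_ca = k_ca),
            class = "calcium_dynamics")
}

#' Release-probability dynamics parameters
#'
#' Per-AP release probability is modelled as
#' `P_r[j] = pr1 * y[j]^facilitation_exponent * z[j]`, with `y >= 1` carrying
#' facilitation (local Ca2+ accumulation / buffer saturation) and `z <= 1` a
#' small activity-dependent reduction of fusogenicity. Both variables start at
#' 1 at train onset; after each AP, `y` is incremented by
#' `y_inc1 * (y_max - y)` and `z` decremented by `z_dec1 * (z - z_min)`;
#' between stimuli both relax exponentially back to 1 with rate constants
#' `k_y` and `k_z`.
#'
#' @param pr1 Release probability of the first AP in a train (0, 1].
#' @param y_inc1 Per-AP increment gain of the facilitation variable.
#' @param y_max Ceiling of `y` (>= 1).
#' @param z_dec1 Per-AP decrement gain of the depression variable.
#' @param z_min Floor of `z` (0..1).
#' @param k_y,k_z Relaxation rate constants towards 1, 1/s.
#' @param facilitation_exponent Exponent applied to `y`; fixed at 4.5 by
#'   default.
#' @return An object of class `pr_dynamics`.
#' @examples
#' pr_dynamics(pr1 = 0.1)                      # static P_r
#' pr_dynamics(pr1 = 0.08, y_inc1 = 0.03, y_max = 2, k_y = 40)
#' @export
pr_dynamics <- function(pr1, y_inc1 = 0, y_max = 1, z_dec1 = 0, z_min = 1,
                        k_y = 1, k_z = 1, facilitation_exponent = 4.5) {
  if (pr1 <= 0 || pr1 > 1) abort("`pr1` must lie in (0, 1].")
  if (y_max < 1) abort("`y_max` must be >= 1.")
  if (z_min < 0 || z_min > 1) abort("`z_min` must lie in [0, 1].")
  if (k_y <= 0 || k_z <= 0) abort("`k_y` and `k_z` must be > 0 (1/s).")
  if (y_inc1 < 0 || z_dec1 < 0) abort("`y_inc1` and `z_dec1` must be >= 0.")
  structure(list(pr1 = pr1, y_inc1 = y_inc1, y_max = y_max, z_dec1 = z_dec1,
                 z_min = z_min, k_y = k_y, k_z = k_z,
                 facilitation_exponent = facilitation_exponent),
            class = "pr_dynamics")
}

#' Single-pool model parameters
#'
#' One type of release site; sites are either empty or occupied by a primed,
#' fusion-competent vesicle. Priming (forward rate `k_f`) depends on effective
#' \[Ca2+\] through a Michaelis-Menten-like saturation (see [priming_rate()]);
#' unpriming (`kb`) is Ca2+-independent.
#'
#' @param n_total Total number of release sites.
#' @param kf_rest Forward priming rate at resting \[Ca2+\], 1/s.
#' @param sigma Slope of the Ca2+-dependence, 1/s per uM.
#' @param k_half Michaelis constant of the saturation, uM above rest.
#' @param kb Backward (unpriming) rate constant, 1/s.
#' @param q Quantal amplitude, nA per vesicle.
#' @return An object of class `single_pool_params`.
#' @examples
#' single_pool_params(n_total = 3000, kf_rest = 0.3, sigma = 10,
#'                    k_half = 2, kb = 0.1, q = 0.012)
#' @export
single_pool_params <- function(n_total, kf_rest, sigma, k_half, kb, q = 1) {
  vals <- c(n_total = n_total, kf_rest = kf_rest, sigma = sigma,
            k_half = k_half, kb = kb, q = q)
  # kf_rest = 0 and kb = 0 are admitted so replenishment can be switched off
  # (pure depletion experiments); resting_state() then needs an explicit pool
  if (any(vals[c("n_total", "k_half", "q")] <= 0) ||
      any(vals[c("kf_rest", "sigma", "kb")] < 0)) {
    abort("single-pool parameters: n_total, k_half, q must be > 0; kf_rest, sigma, kb >= 0.")
  }
  structure(as.list(vals), class = "single_pool_params")
}

#' Sequential two-step priming model parameters
#'
#' Vesicles dock at empty sites (ES), first into a loosely docked state (LS),
#' then mature into a tightly docked, fusion-competent state (TS). Only TS
#' vesicles fuse upon AP arrival. Both forward rates are Ca2+-dependent with
#' the same Michaelis-Menten-like form as the single-pool priming rate.
#'
#' @param n_total Total number of release sites.
#' @param k1_rest,sigma1,k1_half ES->LS forward rate: value at rest (1/s),
#'   Ca2+ slope (1/s per uM) and Michaelis constant (uM above rest).
#' @param b1 LS->ES backward rate, 1/s.
#' @param k2_rest,sigma2,k2_half LS->TS forward rate Ca2+-dependence.
#' @param b2 TS->LS backward rate, 1/s.
#' @param q Quantal amplitude, nA per vesicle.
#' @return An object of class `two_step_params`.
#' @export
two_step_params <- function(n_total, k1_rest, sigma1, k1_half, b1,
                            k2_rest, sigma2, k2_half, b2, q = 1) {
  vals <- c(n_total = n_total, k1_rest = k1_rest, sigma1 = sigma1,
            k1_half = k1_half, b1 = b1, k2_rest = k2_rest, sigma2 = sigma2,
            k2_half = k2_half, b2 = b2, q = q)
  if (any(vals[c("n_total", "k1_rest", "k1_half", "k2_rest", "k2_half", "q")] <= 0) ||
      any(vals[c("sigma1", "sigma2", "b1", "b2")] < 0)) {
    abort("two-step parameters: pool size, forward rates, Michaelis constants and q must be > 0; slopes and backward rates >= 0.")
  }
  structure(as.list(vals), class = "two_step_params")
}

#' Ca2+-dependent priming rate (Michaelis-Menten-like saturation)
#'
#' `k(ca) = (rest_rate + sigma * dCa) / (1 + dCa / k_half)` with
#' `dCa = ca - ca_rest`. Equal to `rest_rate` at rest and saturating towards
#' `sigma * k_half` for large elevations.
#'
#' @param ca Effective \[Ca2+\], nM (vectorised).
#' @param rest_rate Rate at resting \[Ca2+\], 1/s.
#' @param sigma Slope, 1/s per uM.
#' @param k_half Michaelis constant, uM above rest.
#' @param ca_rest Resting \[Ca2+\], nM.
#' @return Rate(s) in 1/s.
#' @examples
#' priming_rate(50, 0.3, sigma = 10, k_half = 2)          # = 0.3 at rest
#' priming_rate(2050, 0.3, sigma = 10, k_half = 2)        # half-saturation
#' @export
priming_rate <- function(ca, rest_rate, sigma, k_half, ca_rest = 50) {
  if (k_half <= 0) abort("`k_half` must be > 0 (uM).")
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (any(ca < ca_rest - 1e-9)) abort("`ca` must be >= `ca_rest`.")
  dca_um <- pmax(ca - ca_rest, 0) / 1000  # nM -> uM
  (rest_rate + sigma * dca_um) / (1 + dca_um / k_half)
}

#' Effective \[Ca2+\] after a silent period
#'
#' Closed-form exponential decay towards rest:
#' `ca_rest + (ca0 - ca_rest) * exp(-k_ca * dt)`.
#'
#' @param ca0 Starting concentration, nM.
#' @param dt Elapsed time, s (>= 0; vectorised).
#' @param dyn A [calcium_dynamics()] object.
#' @return Concentration(s) in nM.
#' @export
ca_after <- function(ca0, dt, dyn) {
  stopifnot(inherits(dyn, "calcium_dynamics"))
  if (any(dt < 0)) abort("`dt` must be >= 0.")
  dyn$ca_rest + (ca0 - dyn$ca_rest) * exp(-dyn$k_ca * dt)
}

#' @export
print.calcium_dynamics <- function(x, ...) {
  cat(sprintf("<calcium_dynamics> ca_rest %g nM, delta_ca_ap %g nM, k_ca %g /s\n",
              x$ca_rest, x$delta_ca_ap, x$k_ca))
  invisible(x)
}

#' @export
print.pr_dynamics <- function(x, ...) {
  cat(sprintf("<pr_dynamics> pr1 %g; y: +%g -> max %g (k_y %g /s); z: -%g -> min %g (k_z %g /s); exponent %g\n",
              x$pr1, x$y_inc1, x$y_max, x$k_y, x$z_dec1, x$z_min, x$k_z,
              x$facilitation_exponent))
  invisible(x)
}

#' @export
print.single_pool_params <- function(x, ...) {
  cat(sprintf("<single_pool_params> N %g sites; kf_rest %g /s, sigma %g /s/uM, K0.5 %g uM, kb %g /s; q %g nA\n",
              x$n_total, x$kf_rest, x$sigma, x$k_half, x$kb, x$q))
  invisible(x)
}

#' @export
print.two_step_params <- function(x, ...) {
  cat(sprintf("<two_step_params> N %g sites; k1 %g (sigma %g, K %g), b1 %g; k2 %g (sigma %g, K %g), b2 %g; q %g nA\n",
              x$n_total, x$k1_rest, x$sigma1, x$k1_half, x$b1,
              x$k2_rest, x$sigma2, x$k2_half, x$b2, x$q))
  invisible(x)
}
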