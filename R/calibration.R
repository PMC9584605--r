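# Calibration: objective-based fitting of model parameters to STP-train and
# recovery datasets, with parameter sharing across experimental conditions
# (e.g. genotypes).

.cfg_slots <- c("params", "calcium", "pr_dyn")

.cfg_set <- function(cfg, name, value) {
  for (slot in .cfg_slots) {
    if (name %in% names(cfg[[slot]])) {
      cfg[[slot]][[name]] <- value
      return(cfg)
    }
  }
  abort(sprintf("unknown calibration parameter `%s`.", name))
}

.cfg_get <- function(cfg, name) {
  for (slot in .cfg_slots) {
    if (name %in% names(cfg[[slot]])) return(cfg[[slot]][[name]])
  }
  abort(sprintf("unknown calibration parameter `%s`.", name))
}

#' Define a calibration problem
#'
#' Couples one or more experimental conditions (each with EPSC-train and,
#' optionally, recovery targets) to a kinetic model whose named parameters are
#' fitted either jointly (`free_shared`, one value for all conditions) or per
#' condition (`free_specific`). Parameter names are looked up across the
#' model, calcium and release-probability parameter sets.
#'
#' @param base List with elements `params` ([single_pool_params()] or
#'   [two_step_params()]), `calcium`, `pr_dyn`: the template configuration.
#' @param conditions Named list; each element a list with `trains` (a list of
#'   target `epsc_train`s) and optionally `recovery` (a `recovery_dataset`, or
#'   a list with `intervals`, `frac_recovery`, `cond_protocol`,
#'   `test_protocol`).
#' @param free_shared Names of parameters shared across conditions.
#' @param free_specific Names of parameters fitted per condition.
#' @param bounds Named list of `c(lower, upper)` for every free parameter.
#' @param weights Optional named numeric weights per dataset type
#'   (`trains`, `recovery`); default equal.
#' @param sim_control List with `rtol`, `atol` for the simulations used inside
#'   the objective.
#' @return A `calibration_problem`.
#' @export
calibration_problem <- function(base, conditions, free_shared = character(),
                                free_specific = character(), bounds,
                                weights = c(trains = 1, recovery = 1),
                                sim_control = list(rtol = 1e-7, atol = 1e-9)) {
  stopifnot(is.list(base), all(.cfg_slots %in% names(base)))
  if (length(conditions) == 0 || is.null(names(conditions))) {
    abort("`conditions` must be a named list.")
  }
  free <- c(free_shared, free_specific)
  if (length(free) == 0) abort("no free parameters.")
  if (anyDuplicated(free)) abort("`free_shared` and `free_specific` overlap.")
  missing_b <- setdiff(free, names(bounds))
  if (length(missing_b) > 0) {
    abort(paste0("missing bounds for: ", paste(missing_b, collapse = ", ")))
  }
  for (nm in free) {
    b <- bounds[[nm]]
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2]) {
      abort(sprintf("bounds for `%s` must be finite c(lower, upper).", nm))
    }
    .cfg_get(base, nm)  # errors early on unknown names
  }
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    if (is.null(cond$trains) || length(cond$trains) == 0) {
      abort(sprintf("condition `%s` has no train dataset.", cn))
    }
    if (is.null(cond$recovery)) {
      warn(sprintf("condition `%s`: no recovery dataset; that term is skipped.", cn))
    }
  }
  structure(list(base = base, conditions = conditions,
                 free_shared = free_shared, free_specific = free_specific,
                 bounds = bounds, weights = weights,
                 sim_control = sim_control),
            class = "calibration_problem")
}

.par_names <- function(problem) {
  c(problem$free_shared,
    unlist(lapply(names(problem$conditions), function(cn) {
      paste(problem$free_specific, cn, sep = ".")
    })))
}

.condition_cfg <- function(problem, par, cond_name) {
  cfg <- problem$base
  for (nm in problem$free_shared) cfg <- .cfg_set(cfg, nm, par[[nm]])
  for (nm in problem$free_specific) {
    cfg <- .cfg_set(cfg, nm, par[[paste(nm, cond_name, sep = ".")]])
  }
  cfg
}

.rel_sq_err <- function(sim, obs) {
  denom <- pmax(abs(obs), 1e-3 * max(abs(obs)))
  mean(((sim - obs) / denom)^2)
}

#' Calibration objective
#'
#' Weighted mean of squared relative errors between simulated and target EPSC
#' amplitudes (all train datasets) and fractional-recovery points, summed over
#' conditions. Exactly zero when the simulation reproduces the targets.
#'
#' @param problem A [calibration_problem()].
#' @param par Named numeric vector over [`.par_names`][calibration_problem]
#'   layout: shared parameters, then `<name>.<condition>` specifics.
#' @return Scalar loss (unitless).
#' @export
stp_objective <- function(problem, par) {
  par <- as.list(par)
  rtol <- problem$sim_control$rtol; atol <- problem$sim_control$atol
  loss <- 0
  for (cn in names(problem$conditions)) {
    cond <- problem$conditions[[cn]]
    cfg <- .condition_cfg(problem, par, cn)
    for (target in cond$trains) {
      prot <- stim_protocol(target$ap_time_s)
      sim <- simulate_train(prot, cfg$params, cfg$calcium, cfg$pr_dyn,
                            rtol = rtol, atol = atol)
      loss <- loss + problem$weights[["trains"]] *
        .rel_sq_err(sim$amplitude_nA, target$amplitude_nA)
    }
    rec <- cond$recovery
    if (!is.null(rec)) {
      if (inherits(rec, "recovery_dataset")) {
        rec <- list(intervals = rec$points$interval_s,
                    frac_recovery = rec$points$frac_recovery,
                    cond_protocol = stim_protocol(rec$cond_train$ap_time_s),
                    test_protocol = stim_protocol(rec$points$test_train[[1]]$ap_time_s -
                                                    min(rec$points$test_train[[1]]$ap_time_s)))
      }
      sim_rec <- recovery_curve(cfg$params, cfg$calcium, cfg$pr_dyn,
                                rec$cond_protocol, rec$intervals,
                                rec$test_protocol, rtol = rtol, atol = atol)
      loss <- loss + problem$weights[["recovery"]] *
        .rel_sq_err(sim_rec$points$frac_recovery, rec$frac_recovery)
    }
  }
  loss
}

#' Fit a calibration problem
#'
#' Bounded local optimisation (`nlminb`) from Latin-hypercube starting points;
#' the best converged start wins. Shared parameters are fitted jointly across
#' conditions by construction, so the fitted values are identical in every
#' condition's configuration.
#'
#' @param problem A [calibration_problem()].
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed RNG seed controlling the start design.
#' @param control Passed to [nlminb()].
#' @return A `calibration_result`: `par` (named vector), `loss`, `configs`
#'   (per condition), `starts` tibble (per-start loss/convergence),
#'   `convergence`, `at_bounds` (names of parameters within 1e-6 of a bound),
#'   `seed`.
#' @export
fit_stp <- function(problem, n_starts = 8, seed = 1,
                    control = list(iter.max = 300, eval.max = 600)) {
  stopifnot(inherits(problem, "calibration_problem"))
  nms <- .par_names(problem)
  base_names <- c(problem$free_shared,
                  rep(problem$free_specific, length(problem$conditions)))
  lower <- vapply(base_names, function(nm) problem$bounds[[nm]][1], 0)
  upper <- vapply(base_names, function(nm) problem$bounds[[nm]][2], 0)
  names(lower) <- names(upper) <- nms
  d <- length(nms)
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, d)
  obj <- function(x) stp_objective(problem, setNames(x, nms))
  runs <- lapply(seq_len(n_starts), function(i) {
    x0 <- lower + design[i, ] * (upper - lower)
    tryCatch(nlminb(x0, obj, lower = lower, upper = upper, control = control),
             error = function(e) list(objective = Inf, convergence = 1L,
                                      par = x0, message = conditionMessage(e)))
  })
  losses <- vapply(runs, function(r) r$objective, 0)
  if (all(!is.finite(losses))) abort("all calibration starts failed; see diagnostics.")
  best <- runs[[which.min(losses)]]
  par <- setNames(best$par, nms)
  tol_b <- 1e-6 * (upper - lower)
  at_bounds <- nms[par <= lower + tol_b | par >= upper - tol_b]
  configs <- lapply(names(problem$conditions), function(cn) {
    .condition_cfg(problem, as.list(par), cn)
  })
  names(configs) <- names(problem$conditions)
  structure(list(par = par, loss = best$objective, configs = configs,
                 starts = tibble(start = seq_len(n_starts), loss = losses,
                                 convergence = vapply(runs, function(r) as.integer(r$convergence), 0L)),
                 convergence = best$convergence, at_bounds = at_bounds,
                 seed = seed, problem = problem),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> loss %.4g (%d starts, best convergence %d)%s\n",
              x$loss, nrow(x$starts), x$convergence,
              if (length(x$at_bounds) > 0)
                paste0("; at bounds: ", paste(x$at_bounds, collapse = ", "))
              else ""))
  print(x$par)
  invisible(x)
}

#' @export
tidy.calibration_result <- function(x, ...) {
  nms <- names(x$par)
  shared <- nms %in% x$problem$free_shared
  tibble(parameter = nms, estimate = as.numeric(x$par), shared = shared,
         condition = ifelse(shared, NA_character_, sub("^[^.]+\\.", "", nms)),
         at_bound = nms %in% x$at_bounds)
}

#' @export
glance.calibration_result <- function(x, ...) {
  tibble(loss = x$loss, n_starts = nrow(x$starts),
         n_converged = sum(x$starts$convergence == 0),
         convergence = x$convergence, seed = x$seed,
         boundary_solution = length(x$at_bounds) > 0)
}
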