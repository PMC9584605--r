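# Recovery-time-course analysis: fractional recovery, mono/bi-exponential
# fitting with nested-model selection, weighted time constants.

#' Fractional recovery of the test EPSC
#'
#' `(EPSC_test1 - EPSC_cond_ss) / (EPSC_cond1 - EPSC_cond_ss)`: 0 at no
#' recovery, 1 at full recovery; overshoot (> 1) is allowed.
#'
#' @param epsc_test1 First amplitude of the test train, nA (vectorised).
#' @param cond_epsc1 First amplitude of the conditioning train, nA.
#' @param cond_epsc_ss Steady-state amplitude of the conditioning train, nA.
#' @return Unitless fractional recovery.
#' @export
fractional_recovery <- function(epsc_test1, cond_epsc1, cond_epsc_ss) {
  if (abs(cond_epsc1 - cond_epsc_ss) < .Machine$double.eps * 100 * max(abs(cond_epsc1), 1)) {
    abort("conditioning train shows no depression; fractional recovery is undefined.")
  }
  (epsc_test1 - cond_epsc_ss) / (cond_epsc1 - cond_epsc_ss)
}

#' Amplitude-weighted time constant of a bi-exponential fit
#'
#' `tau_w = (1 - f_slow) * tau_fast + f_slow * tau_slow`.
#'
#' @param tau_fast,tau_slow Time constants, s (`tau_slow >= tau_fast`).
#' @param f_slow Fractional amplitude of the slow component, in \[0, 1\].
#' @return Weighted time constant, s.
#' @examples
#' weighted_tau(0.028, 2.7, 0.86)  # 2.33 s
#' @export
weighted_tau <- function(tau_fast, tau_slow, f_slow) {
  if (any(f_slow < 0 | f_slow > 1)) abort("`f_slow` must lie in [0, 1].")
  if (any(tau_slow < tau_fast)) abort("`tau_slow` must be >= `tau_fast`.")
  (1 - f_slow) * tau_fast + f_slow * tau_slow
}

.mono_rec <- function(t, A, tau) A * (1 - exp(-t / tau))
.bi_rec <- function(t, A, f, tau1, tau2) {
  A * (1 - (f * exp(-t / tau1) + (1 - f) * exp(-t / tau2)))
}

.fit_mono <- function(t, v) {
  starts <- expand.grid(tau = c(0.02, 0.1, 0.5, 2))
  A0 <- max(v)
  fits <- lapply(starts$tau, function(tau0) {
    tryCatch(minpack.lm::nlsLM(v ~ .mono_rec(t, A, tau),
                               start = list(A = A0, tau = tau0),
                               lower = c(A = 0, tau = 1e-6),
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) return(NULL)
  fits[[which.min(vapply(fits, function(f) sum(resid(f)^2), 0))]]
}

.fit_bi <- function(t, v) {
  grid <- expand.grid(tau1 = c(0.01, 0.05, 0.2), tau2 = c(0.5, 2, 5),
                      f = c(0.2, 0.5, 0.8))
  A0 <- max(v)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tryCatch(minpack.lm::nlsLM(v ~ .bi_rec(t, A, f, tau1, tau2),
                               start = list(A = A0, f = g$f, tau1 = g$tau1,
                                            tau2 = g$tau2),
                               lower = c(A = 0, f = 0, tau1 = 1e-6, tau2 = 1e-6),
                               upper = c(A = Inf, f = 1, tau1 = Inf, tau2 = Inf),
                               control = minpack.lm::nls.lm.control(maxiter = 300)),
             error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) return(NULL)
  fits[[which.min(vapply(fits, function(f) sum(resid(f)^2), 0))]]
}

#' Fit a recovery time course
#'
#' Fits both the mono-exponential `A * (1 - exp(-t/tau))` and the
#' bi-exponential `A * (1 - (f * exp(-t/tau1) + (1 - f) * exp(-t/tau2)))`
#' forms by multi-start nonlinear least squares and selects between them with
#' a nested-model F-test (`F = ((RSS_mono - RSS_bi)/2) / (RSS_bi/(n - 4))`);
#' the bi-exponential is kept when `p < alpha`.
#'
#' @param data Data frame with columns `interval_s` and `value` (fractional
#'   recovery or absolute amplitude).
#' @param force_model `"auto"` (F-test), `"mono"` or `"bi"`.
#' @param alpha Significance level of the F-test.
#' @return An `exp_fit` object: fields `model`, `A`, `f` (fraction of the fast
#'   `tau1` component), `tau1`, `tau2`, `tau_w`, `f_test_p`, `rss`. Methods:
#'   `tidy()`, `glance()`, `autoplot()`, `predict()`.
#' @export
fit_recovery <- function(data, force_model = c("auto", "mono", "bi"),
                         alpha = 0.05) {
  force_model <- match.arg(force_model)
  if (!all(c("interval_s", "value") %in% names(data))) {
    abort("`data` needs columns `interval_s` and `value`.")
  }
  t <- data$interval_s; v <- data$value
  n <- length(t)
  if (n < 5 || (force_model != "mono" && n < 7)) {
    abort("too few points: >= 5 needed for a mono fit, >= 7 for a bi fit.")
  }
  if (diff(range(v)) < 1e-12 * max(abs(v), 1)) {
    abort("constant values: recovery time constant unidentifiable.")
  }
  mono <- .fit_mono(t, v)
  bi <- if (force_model != "mono") .fit_bi(t, v) else NULL
  if (is.null(mono) && is.null(bi)) abort("recovery fit failed from every start.")

  rss_mono <- if (!is.null(mono)) sum(resid(mono)^2) else Inf
  rss_bi <- if (!is.null(bi)) sum(resid(bi)^2) else Inf
  f_test_p <- NA_real_
  if (!is.null(mono) && !is.null(bi)) {
    df_bi <- n - 4
    tol0 <- .Machine$double.eps * sum(v^2)
    if (rss_mono <= tol0) {
      f_test_p <- 1  # mono already fits to numerical precision
    } else if (rss_bi <= tol0) {
      f_test_p <- 0
    } else {
      Fstat <- ((rss_mono - rss_bi) / 2) / (rss_bi / df_bi)
      f_test_p <- pf(max(Fstat, 0), 2, df_bi, lower.tail = FALSE)
    }
  }
  use_bi <- switch(force_model,
                   auto = !is.null(bi) && is.finite(f_test_p) && f_test_p < alpha,
                   mono = FALSE,
                   bi = !is.null(bi))
  if (force_model == "bi" && is.null(bi)) abort("bi-exponential fit failed.")

  if (use_bi) {
    cf <- coef(bi)
    tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]; f <- cf[["f"]]
    if (tau1 > tau2) {  # enforce tau1 = fast component
      tmp <- tau1; tau1 <- tau2; tau2 <- tmp; f <- 1 - f
    }
    res <- list(model = "bi", A = cf[["A"]], f = f, tau1 = tau1, tau2 = tau2,
                tau_w = f * tau1 + (1 - f) * tau2,
                f_test_p = f_test_p, rss = rss_bi, fit = bi, data = data)
  } else {
    cf <- coef(mono)
    res <- list(model = "mono", A = cf[["A"]], f = 1, tau1 = cf[["tau"]],
                tau2 = NA_real_, tau_w = cf[["tau"]],
                f_test_p = f_test_p, rss = rss_mono, fit = mono, data = data)
  }
  structure(res, class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "bi") {
    cat(sprintf("<exp_fit [bi]> A %.4g; tau_fast %.4g s (f %.3g), tau_slow %.4g s; tau_w %.4g s; F-test p %.3g\n",
                x$A, x$tau1, x$f, x$tau2, x$tau_w, x$f_test_p))
  } else {
    cat(sprintf("<exp_fit [mono]> A %.4g; tau %.4g s%s\n", x$A, x$tau1,
                if (is.finite(x$f_test_p)) sprintf("; F-test p %.3g", x$f_test_p) else ""))
  }
  invisible(x)
}

#' @export
tidy.exp_fit <- function(x, ...) {
  tibble(term = c("A", "f_fast", "tau1", "tau2", "tau_w"),
         estimate = c(x$A, x$f, x$tau1, x$tau2, x$tau_w))
}

#' @export
glance.exp_fit <- function(x, ...) {
  tibble(model = x$model, rss = x$rss, f_test_p = x$f_test_p,
         tau_w = x$tau_w, n = nrow(x$data))
}

#' @export
predict.exp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$interval_s else newdata$interval_s
  if (object$model == "bi") {
    .bi_rec(t, object$A, object$f, object$tau1, object$tau2)
  } else {
    .mono_rec(t, object$A, object$tau1)
  }
}
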