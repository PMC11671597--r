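# Nonlinear binding fits: 4PL dose-response EC50 and 1:1 quadratic
# isotherm Kd, both by Levenberg-Marquardt least squares on transformed
# parameters, with seeded case-resampling bootstrap intervals.

fourpl_theta <- function(theta, x) {
  # theta = (bottom, log_span, log_ec50, log_hill); top = bottom + span
  fourpl(x, theta[1], theta[1] + exp(theta[2]), exp(theta[3]),
         exp(theta[4]))
}

fourpl_init <- function(doses, responses) {
  lo <- min(responses)
  hi <- max(responses)
  span <- max(hi - lo, 1e-8 * max(abs(hi), 1))
  mid <- (lo + hi) / 2
  # ec50 heuristic: dose bracketing the half-signal crossing
  ord <- order(doses)
  d <- doses[ord]
  y <- responses[ord]
  above <- y >= mid
  ec50 <- if (any(diff(above) != 0)) {
    i <- which(diff(above) != 0)[1]
    sqrt(d[i] * d[i + 1])
  } else {
    exp(mean(log(d)))
  }
  c(lo, log(span), log(ec50), log(1))
}

# Levenberg-Marquardt on the residual function; info codes 1-4 indicate a
# satisfied convergence test, anything else is an error.
run_lm <- function(resid_fn, start) {
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (!fit$info %in% 1:4) {
    stop("Levenberg-Marquardt did not converge (info ", fit$info, "): ",
         fit$message, call. = FALSE)
  }
  fit$par
}

fit_4pl_core <- function(doses, responses, start, fix_hill = FALSE) {
  if (fix_hill) {
    par <- run_lm(function(p) {
      responses - fourpl_theta(c(p, log(1)), doses)
    }, start[1:3])
    c(par, log(1))
  } else {
    run_lm(function(p) responses - fourpl_theta(p, doses), start)
  }
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `y = bottom + (top - bottom)/(1 + (ec50/x)^hill)` with `top >= bottom`
#' and `ec50, hill > 0` enforced by fitting `(bottom, log(top - bottom),
#' log(ec50), log(hill))`. Initialization takes the asymptotes from the
#' response extremes and EC50 from the doses bracketing the half-signal
#' crossing. Because the fit is performed in log(ec50), rescaling all
#' doses by a constant rescales the fitted EC50 by the same constant.
#'
#' @param doses Positive dose vector (uM), at least 3 distinct values.
#' @param responses Signal vector, same length, at least 5 points.
#' @param fix_hill Fix the Hill slope at 1 (default `FALSE`, free).
#' @param n_boot Bootstrap resamples for percentile intervals (0 = none).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return Object of class `dose_response_fit`: a list with `bottom`,
#'   `top`, `ec50`, `hill`, `rss`, `fitted`, `ci` (percentile intervals
#'   per parameter when `n_boot > 0`), `n`.
#' @export
#' @examples
#' d <- 10 * sqrt(10)^(0:6)
#' y <- fourpl(d, 0, 1, 280, 1)
#' fit_4pl(d, y)$ec50
fit_4pl <- function(doses, responses, fix_hill = FALSE, n_boot = 0,
                    boot_seed = 1L) {
  if (length(doses) != length(responses)) {
    stop("`doses` and `responses` lengths differ", call. = FALSE)
  }
  if (length(doses) < 5) stop("need at least 5 points", call. = FALSE)
  if (length(unique(doses)) < 3) {
    stop("need at least 3 distinct doses", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  start <- fourpl_init(doses, responses)
  theta <- tryCatch(
    fit_4pl_core(doses, responses, start, fix_hill = fix_hill),
    error = function(e) stop("4PL fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  rss <- sum((responses - fourpl_theta(theta, doses))^2)
  rss_start <- sum((responses - fourpl_theta(start, doses))^2)
  if (rss > rss_start + 1e-8 * (1 + rss_start)) {
    stop("4PL fit did not improve on the initial heuristic", call. = FALSE)
  }
  out <- structure(
    list(bottom = theta[1], top = theta[1] + exp(theta[2]),
         ec50 = exp(theta[3]), hill = exp(theta[4]), rss = rss,
         fitted = fourpl_theta(theta, doses), n = length(doses),
         ci = NULL),
    class = "dose_response_fit")
  if (n_boot > 0) {
    out$ci <- bootstrap_ci(doses, responses, n_boot, boot_seed,
                           function(d, y) {
                             th <- fit_4pl_core(d, y, fourpl_init(d, y),
                                                fix_hill = fix_hill)
                             c(bottom = th[1], top = th[1] + exp(th[2]),
                               ec50 = exp(th[3]), hill = exp(th[4]))
                           })
  }
  out
}

isotherm_init <- function(ligand, signal, protein_conc) {
  lo <- min(signal)
  hi <- max(signal)
  span <- max(hi - lo, 1e-8 * max(abs(hi), 1))
  mid <- (lo + hi) / 2
  pos <- ligand[ligand > 0]
  kd0 <- if (length(pos)) exp(mean(log(pos))) else 1
  cross <- which(signal >= mid & ligand > 0)
  if (length(cross)) kd0 <- ligand[cross[1]]
  c(lo, log(span), log(kd0))
}

fit_isotherm_core <- function(ligand, signal, protein_conc, start) {
  run_lm(function(p) {
    signal - (p[1] + exp(p[2]) *
                isotherm_fraction_bound(ligand, protein_conc, exp(p[3])))
  }, start)
}

#' Fit a 1:1 quadratic binding isotherm
#'
#' Least-squares fit of
#' `signal = baseline + amplitude * f(L; P, Kd)` where `f` is the exact
#' quadratic-isotherm fraction bound ([isotherm_fraction_bound()]) at
#' fixed total protein concentration `P`. `Kd` and the amplitude are
#' fitted on the log scale.
#'
#' @param ligand Total ligand concentrations (uM, >= 0), >= 5 points.
#' @param signal Saturation signal, same length.
#' @param protein_conc Total protein concentration (uM), > 0.
#' @param n_boot Bootstrap resamples for percentile intervals (0 = none).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return Object of class `isotherm_fit`: a list with `kd`, `amplitude`,
#'   `baseline`, `protein_conc`, `rss`, `fitted`, `ci`, `n`.
#' @export
#' @examples
#' L <- 2 * sqrt(10)^(0:11)
#' y <- isotherm_fraction_bound(L, 0.05, 204)
#' fit_isotherm(L, y, protein_conc = 0.05)$kd
fit_isotherm <- function(ligand, signal, protein_conc, n_boot = 0,
                         boot_seed = 1L) {
  if (length(ligand) != length(signal)) {
    stop("`ligand` and `signal` lengths differ", call. = FALSE)
  }
  if (length(ligand) < 5) stop("need at least 5 points", call. = FALSE)
  if (protein_conc <= 0) stop("`protein_conc` must be positive",
                              call. = FALSE)
  start <- isotherm_init(ligand, signal, protein_conc)
  theta <- tryCatch(
    fit_isotherm_core(ligand, signal, protein_conc, start),
    error = function(e) stop("isotherm fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  pred <- theta[1] + exp(theta[2]) *
    isotherm_fraction_bound(ligand, protein_conc, exp(theta[3]))
  out <- structure(
    list(kd = exp(theta[3]), amplitude = exp(theta[2]),
         baseline = theta[1], protein_conc = protein_conc,
         rss = sum((signal - pred)^2), fitted = pred, n = length(ligand),
         ci = NULL),
    class = "isotherm_fit")
  if (n_boot > 0) {
    out$ci <- bootstrap_ci(ligand, signal, n_boot, boot_seed,
                           function(L, y) {
                             th <- fit_isotherm_core(
                               L, y, protein_conc,
                               isotherm_init(L, y, protein_conc))
                             c(kd = exp(th[3]), amplitude = exp(th[2]),
                               baseline = th[1])
                           })
  }
  out
}

# Seeded case-resampling bootstrap; percentile 95% intervals per parameter.
bootstrap_ci <- function(x, y, n_boot, seed, refit, level = 0.95) {
  n <- length(x)
  est <- with_substream(substream_seed(seed, "bootstrap"), {
    reps <- lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(refit(x[idx], y[idx]), error = function(e) NULL)
    })
    do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  })
  if (is.null(est) || nrow(est) == 0) return(NULL)
  a <- (1 - level) / 2
  ci <- t(apply(est, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  ci
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit (n =", x$n, "points)\n")
  cat(sprintf("  bottom %.4g  top %.4g  EC50 %.4g uM  Hill %.3g  RSS %.3g\n",
              x$bottom, x$top, x$ec50, x$hill, x$rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  EC50 95%% CI [%.4g, %.4g]\n",
                x$ci["ec50", "lower"], x$ci["ec50", "upper"]))
  }
  invisible(x)
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("1:1 quadratic isotherm fit (n =", x$n, "points)\n")
  cat(sprintf("  Kd %.4g uM  amplitude %.4g  baseline %.4g  RSS %.3g\n",
              x$kd, x$amplitude, x$baseline, x$rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  Kd 95%% CI [%.4g, %.4g]\n",
                x$ci["kd", "lower"], x$ci["kd", "upper"]))
  }
  invisible(x)
}
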