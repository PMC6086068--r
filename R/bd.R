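#' Constant-rate birth-death log-likelihood of branching times
#'
#' Reconstructed-process likelihood of a dated, complete species phylogeny
#' under a constant-rate birth-death model, conditioned on a crown start
#' (two ancestral lineages at the crown age) and on both crown lineages
#' leaving extant descendants. With r = lambda - mu,
#' E(t) = mu (1 - exp(-r t)) / (lambda - mu exp(-r t)) the extinction
#' probability of a single lineage over time t, and
#' p1(t) = r^2 exp(-r t) / (lambda - mu exp(-r t))^2 the probability that a
#' lineage survives with exactly one sampled descendant, the log-likelihood
#' of branching times t1 >= t2 >= ... >= t_{n-1} (t1 the crown age) is
#'
#'   (n-2) log lambda + sum_{i=2}^{n-1} log p1(t_i)
#'     + 2 log p1(t1) - 2 log(1 - E(t1)).
#'
#' Parameter-independent combinatorial constants are omitted, so only
#' likelihood differences (and hence ML estimates) are meaningful, not the
#' absolute value. At lambda = mu the continuous limits
#' p1(t) = 1/(1 + lambda t)^2 and E(t) = lambda t/(1 + lambda t) are used.
#'
#' @param bt Branching times (Myr before present), e.g. from
#'   [branching_times()]; length n-1 for n tips, n >= 2.
#' @param lambda Speciation rate, per Myr, > 0.
#' @param mu Extinction rate, per Myr, >= 0.
#' @return Log-likelihood in nats (`-Inf` where the conditioning probability
#'   underflows, e.g. mu much larger than lambda).
#' @examples
#' bd_loglik(c(2, 1), lambda = 0.8, mu = 0.4)
#' @export
bd_loglik <- function(bt, lambda, mu) {
  stopifnot(is.numeric(bt), length(bt) >= 1L, all(is.finite(bt)),
            all(bt > 0), is.finite(lambda), is.finite(mu), mu >= 0)
  if (lambda <= 0) stop("'lambda' must be > 0", call. = FALSE)
  t1 <- max(bt)
  lp <- bd_log_p1(bt, lambda, mu)
  le <- bd_log_1mE(t1, lambda, mu)
  ll <- (length(bt) - 1L) * log(lambda) + sum(lp) + lp[which.max(bt)] -
    2 * le
  if (is.nan(ll)) -Inf else ll
}

# log p1(t), numerically stable for both signs of r = lambda - mu.
# For r >= 0:  2 log r - r t - 2 log(lambda - mu e^{-rt}), e^{-rt} <= 1.
# For r < 0 :  2 log|r| + r t - 2 log(mu - lambda e^{rt}),  e^{rt}  <= 1.
bd_log_p1 <- function(t, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-10 * lambda)
    return(-2 * log1p(lambda * t))
  if (r > 0)
    2 * log(r) - r * t - 2 * log(lambda - mu * exp(-r * t))
  else
    2 * log(-r) + r * t - 2 * log(mu - lambda * exp(r * t))
}

# log(1 - E(t)): survival probability of one lineage over t
bd_log_1mE <- function(t, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-10 * lambda)
    return(-log1p(lambda * t))
  # 1 - E = r / (lambda - mu e^{-rt}) = (r e^{rt}) / (lambda e^{rt} - mu)
  if (r > 0)
    log(r) - log(lambda - mu * exp(-r * t))
  else
    log(-r) + r * t - log(mu - lambda * exp(r * t))
}

#' Maximum-likelihood birth-death rates from branching times
#'
#' Maximises [bd_loglik()] over lambda > 0 and mu >= 0. Optimisation runs in
#' log-transformed parameters with a quasi-Newton optimiser from several
#' starting points (a pure-birth moment estimate plus perturbations), and a
#' closed-form pure-birth (mu = 0) candidate is always evaluated: for mu = 0
#' the log-likelihood is maximised at
#' lambda = (n - 2) / (2 t1 + sum_{i>=2} t_i).
#'
#' @param bt Branching times, as for [bd_loglik()].
#' @param mu_fixed Optional: hold the extinction rate fixed at this value and
#'   maximise over lambda only.
#' @param n_starts Number of optimiser starts (default 5).
#' @return Object of class `bd_fit`: list with `lambda_hat`, `mu_hat`
#'   (per Myr), `loglik`, `converged`, `at_boundary` (TRUE when mu_hat is at
#'   the zero boundary or the fit is degenerate, e.g. n = 2), `n_tips`.
#' @examples
#' bd_ml(c(2, 1), mu_fixed = 0)$lambda_hat  # 0.2
#' @export
bd_ml <- function(bt, mu_fixed = NULL, n_starts = 5L) {
  stopifnot(is.numeric(bt), length(bt) >= 1L, all(bt > 0))
  n <- length(bt) + 1L
  t1 <- max(bt)
  yule_denom <- 2 * t1 + sum(bt) - t1          # 2 t1 + sum of later times
  lam0 <- if (n > 2L) (n - 2L) / yule_denom else 0.5 / t1

  mu_floor <- 1e-8
  best <- list(value = -Inf, lambda = NA_real_, mu = NA_real_,
               converged = FALSE)

  if (!is.null(mu_fixed)) {
    stopifnot(mu_fixed >= 0)
    obj <- function(p) -bd_loglik(bt, exp(p), mu_fixed)
    starts <- log(lam0 * c(1, 0.5, 2, 0.1, 10)[seq_len(n_starts)])
    for (s in starts) {
      fit <- try(stats::optim(s, obj, method = "L-BFGS-B",
                              lower = log(1e-8), upper = log(1e4)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (-fit$value > best$value)
        best <- list(value = -fit$value, lambda = exp(fit$par),
                     mu = mu_fixed, converged = fit$convergence == 0)
    }
  } else {
    obj <- function(p) -bd_loglik(bt, exp(p[1]), exp(p[2]))
    starts <- list(c(lam0, lam0 / 10), c(lam0, lam0 / 2),
                   c(2 * lam0, lam0 * 0.9), c(lam0 / 2, lam0 / 20),
                   c(4 * lam0, 2 * lam0))[seq_len(n_starts)]
    for (s in starts) {
      fit <- try(stats::optim(log(pmax(s, mu_floor)), obj,
                              method = "L-BFGS-B",
                              lower = log(c(1e-8, mu_floor)),
                              upper = log(c(1e4, 1e4))),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (-fit$value > best$value)
        best <- list(value = -fit$value, lambda = exp(fit$par[1]),
                     mu = exp(fit$par[2]), converged = fit$convergence == 0)
    }
    # pure-birth closed form as explicit boundary candidate
    ll0 <- bd_loglik(bt, lam0, 0)
    if (ll0 >= best$value)
      best <- list(value = ll0, lambda = lam0, mu = 0, converged = TRUE)
  }

  at_bound <- (is.null(mu_fixed) && isTRUE(best$mu <= mu_floor * 1.01)) ||
    isTRUE(best$lambda <= 1e-8 * 1.01) || isTRUE(best$lambda >= 1e4 / 1.01) ||
    n == 2L
  structure(list(lambda_hat = best$lambda, mu_hat = best$mu,
                 loglik = best$value, converged = isTRUE(best$converged),
                 at_boundary = at_bound, n_tips = n),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf(paste0("Birth-death ML fit (n = %d tips): lambda = %.4f, ",
                     "mu = %.4f, logLik = %.3f%s%s\n"),
              x$n_tips, x$lambda_hat, x$mu_hat, x$loglik,
              if (x$converged) "" else " [not converged]",
              if (x$at_boundary) " [boundary]" else ""))
  invisible(x)
}

#' Birth-death ML fits for a list of species trees
#'
#' Fits [bd_ml()] to every tree with at least 2 tips; single-tip trees are
#' excluded (the reconstructed-process likelihood is undefined for them) and
#' counted.
#'
#' @param trees List of ultrametric `phylo` objects.
#' @return Data frame with one row per fitted tree (`n_tips`, `lambda_hat`,
#'   `mu_hat`, `loglik`, `converged`, `at_boundary`) and an attribute
#'   `n_excluded`, the number of single-tip trees skipped.
#' @export
bd_fit_trees <- function(trees) {
  ok <- vapply(trees, function(tr) length(tr$tip.label) >= 2L, TRUE)
  fits <- lapply(trees[ok], function(tr) {
    f <- bd_ml(branching_times(tr))
    data.frame(n_tips = f$n_tips, lambda_hat = f$lambda_hat,
               mu_hat = f$mu_hat, loglik = f$loglik,
               converged = f$converged, at_boundary = f$at_boundary)
  })
  out <- if (length(fits)) do.call(rbind, fits) else
    data.frame(n_tips = integer(0), lambda_hat = numeric(0),
               mu_hat = numeric(0), loglik = numeric(0),
               converged = logical(0), at_boundary = logical(0))
  attr(out, "n_excluded") <- sum(!ok)
  out
}
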