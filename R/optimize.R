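# Univariate root-position optimization (recursive bracketing + Brent on
# the derivative, with objective evaluation to reject minima) and
# coordinate-ascent optimization of the model parameters.

#' Find sign-change bracketing windows of a scalar function
#'
#' Recursively bisects \code{[lo, hi]} to depth \code{max_depth} and returns
#' the leaf subintervals on which \code{f} changes sign.  Such windows are
#' safe inputs for a root finder; a function with no sign change yields an
#' empty list.
#'
#' @param f A scalar function, finite on \code{[lo, hi]}.
#' @param lo,hi Interval endpoints.
#' @param max_depth Bisection depth; the interval is examined at a
#'   resolution of \code{(hi - lo) / 2^max_depth}.
#' @return List of \code{c(a, b)} windows with \code{sign(f(a)) != sign(f(b))}.
#' @export
find_brackets <- function(f, lo, hi, max_depth = 8) {
  stopifnot(is.function(f), lo < hi, max_depth >= 0)
  x <- seq(lo, hi, length.out = 2L^max_depth + 1L)
  fx <- vapply(x, f, numeric(1))
  if (any(!is.finite(fx)))
    stop("non-finite function value during bracketing", call. = FALSE)
  s <- sign(fx)
  idx <- which(s[-length(s)] * s[-1L] < 0 |
                 (s[-length(s)] != 0 & s[-1L] == 0))
  lapply(idx, function(i) c(x[i], x[i + 1L]))
}

#' Find a root of a scalar function in a bracketing window
#'
#' Brent's method (bisection / secant / inverse quadratic interpolation) on
#' a window where the function changes sign.
#'
#' @param f A scalar function.
#' @param window Numeric \code{c(a, b)} with \code{sign(f(a)) != sign(f(b))}.
#' @param tol Convergence tolerance on the abscissa.
#' @return The root location.
#' @export
brent_root <- function(f, window, tol = 1e-10) {
  stopifnot(length(window) == 2L)
  stats::uniroot(f, interval = sort(window), tol = tol,
                 check.conv = FALSE)$root
}

# Shared implementation used by both the exported wrapper and the search
# drivers (which hold a prebuilt engine).
.optimize_beta_impl <- function(engine, eid, params, tol = 1e-7,
                                max_depth = 8) {
  cache <- .root_cache(engine, eid, params)
  g <- function(b) .dll_at_beta(engine, cache, b)
  # scan the objective itself on the bisection grid: a sign change in its
  # successive differences brackets an interior extremum of LL, i.e. a root
  # of the derivative, at half the evaluation cost of scanning g directly
  x <- seq(0, 1, length.out = 2L^max_depth + 1L)
  fx <- vapply(x, function(b) .ll_at_beta(engine, cache, b), numeric(1))
  d <- sign(diff(fx))
  idx <- which(d[-length(d)] * d[-1L] < 0 | (d[-length(d)] != 0 & d[-1L] == 0))
  roots <- vapply(idx, function(i) {
    w <- c(x[i], x[i + 2L])
    if (sign(g(w[1])) * sign(g(w[2])) <= 0)
      tryCatch(brent_root(g, w, tol), error = function(e) NA_real_)
    else NA_real_
  }, numeric(1))
  # candidates: derivative roots, the endpoints (boundary optima have no
  # interior sign change), and the best grid point as a safety net on
  # surfaces too flat or rough for the window detection
  cand <- unique(c(0, 1, roots[is.finite(roots)], x[which.max(fx)]))
  lls <- vapply(cand, function(b) .ll_at_beta(engine, cache, b), numeric(1))
  # argmax; near-ties (delta < 1e-10) resolved towards the smallest beta
  best_ll <- max(lls)
  tied <- which(lls >= best_ll - 1e-10)
  pick <- tied[which.min(cand[tied])]
  list(beta = cand[pick], ll = lls[pick])
}

#' Optimize the root position along one branch
#'
#' Maximizes LL(\code{beta}) on an edge by locating the roots of the
#' derivative (recursive bracketing, then Brent's method in each window)
#' and evaluating the objective at every derivative root plus the interval
#' endpoints \{0, 1\} -- a derivative root may be a minimum, and boundary
#' optima have no interior derivative root, so both must be checked.
#' Near-equal candidates (log-likelihood within 1e-10) resolve to the
#' smallest \code{beta} for determinism.
#'
#' @param edge Edge id.
#' @param params An \code{nr_model}.
#' @param tree An \code{nr_tree}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}.
#' @param tol Brent tolerance on \code{beta}.
#' @param max_depth Bracketing recursion depth.
#' @return List with \code{beta} (optimal position) and \code{ll} (its
#'   log-likelihood).
#' @export
optimize_beta <- function(edge, params, tree, msa, tol = 1e-7, max_depth = 8) {
  engine <- .make_engine(tree, msa)
  .optimize_beta_impl(engine, .check_edge(tree, edge), params, tol, max_depth)
}

# -- model-parameter coordinate ascent ---------------------------------------

# LL of fixed rooted placement for given params, via a shared engine.
.ll_rooted_params <- function(engine, eid, beta, params) {
  cache <- .root_cache(engine, eid, params)
  .ll_at_beta(engine, cache, beta)
}

# Guard: return `new` only if it did not decrease the log-likelihood.
.monotone <- function(entry_ll, new_ll, entry, new, what) {
  if (is.finite(new_ll) && new_ll >= entry_ll - 1e-9) new
  else {
    warning("optimization of ", what, " failed to improve the likelihood; ",
            "keeping previous values", call. = FALSE)
    entry
  }
}

.optimize_rates_impl <- function(engine, eid, beta, params, maxit = 100,
                                 factr = 1e8) {
  fn <- function(lr) {
    p <- params; p$rates[] <- exp(lr)
    ll <- tryCatch(.ll_rooted_params(engine, eid, beta, p),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  entry_ll <- .ll_rooted_params(engine, eid, beta, params)
  res <- tryCatch(
    stats::optim(log(pmax(params$rates, 1e-7)), fn, method = "L-BFGS-B",
                 lower = log(1e-7), upper = log(100),
                 control = list(maxit = maxit, factr = factr)),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("rate optimization failed; keeping previous rates", call. = FALSE)
    return(list(params = params, ll = entry_ll))
  }
  new <- params; new$rates[] <- exp(res$par)
  out <- .monotone(entry_ll, -res$value, params, new, "substitution rates")
  list(params = out, ll = max(entry_ll, -res$value))
}

#' Optimize the 12 UNREST substitution rates
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of the log-likelihood over
#' the log-rates, holding the rooted tree and all other parameters fixed.
#' Rates are bounded to \eqn{[10^{-7}, 100]}.  The call never decreases the
#' log-likelihood: if the optimizer fails to improve it, the entry
#' parameters are returned with a warning.
#'
#' @param params An \code{nr_model}.
#' @param rooted An \code{nr_rooted}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}.
#' @return An \code{nr_model} with updated rates.
#' @export
optimize_rates <- function(params, rooted, msa) {
  engine <- .make_engine(rooted$tree, msa)
  .optimize_rates_impl(engine, rooted$edge, rooted$beta, params)$params
}

.optimize_freqs_impl <- function(engine, eid, beta, params, maxit = 100,
                                 factr = 1e8) {
  to_freqs <- function(x) { e <- exp(c(x, 0)); e / sum(e) }
  fn <- function(x) {
    p <- params; p$freqs[] <- to_freqs(x)
    ll <- tryCatch(.ll_rooted_params(engine, eid, beta, p),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  entry_ll <- .ll_rooted_params(engine, eid, beta, params)
  x0 <- log(params$freqs[1:3] / params$freqs[4])
  res <- tryCatch(
    stats::optim(x0, fn, method = "L-BFGS-B", lower = -30, upper = 30,
                 control = list(maxit = maxit, factr = factr)),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("frequency optimization failed; keeping previous frequencies",
            call. = FALSE)
    return(list(params = params, ll = entry_ll))
  }
  new <- params; new$freqs[] <- to_freqs(res$par)
  out <- .monotone(entry_ll, -res$value, params, new, "base frequencies")
  list(params = out, ll = max(entry_ll, -res$value))
}

#' Optimize the root base frequencies
#'
#' Maximizes the log-likelihood over the frequency simplex via a softmax
#' parameterization of three free coordinates (L-BFGS-B).  Frequencies
#' remain positive and sum to 1; the log-likelihood never decreases.
#'
#' @inheritParams optimize_rates
#' @return An \code{nr_model} with updated frequencies.
#' @export
optimize_freqs <- function(params, rooted, msa) {
  engine <- .make_engine(rooted$tree, msa)
  .optimize_freqs_impl(engine, rooted$edge, rooted$beta, params)$params
}

.optimize_alpha_impl <- function(engine, eid, beta, params, iteration) {
  if (params$n_cats <= 1L || iteration %% 10L != 0L)
    return(list(params = params, ll = NA_real_))
  fn <- function(la) {
    p <- params; p$alpha <- exp(la)
    ll <- tryCatch(.ll_rooted_params(engine, eid, beta, p),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  entry_ll <- .ll_rooted_params(engine, eid, beta, params)
  res <- stats::optimize(fn, interval = log(c(0.02, 100)), tol = 1e-4)
  new <- params; new$alpha <- exp(res$minimum)
  out <- .monotone(entry_ll, -res$objective, params, new, "gamma shape")
  list(params = out, ll = max(entry_ll, -res$objective))
}

#' Optimize the gamma shape parameter
#'
#' Brent-style univariate maximization of the log-likelihood over
#' \eqn{\log\alpha \in [\log 0.02, \log 100]}.  The update only fires on
#' every 10th iteration of the surrounding search (\code{iteration \%\% 10
#' == 0}) and only when gamma rate categories are enabled; otherwise the
#' parameters are returned unchanged.
#'
#' @inheritParams optimize_rates
#' @param iteration Current iteration number of the surrounding search
#'   (1-based).
#' @return An \code{nr_model}, possibly with updated \code{alpha}.
#' @export
optimize_alpha <- function(params, rooted, msa, iteration) {
  if (params$n_cats <= 1L || iteration %% 10L != 0L) return(params)
  engine <- .make_engine(rooted$tree, msa)
  .optimize_alpha_impl(engine, rooted$edge, rooted$beta, params, iteration)$params
}
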