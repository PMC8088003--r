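# Root-search drivers: heuristic search mode and per-branch exhaustive mode
# with likelihood weight ratios.

#' Configuration for a root search
#'
#' @param mode \code{"search"} (heuristic, returns the best root) or
#'   \code{"exhaustive"} (evaluates every branch and reports likelihood
#'   weight ratios).
#' @param init_strategy How search mode picks starting branches:
#'   \code{"modified_mad"} ranks branches by the approximate
#'   minimal-ancestor-deviation score ([mad_rank_edges()]), \code{"random"}
#'   samples branches uniformly (the unbiased fallback).
#' @param init_fraction Fraction of branches used as starting roots
#'   (default 1\%; at least one).
#' @param top_fraction Fraction of branches whose root position is fully
#'   optimized in each search iteration (default 1\%; at least one).
#' @param atol Stopping tolerance on the log-likelihood change between
#'   iterations.
#' @param brtol Stopping tolerance on the root-position change along a
#'   branch (used by early stopping).
#' @param early_stop Stop when the best root lands on the same branch as in
#'   the previous iteration with \code{|d beta| < brtol}.  Faster, but the
#'   reported likelihoods are not fully optimized.
#' @param max_iters Hard iteration cap (default 500; a safety net, not a
#'   tuning parameter).
#' @param seed Integer seed controlling all randomness of the run.
#' @param n_cats Number of discrete-gamma categories (1 = no gamma, the
#'   default).
#' @param p_inv Proportion of invariant sites (0 disables the class; this
#'   proportion is held fixed, not optimized).
#' @param optimize_model Optimize the substitution model (rates,
#'   frequencies, gamma shape) during the search.  Set to \code{FALSE} to
#'   score root positions under the supplied fixed parameters.
#' @param params Starting model parameters (an \code{nr_model}); defaults to
#'   [default_params()].  Each search start / exhaustive branch
#'   re-initializes from these to avoid local optima.
#' @param lwr_threshold Branch annotations with a likelihood weight ratio
#'   below this value are suppressed in newick output (default 1e-4).
#' @return An object of class \code{nr_config}.
#' @export
search_config <- function(mode = c("search", "exhaustive"),
                          init_strategy = c("modified_mad", "random"),
                          init_fraction = 0.01, top_fraction = 0.01,
                          atol = 1e-4, brtol = 1e-8, early_stop = FALSE,
                          max_iters = 500L, seed = 1L,
                          n_cats = 1L, p_inv = 0,
                          optimize_model = TRUE, params = NULL,
                          lwr_threshold = 1e-4) {
  mode <- match.arg(mode)
  init_strategy <- match.arg(init_strategy)
  stopifnot(init_fraction > 0, init_fraction <= 1,
            top_fraction > 0, top_fraction <= 1,
            atol > 0, brtol > 0, max_iters >= 1)
  if (is.null(params)) params <- default_params(n_cats = n_cats, p_inv = p_inv)
  stopifnot(inherits(params, "nr_model"))
  structure(list(mode = mode, init_strategy = init_strategy,
                 init_fraction = init_fraction, top_fraction = top_fraction,
                 atol = atol, brtol = brtol, early_stop = early_stop,
                 max_iters = as.integer(max_iters), seed = as.integer(seed),
                 n_cats = as.integer(n_cats), p_inv = p_inv,
                 optimize_model = isTRUE(optimize_model), params = params,
                 lwr_threshold = lwr_threshold),
            class = "nr_config")
}

# Run expr with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Select starting branches for the root search
#'
#' Picks \code{ceiling(fraction * n_edges)} branches (at least one), either
#' the top of the approximate-MAD ranking or a uniform random sample.
#'
#' @param tree An \code{nr_tree}.
#' @param strategy \code{"modified_mad"} or \code{"random"}.
#' @param fraction Fraction of branches to select, in \eqn{(0, 1]}.
#' @param seed Seed for the random strategy.
#' @return Integer vector of edge ids.
#' @export
select_initial_roots <- function(tree, strategy = c("modified_mad", "random"),
                                 fraction = 0.01, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(fraction > 0, fraction <= 1)
  E <- n_edges(tree)
  k <- max(1L, as.integer(ceiling(fraction * E)))
  if (strategy == "modified_mad") utils::head(mad_rank_edges(tree), k)
  else .with_seed(seed, sample(seq_len(E), k))
}

# Midpoint LLs for every edge, shared-engine implementation.
.midpoint_impl <- function(engine, params) {
  E <- n_edges(engine$tree)
  lls <- vapply(seq_len(E), function(e)
    tryCatch(.ll_rooted_params(engine, e, 0.5, params),
             error = function(err) -Inf),
    numeric(1))
  ord <- order(-lls, seq_len(E))
  data.frame(edge = ord, ll = lls[ord])
}

#' Rank all branches by midpoint root log-likelihood
#'
#' Scores every branch by the log-likelihood of rooting at its midpoint
#' (\code{beta = 0.5}) under fixed model parameters, in descending order.
#' This is the cheap per-iteration screen from which the top candidates are
#' then fully optimized.
#'
#' @param tree An \code{nr_tree}.
#' @param params An \code{nr_model}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}.
#' @return Data frame with columns \code{edge} and \code{ll}, best first.
#' @export
midpoint_ll_ranking <- function(tree, params, msa) {
  .midpoint_impl(.make_engine(tree, msa), params)
}

#' Likelihood weight ratios
#'
#' Converts per-branch log-likelihoods into normalized weights
#' \eqn{w_i = \exp(\ell_i - \max_j \ell_j) / \sum_j \exp(\ell_j - \max_j
#' \ell_j)}.  Weights sum to 1 and are invariant to adding a constant to
#' all log-likelihoods.  Non-finite entries get weight 0.
#'
#' @param lls Numeric vector of log-likelihoods (at least one finite).
#' @return Numeric vector of weights summing to 1.
#' @export
compute_lwr <- function(lls) {
  lls <- as.numeric(lls)
  lls[is.na(lls)] <- -Inf
  if (!any(is.finite(lls)))
    stop("no finite log-likelihoods to weight", call. = FALSE)
  w <- exp(lls - max(lls))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Early-stopping test for consecutive root placements
#'
#' @param prev,cur Root placements: \code{nr_rooted} objects or lists with
#'   \code{edge} and \code{beta}.
#' @param brtol Tolerance on the root-position change along the branch.
#' @return \code{TRUE} iff both placements are on the same branch and
#'   \code{|prev$beta - cur$beta| < brtol}.
#' @export
early_stop_check <- function(prev, cur, brtol) {
  if (is.null(prev) || is.null(cur)) return(FALSE)
  prev$edge == cur$edge && abs(prev$beta - cur$beta) < brtol
}

# One search-mode start: iterate model optimization and root relocation.
.search_one <- function(engine, start_edge, config) {
  tree <- engine$tree
  E <- n_edges(tree)
  n_top <- max(1L, as.integer(ceiling(config$top_fraction * E)))
  params <- config$params               # per-start re-initialization
  edge <- start_edge; beta <- 0.5
  prev_ll <- -Inf; prev_place <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (config$optimize_model) {
      params <- .optimize_rates_impl(engine, edge, beta, params)$params
      params <- .optimize_freqs_impl(engine, edge, beta, params)$params
      params <- .optimize_alpha_impl(engine, edge, beta, params, iter)$params
    }
    rank <- .midpoint_impl(engine, params)
    top <- rank$edge[seq_len(n_top)]
    cand <- lapply(top, function(e) .optimize_beta_impl(engine, e, params))
    lls <- vapply(cand, `[[`, numeric(1), "ll")
    k <- which.max(lls)
    cur <- list(edge = top[k], beta = cand[[k]]$beta, ll = lls[k])
    done <- abs(cur$ll - prev_ll) < config$atol ||
      (config$early_stop &&
         early_stop_check(prev_place, cur, config$brtol)) ||
      iter >= config$max_iters
    edge <- cur$edge; beta <- cur$beta
    prev_ll <- cur$ll; prev_place <- cur
    if (done) break
  }
  list(edge = edge, beta = beta, ll = prev_ll, params = params,
       iterations = iter)
}

#' Heuristic root search
#'
#' For each starting branch (chosen by [select_initial_roots()]), iterates:
#' optimize the model parameters on the current rooted tree (rates,
#' frequencies, and -- every 10th iteration -- the gamma shape), rank all
#' branches by midpoint root likelihood, fully optimize the root position on
#' the top-ranked branches, and move the root to the best one.  Iteration
#' stops when the log-likelihood improves by less than \code{atol}, when
#' early stopping triggers, or after \code{max_iters} iterations.  The best
#' placement over all starts is reported.  Model parameters re-initialize at
#' every start to avoid local optima of the rooting likelihood surface.
#'
#' @param tree An \code{nr_tree}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}.
#' @param config An \code{nr_config} from [search_config()].
#' @return An object of class \code{nr_report}; see [exhaustive_mode()] for
#'   the fields.
#' @export
search_mode <- function(tree, msa, config = search_config()) {
  stopifnot(inherits(tree, "nr_tree"), inherits(config, "nr_config"))
  engine <- .make_engine(tree, msa)
  starts <- select_initial_roots(tree, config$init_strategy,
                                 config$init_fraction, config$seed)
  results <- lapply(starts, function(s) {
    tryCatch(.search_one(engine, s, config),
             error = function(e) {
               warning("search start on edge ", s, " failed: ",
                       conditionMessage(e), call. = FALSE)
               NULL
             })
  })
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("every search start failed", call. = FALSE)
  results <- results[ok]; starts <- starts[ok]
  lls <- vapply(results, `[[`, numeric(1), "ll")
  best <- results[[which.max(lls)]]
  tab <- data.frame(edge = vapply(results, `[[`, numeric(1), "edge"),
                    beta = vapply(results, `[[`, numeric(1), "beta"),
                    ll = lls,
                    start_edge = starts,
                    iterations = vapply(results, `[[`, numeric(1), "iterations"))
  structure(list(mode = "search", tree = tree, table = tab, best = best,
                 config = config),
            class = "nr_report")
}

# Exhaustive evaluation of a single branch as root.
.exhaustive_one <- function(engine, eid, config) {
  params <- config$params               # per-branch re-initialization
  beta <- 0.5; prev_ll <- -Inf; prev_beta <- NA_real_; ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (config$optimize_model) {
      params <- .optimize_rates_impl(engine, eid, beta, params)$params
      params <- .optimize_freqs_impl(engine, eid, beta, params)$params
      params <- .optimize_alpha_impl(engine, eid, beta, params, iter)$params
    }
    opt <- .optimize_beta_impl(engine, eid, params)
    ll <- opt$ll
    done <- abs(ll - prev_ll) < config$atol ||
      (config$early_stop && !is.na(prev_beta) &&
         abs(opt$beta - prev_beta) < config$brtol) ||
      iter >= config$max_iters ||
      !config$optimize_model
    prev_ll <- ll; prev_beta <- beta <- opt$beta
    if (done) break
  }
  list(edge = eid, beta = beta, ll = ll, params = params, iterations = iter)
}

#' Exhaustive root evaluation with likelihood weight ratios
#'
#' Evaluates every branch of the tree as a candidate root.  For each branch
#' the model parameters are re-initialized and the model-optimization /
#' root-position-optimization cycle is iterated under the same stopping
#' rules as search mode.  The per-branch maximized log-likelihoods are then
#' converted into likelihood weight ratios ([compute_lwr()]) quantifying the
#' support for a root on each branch, and the best placement is annotated
#' onto the tree.
#'
#' Individual branch failures are recorded (weight 0) with a warning rather
#' than aborting the run.  When \code{checkpoint} is given, each completed
#' branch is appended to a crash-safe log and a restarted run resumes after
#' the last complete record ([checkpoint_resume()]).
#'
#' @inheritParams search_mode
#' @param checkpoint Optional path to an append-only checkpoint log.
#' @return An object of class \code{nr_report}: a list with \code{mode},
#'   \code{tree}, a per-branch \code{table} (edge, beta, ll, lwr),
#'   \code{best} (edge, beta, ll, params), the annotated rooted
#'   \code{newick} string, and the \code{config}.
#' @export
exhaustive_mode <- function(tree, msa, config = search_config(mode = "exhaustive"),
                            checkpoint = NULL) {
  stopifnot(inherits(tree, "nr_tree"), inherits(config, "nr_config"))
  engine <- .make_engine(tree, msa)
  E <- n_edges(tree)
  done_records <- list()
  units <- seq_len(E)
  if (!is.null(checkpoint)) {
    res <- checkpoint_resume(checkpoint, units)
    units <- res$remaining
    done_records <- res$records
  }
  fresh <- lapply(units, function(e) {
    rec <- tryCatch(.exhaustive_one(engine, e, config),
                    error = function(err) {
                      warning("root evaluation on edge ", e, " failed: ",
                              conditionMessage(err), call. = FALSE)
                      list(edge = e, beta = NA_real_, ll = NA_real_,
                           params = NULL, iterations = NA_integer_)
                    })
    if (!is.null(checkpoint)) checkpoint_append(checkpoint, rec)
    rec
  })
  records <- c(done_records, fresh)
  edges <- vapply(records, `[[`, numeric(1), "edge")
  records <- records[order(edges)]
  beta <- vapply(records, `[[`, numeric(1), "beta")
  ll <- vapply(records, `[[`, numeric(1), "ll")
  lwr <- compute_lwr(ll)
  k <- which.max(ifelse(is.na(ll), -Inf, ll))
  best <- records[[k]]
  ann <- list()
  for (e in seq_len(E)) {
    if (!is.na(lwr[e]) && lwr[e] >= config$lwr_threshold)
      ann[[as.character(e)]] <- c(LWR = lwr[e], alpha = beta[e], LL = ll[e])
  }
  rooted <- place_root(tree, best$edge, best$beta)
  nwk <- write_newick_annotated(rooted, ann)
  tab <- data.frame(edge = seq_len(E), beta = beta, ll = ll, lwr = lwr)
  structure(list(mode = "exhaustive", tree = tree, table = tab, best = best,
                 newick = nwk, config = config),
            class = "nr_report")
}

#' @export
print.nr_report <- function(x, ...) {
  cat(sprintf("Root placement report (%s mode)\n", x$mode))
  t <- x$tree$length[x$best$edge]
  cat(sprintf("  best root: edge %d, beta = %.4f (split %.4g + %.4g), logL = %.4f\n",
              x$best$edge, x$best$beta, x$best$beta * t,
              (1 - x$best$beta) * t, x$best$ll))
  if (x$mode == "exhaustive") {
    top <- utils::head(x$table[order(-x$table$lwr), ], 5)
    cat("  top branches by likelihood weight ratio:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    edge %3d  LWR %.4f  logL %.4f\n",
                  top$edge[i], top$lwr[i], top$ll[i]))
  }
  invisible(x)
}
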