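# Felsenstein pruning under UNREST+G+I.
#
# Conditional likelihood vectors (CLVs) are 4 x n_patterns matrices.  The
# tree is evaluated about the rooted edge: the CLVs of the two subtrees
# hanging off the split edge's endpoints are computed once per (edge,
# parameters) and reused across root positions beta, since only the two
# root-adjacent transition matrices depend on beta.

# Pruning engine: everything that depends only on tree + alignment.
.make_engine <- function(tree, msa) {
  pmsa <- .as_pmsa(msa)
  if (!setequal(tree$labels, pmsa$labels) ||
      length(tree$labels) != length(pmsa$labels))
    stop("taxa of tree and alignment do not match exactly", call. = FALSE)
  ord <- match(tree$labels, pmsa$labels)
  npat <- ncol(pmsa$patterns)
  tipclv <- lapply(seq_along(ord), function(i)
    .tip_clv(pmsa$patterns[ord[i], ]))
  # per-pattern 0/1 indicator of states compatible with *every* taxon;
  # a pattern can be invariant only where this is non-zero
  inv_ind <- Reduce(`*`, tipclv)
  list(tree = tree, npat = npat, weights = as.numeric(pmsa$weights),
       tipclv = tipclv, inv_ind = inv_ind)
}

# CLV of the subtree rooted at the start node of `po`, for one rate class.
# Returns list(clv = 4 x npat, logs = per-pattern log scaling).
.side_clv <- function(engine, po, ed, rate, start) {
  tree <- engine$tree
  if (!nrow(po)) {  # side is a single tip
    return(list(clv = engine$tipclv[[start]], logs = numeric(engine$npat)))
  }
  clv <- vector("list", tree$nnode)
  logs <- numeric(engine$npat)
  nr <- nrow(po)
  for (i in seq_len(nr)) {
    parent <- po[i, 1L]; child <- po[i, 2L]; eid <- po[i, 3L]
    P <- .pmat(ed, tree$length[eid] * rate)
    cc <- if (child <= tree$ntips) engine$tipclv[[child]] else clv[[child]]
    cur <- clv[[parent]]
    m <- if (is.null(cur)) P %*% cc else cur * (P %*% cc)
    # underflow guard: column sums bound the column maxima within a factor
    # of 4.  Checking every few joins is enough: entries shrink gradually
    # and the 1e-200 trigger leaves ~50 orders of magnitude of headroom
    # before double-precision underflow at 1e-308.
    if (i %% 4L == 0L || i == nr) {
      cs <- .colSums(m, 4L, ncol(m))
      if (min(cs) < 1e-200) {
        sc <- pmax(cs, 1e-300)
        m <- m * rep(1 / sc, each = 4L)
        logs <- logs + log(sc)
      }
    }
    clv[[parent]] <- m
  }
  list(clv = clv[[start]], logs = logs)
}

# Per-(edge, params) cache enabling cheap LL(beta) evaluations.
.root_cache <- function(engine, eid, params) {
  tree <- engine$tree
  orient <- .orient_edge(tree, eid)
  Q <- build_rate_matrix(params)
  ed <- .eig_decomp(Q$Q)
  cls <- .site_rate_list(params)
  var_rates <- cls$rate[!cls$invariant]
  var_probs <- cls$prob[!cls$invariant]
  sides <- lapply(var_rates, function(r) {
    list(A = .side_clv(engine, orient$poA, ed, r, orient$a),
         B = .side_clv(engine, orient$poB, ed, r, orient$b))
  })
  list(eid = eid, t = orient$t, ed = ed, params = params,
       var_rates = var_rates, var_probs = var_probs, sides = sides,
       p_inv = params$p_inv)
}

# Log-likelihood at a root position beta, given a cache.
.ll_at_beta <- function(engine, cache, beta) {
  freqs <- rbind(unname(cache$params$freqs))   # 1x4 for vector-matrix BLAS
  t <- cache$t
  nvar <- length(cache$var_rates)
  site <- vector("list", nvar)
  logs <- vector("list", nvar)
  for (c in seq_len(nvar)) {
    r <- cache$var_rates[c]
    PA <- .pmat(cache$ed, beta * t * r)
    PB <- .pmat(cache$ed, (1 - beta) * t * r)
    sA <- cache$sides[[c]]$A; sB <- cache$sides[[c]]$B
    site[[c]] <- drop(freqs %*% ((PA %*% sA$clv) * (PB %*% sB$clv)))
    logs[[c]] <- sA$logs + sB$logs
  }
  if (nvar == 1L && cache$p_inv == 0) {        # common case: no rate mixture
    tot <- site[[1L]]
    scale <- logs[[1L]]
  } else {
    Mlog <- do.call(pmax, logs)
    if (cache$p_inv > 0) {
      invlik <- drop(freqs %*% engine$inv_ind)
      Mlog <- pmax(Mlog, ifelse(invlik > 0, 0, -Inf))
    }
    tot <- 0
    for (c in seq_len(nvar))
      tot <- tot + cache$var_probs[c] * site[[c]] * exp(logs[[c]] - Mlog)
    if (cache$p_inv > 0)
      tot <- tot + cache$p_inv * invlik * exp(-Mlog)
    scale <- Mlog
  }
  if (any(tot <= 0) || any(!is.finite(tot))) {
    bad <- which(tot <= 0 | !is.finite(tot))[1]
    stop("non-finite site likelihood at pattern ", bad,
         " (root edge ", cache$eid, ", beta = ", beta, ")", call. = FALSE)
  }
  sum(engine$weights * (log(tot) + scale))
}

#' Log-likelihood of a rooted tree
#'
#' Computes the pruning log-likelihood of the alignment given a rooted tree
#' under UNREST+G+I.  Site patterns are weighted by their multiplicity;
#' gamma categories are mixed with equal probabilities and the invariant
#' class contributes only for patterns whose non-ambiguous characters are
#' identical.  Per-pattern log-scaling protects against numerical underflow
#' on large trees.
#'
#' @param rooted An \code{nr_rooted} from [place_root()].
#' @param params An \code{nr_model}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}; taxa must match the tree
#'   exactly.
#' @return The log-likelihood (a single finite number).
#' @export
log_likelihood <- function(rooted, params, msa) {
  stopifnot(inherits(rooted, "nr_rooted"), inherits(params, "nr_model"))
  engine <- .make_engine(rooted$tree, msa)
  cache <- .root_cache(engine, rooted$edge, params)
  .ll_at_beta(engine, cache, rooted$beta)
}

#' Log-likelihood as a function of the root position on an edge
#'
#' Equivalent to \code{log_likelihood(place_root(tree, edge, beta), params,
#' msa)}.  The conditional likelihoods of the two subtrees flanking the
#' split edge do not depend on \code{beta}, so repeated evaluations on the
#' same edge share them (see [optimize_beta()]).
#'
#' @param edge Edge id.
#' @param beta Root position in \eqn{[0, 1]}.
#' @param params An \code{nr_model}.
#' @param tree An \code{nr_tree}.
#' @param msa An \code{nr_msa} or \code{nr_pmsa}.
#' @return The log-likelihood.
#' @export
root_ll <- function(edge, beta, params, tree, msa) {
  log_likelihood(place_root(tree, edge, beta), params, msa)
}

# Finite-difference derivative of LL(beta) with a cache.
.dll_at_beta <- function(engine, cache, beta) {
  h <- max(1e-7, 1e-5 * beta * (1 - beta))
  lo <- beta - h; hi <- beta + h
  if (lo < 0) lo <- beta
  if (hi > 1) hi <- beta
  if (hi == lo) return(0)
  (.ll_at_beta(engine, cache, hi) - .ll_at_beta(engine, cache, lo)) / (hi - lo)
}

#' Derivative of the root-position log-likelihood
#'
#' Central finite difference of LL(\code{beta}) with adaptive step
#' \eqn{h = \max(10^{-7}, 10^{-5}\beta(1-\beta))}; one-sided at the interval
#' boundaries.  Used by the bracketing + Brent root-position optimizer.
#'
#' @inheritParams root_ll
#' @return Numeric derivative d LL / d beta.
#' @export
dll_dbeta <- function(edge, beta, params, tree, msa) {
  engine <- .make_engine(tree, msa)
  cache <- .root_cache(engine, .check_edge(tree, edge), params)
  .dll_at_beta(engine, cache, beta)
}
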