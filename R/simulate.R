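# Synthetic data: random rooted trees, random UNREST parameters, and
# sequence simulation along the tree, used for validation and recovery
# studies.

#' Configuration for a simulation / root-recovery trial
#'
#' Defaults reproduce the validation study conditions: branch lengths drawn
#' from an exponential distribution with scale 0.5 (expected substitutions
#' per site), substitution rates drawn uniformly on \eqn{[0.01, 1.01]}, and
#' base frequencies from normalized exponential draws.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param n_sites Alignment length (>= 1).
#' @param seed Integer seed for the whole trial.
#' @param bl_scale Exponential scale (mean) of branch lengths.
#' @param rate_bounds Lower and upper bound of the uniform rate draws.
#' @return An object of class \code{nr_simconfig}.
#' @export
sim_config <- function(n_taxa, n_sites, seed = 1L, bl_scale = 0.5,
                       rate_bounds = c(0.01, 1.01)) {
  stopifnot(n_taxa >= 3, n_sites >= 1, bl_scale > 0,
            length(rate_bounds) == 2L, rate_bounds[1] >= 0,
            rate_bounds[2] > rate_bounds[1])
  structure(list(n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
                 seed = as.integer(seed), bl_scale = bl_scale,
                 rate_bounds = rate_bounds),
            class = "nr_simconfig")
}

#' Generate a random rooted binary tree
#'
#' Topology by uniform random joins (coalescent-style: repeatedly merge a
#' uniformly chosen pair of lineages), with i.i.d. exponential branch
#' lengths of scale \code{bl_scale}.  The result is returned as an
#' \code{nr_rooted}: the unrooted tree plus the (edge, beta) placement that
#' records where the true root sits, which is what recovery studies compare
#' against.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param seed Optional seed; \code{NULL} uses the current RNG state.
#' @param bl_scale Mean branch length (expected substitutions per site).
#' @return An \code{nr_rooted} whose \code{$tree} has \code{2 n_taxa - 3}
#'   edges.
#' @export
random_rooted_tree <- function(n_taxa, seed = NULL, bl_scale = 0.5) {
  stopifnot(n_taxa >= 3)
  gen <- function() {
    n <- as.integer(n_taxa)
    labels <- sprintf("t%d", seq_len(n))
    # rooted: internals n+1 .. 2n-1, root created last
    parent <- integer(0); child <- integer(0); plen <- numeric(0)
    pool <- seq_len(n)
    nxt <- n + 1L
    while (length(pool) > 1L) {
      pick <- sample(length(pool), 2L)
      parent <- c(parent, nxt, nxt)
      child <- c(child, pool[pick])
      plen <- c(plen, stats::rexp(2L, rate = 1 / bl_scale))
      pool <- c(pool[-pick], nxt)
      nxt <- nxt + 1L
    }
    root <- nxt - 1L
    # unroot: merge the two root-adjacent edges
    at_root <- which(parent == root)
    c1 <- child[at_root[1L]]; c2 <- child[at_root[2L]]
    t1 <- plen[at_root[1L]]; t2 <- plen[at_root[2L]]
    keep <- setdiff(seq_along(parent), at_root)
    edge <- cbind(c(parent[keep], c1), c(child[keep], c2))
    elen <- c(plen[keep], t1 + t2)
    tree <- .new_tree(labels, edge, elen)
    beta <- if (t1 + t2 > 0) t1 / (t1 + t2) else 0.5
    place_root(tree, nrow(edge), beta)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Draw random UNREST model parameters
#'
#' The 12 substitution rates are i.i.d. uniform on \code{rate_bounds}
#' (default \eqn{[0.01, 1.01]}, spanning two orders of magnitude, which
#' makes the process strongly non-reversible with high probability); base
#' frequencies are i.i.d. exponential draws normalized to sum to 1.
#'
#' @param seed Optional seed; \code{NULL} uses the current RNG state.
#' @param rate_bounds Uniform bounds for the rate draws.
#' @param n_cats,p_inv Passed through to [model_params()].
#' @param alpha Gamma shape used when \code{n_cats > 1}.
#' @return An \code{nr_model}.
#' @export
random_model <- function(seed = NULL, rate_bounds = c(0.01, 1.01),
                         n_cats = 1L, p_inv = 0, alpha = 1.0) {
  gen <- function() {
    rates <- stats::runif(12L, rate_bounds[1], rate_bounds[2])
    f <- stats::rexp(4L)
    model_params(rates = rates, freqs = f / sum(f), alpha = alpha,
                 n_cats = n_cats, p_inv = p_inv)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Simulate an alignment along a rooted tree
#'
#' Root states are drawn from the model's root frequencies; states then
#' evolve edge by edge using the UNREST transition matrices.  Each site is
#' independently assigned a rate class (gamma category or invariant class)
#' first, and all transitions on that site use the class rate.  No indels
#' are simulated: the output is a gap-free alignment of exactly
#' \code{n_sites} columns.
#'
#' @param rooted An \code{nr_rooted} (e.g. from [random_rooted_tree()]).
#' @param params An \code{nr_model}.
#' @param n_sites Number of sites to simulate.
#' @param seed Optional seed; \code{NULL} uses the current RNG state.
#' @return An \code{nr_msa}.
#' @export
simulate_msa <- function(rooted, params, n_sites, seed = NULL) {
  stopifnot(inherits(rooted, "nr_rooted"), inherits(params, "nr_model"),
            n_sites >= 1)
  gen <- function() {
    tree <- rooted$tree
    n_sites <- as.integer(n_sites)
    Q <- build_rate_matrix(params)
    ed <- .eig_decomp(Q$Q)
    cls <- site_rates(params)
    cl_of <- sample.int(nrow(cls), n_sites, replace = TRUE, prob = cls$prob)
    evolve <- function(parent_states, elen) {
      out <- integer(n_sites)
      for (ci in seq_len(nrow(cls))) {
        s_len <- elen * cls$rate[ci]
        P <- .pmat(ed, s_len)
        for (s in 1:4) {
          idx <- which(cl_of == ci & parent_states == s)
          if (length(idx))
            out[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                   prob = P[s, ])
        }
      }
      out
    }
    states <- matrix(NA_integer_, tree$nnode, n_sites)
    root_states <- sample.int(4L, n_sites, replace = TRUE, prob = params$freqs)
    orient <- .orient_edge(tree, rooted$edge)
    states[orient$a, ] <- evolve(root_states, rooted$beta * orient$t)
    states[orient$b, ] <- evolve(root_states, (1 - rooted$beta) * orient$t)
    for (po in list(orient$poA, orient$poB)) {
      for (i in rev(seq_len(nrow(po)))) {   # preorder: parents first
        states[po[i, 2L], ] <- evolve(states[po[i, 1L], ],
                                      tree$length[po[i, 3L]])
      }
    }
    seqs <- apply(states[seq_len(tree$ntips), , drop = FALSE], 1L,
                  function(s) paste(.nuc[s], collapse = ""))
    .new_msa(tree$labels, seqs)
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Run one root-recovery trial
#'
#' Simulates a rooted tree, random model and alignment under \code{config},
#' discards the root, runs the heuristic root search on the unrooted tree,
#' and scores the inferred root against the true one with the normalized
#' topological root distance.
#'
#' @param config An \code{nr_simconfig} from [sim_config()].
#' @param search Optional \code{nr_config} controlling the search; defaults
#'   to [search_config()] with the trial's seed.
#' @return List with \code{distance} (normalized root distance),
#'   \code{recovered} (TRUE iff the true root branch was chosen),
#'   \code{true_edge}, \code{inferred_edge}, \code{ll} and the search
#'   \code{report}.
#' @export
run_recovery_trial <- function(config, search = NULL) {
  stopifnot(inherits(config, "nr_simconfig"))
  sim <- .with_seed(config$seed, {
    rooted <- random_rooted_tree(config$n_taxa, bl_scale = config$bl_scale)
    model <- random_model(rate_bounds = config$rate_bounds)
    msa <- simulate_msa(rooted, model, config$n_sites)
    list(rooted = rooted, model = model, msa = msa)
  })
  if (is.null(search)) search <- search_config(seed = config$seed)
  report <- search_mode(sim$rooted$tree, sim$msa, search)
  d <- root_distance(sim$rooted$tree, sim$rooted$edge, report$best$edge)
  list(distance = d,
       recovered = report$best$edge == sim$rooted$edge,
       true_edge = sim$rooted$edge, inferred_edge = report$best$edge,
       ll = report$best$ll, report = report, model = sim$model,
       rooted = sim$rooted, msa = sim$msa)
}
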