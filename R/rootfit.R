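# User-facing model-fitting interface: root_fit() and its S3 methods.

#' Fit a maximum-likelihood root placement
#'
#' The main entry point of the package.  Given an unrooted binary tree with
#' branch lengths (expected substitutions per site) and a matching DNA
#' alignment, finds the root placement maximizing the likelihood under the
#' non-reversible UNREST(+G+I) model.  In \code{"search"} mode a heuristic
#' iterative search returns the best root; in \code{"exhaustive"} mode every
#' branch is evaluated and annotated with its likelihood weight ratio (LWR),
#' quantifying root-placement uncertainty.
#'
#' @param tree An \code{nr_tree}, an \pkg{ape} \code{phylo}, a newick
#'   string, or a path to a newick file.
#' @param msa An \code{nr_msa}/\code{nr_pmsa} or a path to a FASTA/PHYLIP
#'   file.  Taxa must match the tree exactly.
#' @param mode \code{"search"} or \code{"exhaustive"}.
#' @param rate_categories Number of discrete-gamma categories (1 = no
#'   gamma).
#' @param invariant_sites Proportion of invariant sites (0 disables).
#' @param early_stop Enable the early-stopping rule (see
#'   [search_config()]).
#' @param seed Integer seed.
#' @param ... Further arguments to [search_config()] (e.g. \code{atol},
#'   \code{brtol}, \code{init_strategy}, \code{optimize_model}).
#' @return An object of class \code{root_fit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{plot} and
#'   \code{simulate}.
#' @examples
#' rt <- random_rooted_tree(8, seed = 5)
#' m <- random_model(seed = 5)
#' aln <- simulate_msa(rt, m, 500, seed = 5)
#' fit <- root_fit(rt$tree, aln, seed = 5)
#' fit
#' coef(fit)
#' @export
root_fit <- function(tree, msa, mode = c("search", "exhaustive"),
                     rate_categories = 1L, invariant_sites = 0,
                     early_stop = FALSE, seed = 1L, ...) {
  mode <- match.arg(mode)
  tree <- .coerce_tree(tree)
  msa <- .coerce_msa(msa)
  cfg <- search_config(mode = mode, n_cats = rate_categories,
                       p_inv = invariant_sites, early_stop = early_stop,
                       seed = seed, ...)
  report <- if (mode == "exhaustive") exhaustive_mode(tree, msa, cfg)
  else search_mode(tree, msa, cfg)
  pm <- .as_pmsa(msa)
  structure(list(report = report, tree = tree, msa = pm,
                 n_sites = sum(pm$weights), config = cfg,
                 call = match.call()),
            class = "root_fit")
}

.coerce_tree <- function(tree) {
  if (inherits(tree, "nr_tree")) return(tree)
  if (inherits(tree, "phylo")) return(.from_phylo(tree))
  if (is.character(tree) && length(tree) == 1L) {
    if (grepl("\\(", tree)) return(parse_newick(tree))
    return(read_newick(tree))
  }
  stop("cannot interpret `tree` as a phylogenetic tree", call. = FALSE)
}

.coerce_msa <- function(msa) {
  if (inherits(msa, "nr_msa") || inherits(msa, "nr_pmsa")) return(msa)
  if (is.character(msa) && length(msa) == 1L) return(read_msa(msa))
  stop("cannot interpret `msa` as an alignment", call. = FALSE)
}

#' Rooted tree from a fitted root placement
#'
#' @param object A \code{root_fit}.
#' @return An \code{nr_rooted} at the fitted (edge, beta).
#' @export
rooted_tree <- function(object) {
  stopifnot(inherits(object, "root_fit"))
  place_root(object$tree, object$report$best$edge, object$report$best$beta)
}

#' @export
print.root_fit <- function(x, ...) {
  cat("Maximum-likelihood root placement (UNREST",
      if (x$config$n_cats > 1) paste0("+G", x$config$n_cats),
      if (x$config$p_inv > 0) "+I", ")\n", sep = "")
  cat(sprintf("  %d taxa, %d sites (%d patterns), %d candidate branches\n",
              x$tree$ntips, x$n_sites, ncol(x$msa$patterns),
              n_edges(x$tree)))
  print(x$report)
  invisible(x)
}

#' @export
coef.root_fit <- function(object, ...) {
  p <- object$report$best$params
  out <- c(p$rates, p$freqs)
  if (p$n_cats > 1) out <- c(out, alpha = p$alpha)
  if (p$p_inv > 0) out <- c(out, p_inv = p$p_inv)
  out
}

#' @export
logLik.root_fit <- function(object, ...) {
  p <- object$report$best$params
  # 12 rates (one scale absorbed by the unit-rate normalization) + 3 free
  # frequencies + the root position
  df <- 11L + 3L + 1L + (p$n_cats > 1L)
  structure(object$report$best$ll, df = df, nobs = object$n_sites,
            class = "logLik")
}

#' @export
summary.root_fit <- function(object, ...) {
  rep <- object$report
  structure(list(fit = object, mode = rep$mode, best = rep$best,
                 table = rep$table,
                 lwr_top = if (rep$mode == "exhaustive")
                   utils::head(rep$table[order(-rep$table$lwr), ], 10)),
            class = "summary.root_fit")
}

#' @export
print.summary.root_fit <- function(x, ...) {
  print(x$fit)
  cat("\nModel parameters at the best root:\n")
  print(x$best$params)
  if (!is.null(x$lwr_top)) {
    cat("\nPer-branch root support (top 10 by LWR):\n")
    print(x$lwr_top, row.names = FALSE)
  }
  invisible(x)
}

#' Plot per-branch root support
#'
#' For an exhaustive fit, draws the likelihood weight ratio of every branch
#' (the posterior-like support for the root sitting on that branch); for a
#' search fit, the optimized log-likelihood of each evaluated start.
#'
#' @param x A \code{root_fit}.
#' @param ... Passed to [graphics::barplot()].
#' @return The fit, invisibly.
#' @export
plot.root_fit <- function(x, ...) {
  tab <- x$report$table
  if (x$report$mode == "exhaustive") {
    graphics::barplot(tab$lwr, names.arg = tab$edge,
                      xlab = "branch (edge id)",
                      ylab = "likelihood weight ratio", ...)
  } else {
    graphics::barplot(tab$ll - max(tab$ll), names.arg = tab$start_edge,
                      xlab = "start branch (edge id)",
                      ylab = "log-likelihood difference from best", ...)
  }
  invisible(x)
}

#' Simulate alignments from a fitted root placement
#'
#' Draws alignments of the fitted alignment's length from the fitted model
#' on the fitted rooted tree, e.g. for parametric-bootstrap checks of root
#' support.
#'
#' @param object A \code{root_fit}.
#' @param nsim Number of alignments.
#' @param seed Integer seed.
#' @param ... Ignored.
#' @return A list of \code{nr_msa} objects.
#' @export
simulate.root_fit <- function(object, nsim = 1, seed = 1L, ...) {
  rooted <- rooted_tree(object)
  p <- object$report$best$params
  .with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_msa(rooted, p, object$n_sites)))
}
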