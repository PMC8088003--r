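# Unrooted tree structure and newick input/output.
#
# An nr_tree is an unrooted binary tree on n >= 3 tips: nodes 1..n are tips
# (in the order of `labels`), nodes n+1 .. 2n-2 are internal, and the 2n-3
# edges carry stable integer ids equal to their row in `edge`.  Branch
# lengths are in expected substitutions per site.  A root is represented
# separately as an nr_rooted: the tree plus an (edge, beta) placement that
# splits a branch of length t into beta*t and (1-beta)*t.

.new_tree <- function(labels, edge, length) {
  ntips <- length(labels)
  nnode <- 2L * ntips - 2L
  storage.mode(edge) <- "integer"
  if (nrow(edge) != 2L * ntips - 3L)
    stop("not a binary unrooted tree: expected ", 2L * ntips - 3L,
         " edges, found ", nrow(edge), call. = FALSE)
  if (any(length < 0) || anyNA(length))
    stop("branch lengths must be present and non-negative", call. = FALSE)
  adj <- vector("list", nnode)
  for (i in seq_len(nrow(edge))) {
    adj[[edge[i, 1L]]] <- c(adj[[edge[i, 1L]]], i)
    adj[[edge[i, 2L]]] <- c(adj[[edge[i, 2L]]], i)
  }
  deg <- lengths(adj)
  if (any(deg[seq_len(ntips)] != 1L))
    stop("tip nodes must have degree 1", call. = FALSE)
  if (nnode > ntips && any(deg[(ntips + 1L):nnode] != 3L))
    stop("tree is not binary (multifurcation or unresolved node)", call. = FALSE)
  structure(list(ntips = ntips, labels = labels, nnode = nnode,
                 edge = edge, length = as.numeric(length), adj = adj),
            class = "nr_tree")
}

.from_phylo <- function(phy) {
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(phy$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  if (ape::Ntip(phy) < 3L)
    stop("tree must have at least 3 tips", call. = FALSE)
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (phy$Nnode != ape::Ntip(phy) - 2L)
    stop("tree is not a binary unrooted tree (multifurcations are not supported)",
         call. = FALSE)
  .new_tree(phy$tip.label, phy$edge, phy$edge.length)
}

#' Parse a newick tree
#'
#' Accepts unrooted (trifurcating base) or rooted (bifurcating base) binary
#' newick; a rooted input is silently unrooted by merging the two
#' root-adjacent branches into one, summing their lengths.  Bracketed
#' \code{[...]} comments (as emitted by [write_newick_annotated()]) are
#' stripped before parsing.  All branch lengths must be present.
#'
#' @param text A newick string.
#' @return An object of class \code{nr_tree}.
#' @seealso [read_newick()], [write_newick()], [place_root()]
#' @export
parse_newick <- function(text) {
  text <- gsub("\\[[^]]*\\]", "", text)
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) NULL)
  if (!inherits(phy, "phylo")) stop("invalid newick string", call. = FALSE)
  .from_phylo(phy)
}

#' Read a newick tree from a file
#'
#' @param path Path to a newick file (first tree is used).
#' @return An object of class \code{nr_tree}.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

# Convert to ape's phylo (for serialization and interop).
.to_phylo <- function(tree) {
  ntips <- tree$ntips
  # DFS from the first internal node; ape wants internal nodes numbered in
  # preorder starting at ntips+1
  root <- ntips + 1L
  newid <- integer(tree$nnode)
  newid[seq_len(ntips)] <- seq_len(ntips)
  nexti <- ntips + 1L
  pe <- integer(0)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  visit <- function(node, from_edge) {
    if (node > ntips) { newid[node] <<- nexti; nexti <<- nexti + 1L }
    for (eid in tree$adj[[node]]) {
      if (length(from_edge) && eid == from_edge) next
      o <- .other_end(tree, eid, node)
      parent <<- c(parent, node); child <<- c(child, o); elen <<- c(elen, tree$length[eid])
      visit(o, eid)
    }
  }
  visit(root, integer(0))
  edge <- cbind(newid[parent], newid[child])
  phy <- list(edge = edge, edge.length = elen, tip.label = tree$labels,
              Nnode = tree$nnode - ntips)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Serialize an unrooted tree to newick
#'
#' @param tree An \code{nr_tree}.
#' @param digits Significant digits for branch lengths.
#' @return A newick string with a trifurcating base.
#' @export
write_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "nr_tree"))
  ape::write.tree(.to_phylo(tree), digits = digits)
}

.other_end <- function(tree, eid, node) {
  a <- tree$edge[eid, 1L]
  if (a == node) tree$edge[eid, 2L] else a
}

.check_edge <- function(tree, edge) {
  if (!is.numeric(edge) || length(edge) != 1L || is.na(edge) ||
      edge < 1L || edge > nrow(tree$edge))
    stop("unknown edge id: ", edge, call. = FALSE)
  as.integer(edge)
}

#' Number of edges of an unrooted tree
#' @param tree An \code{nr_tree}.
#' @return Integer edge count (2n-3 for n tips).
#' @export
n_edges <- function(tree) nrow(tree$edge)

#' Place a root on a branch
#'
#' Inserts a degree-2 root on edge \code{edge}, splitting its length
#' \eqn{t} into \eqn{\beta t} and \eqn{(1-\beta) t}.  The two root-adjacent
#' branch lengths always sum to the original branch length, so tip-to-tip
#' path lengths are unchanged.
#'
#' @param tree An \code{nr_tree}.
#' @param edge Edge id (1-based, stable across the tree's lifetime).
#' @param beta Split fraction in \eqn{[0, 1]}; \code{beta*t} is the length of
#'   the branch leading to the edge's first endpoint.
#' @return An object of class \code{nr_rooted}.
#' @export
place_root <- function(tree, edge, beta = 0.5) {
  stopifnot(inherits(tree, "nr_tree"))
  edge <- .check_edge(tree, edge)
  if (!is.finite(beta) || beta < 0 || beta > 1)
    stop("beta must lie in [0, 1]", call. = FALSE)
  structure(list(tree = tree, edge = edge, beta = beta), class = "nr_rooted")
}

#' Root-adjacent branch lengths of a rooted tree
#' @param rooted An \code{nr_rooted}.
#' @return Numeric vector \code{c(beta*t, (1-beta)*t)}.
#' @export
root_branch_lengths <- function(rooted) {
  stopifnot(inherits(rooted, "nr_rooted"))
  t <- rooted$tree$length[rooted$edge]
  c(rooted$beta * t, (1 - rooted$beta) * t)
}

# Post-order edge traversal of the subtree hanging off `start` when the
# edge `avoid` is removed.  Rows (parent, child, eid), children before
# parents.
.postorder_side <- function(tree, start, avoid) {
  E <- nrow(tree$edge)
  p <- integer(E); cc <- integer(E); ee <- integer(E); k <- 0L
  sn <- integer(E + 1L); se <- integer(E + 1L); top <- 1L
  sn[1L] <- start; se[1L] <- avoid
  while (top > 0L) {
    node <- sn[top]; from <- se[top]; top <- top - 1L
    for (eid in tree$adj[[node]]) {
      if (eid == from) next
      o <- .other_end(tree, eid, node)
      k <- k + 1L
      p[k] <- node; cc[k] <- o; ee[k] <- eid
      top <- top + 1L
      sn[top] <- o; se[top] <- eid
    }
  }
  idx <- if (k) k:1L else integer(0)
  cbind(parent = p[idx], child = cc[idx], eid = ee[idx])
}

# Both-side orientation of the tree about an edge; used by the pruning
# engine and the simulator.
.orient_edge <- function(tree, eid) {
  a <- tree$edge[eid, 1L]; b <- tree$edge[eid, 2L]
  list(a = a, b = b, t = tree$length[eid],
       poA = .postorder_side(tree, a, eid),
       poB = .postorder_side(tree, b, eid))
}

# Tip indices on each side of an edge.
.tip_sides <- function(tree, eid) {
  a <- tree$edge[eid, 1L]; b <- tree$edge[eid, 2L]
  po <- .postorder_side(tree, a, eid)
  inA <- c(a, po[, "child"])
  A <- inA[inA <= tree$ntips]
  list(A = sort(A), B = sort(setdiff(seq_len(tree$ntips), A)))
}

# All-pairs node distances along the tree (branch-length weighted).
.node_dists <- function(tree) {
  n <- tree$nnode
  D <- matrix(0, n, n)
  for (s in seq_len(n)) {
    po <- .postorder_side(tree, s, 0L)  # full preorder reversed from s
    # walk preorder: parent's distance known before child
    for (i in rev(seq_len(nrow(po)))) {
      D[s, po[i, "child"]] <- D[s, po[i, "parent"]] + tree$length[po[i, "eid"]]
    }
  }
  D
}

#' Rank branches as candidate roots by approximate minimal ancestor deviation
#'
#' Scores each branch with the minimal-ancestor-deviation (MAD) statistic
#' evaluated with the candidate root fixed at the branch midpoint: the mean,
#' over all tip pairs \eqn{(i, j)} straddling the branch, of
#' \eqn{|2 d(m, i) / d(i, j) - 1|} where \eqn{m} is the midpoint.  Lower is
#' better; under a strict molecular clock the true root branch scores 0.
#' This is a screening heuristic used to pick starting branches for the
#' likelihood search, not a rooting method in itself.
#'
#' @param tree An \code{nr_tree}.
#' @return Integer vector of all edge ids, best (lowest deviation) first.
#' @export
mad_rank_edges <- function(tree) {
  stopifnot(inherits(tree, "nr_tree"))
  D <- .node_dists(tree)
  E <- n_edges(tree)
  score <- numeric(E)
  for (e in seq_len(E)) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; t <- tree$length[e]
    sides <- .tip_sides(tree, e)
    dmi <- D[a, sides$A] + t / 2
    dmj <- D[b, sides$B] + t / 2
    dij <- outer(dmi, dmj, `+`)
    dev <- abs(2 * outer(dmi, dmj, function(x, y) x) / pmax(dij, .Machine$double.eps) - 1)
    dev[dij == 0] <- 0
    score[e] <- mean(dev)
  }
  order(score, seq_len(E))
}

#' Normalized topological distance between two root placements
#'
#' Counts the nodes on the path between the midpoints of two branches and
#' divides by the total number of nodes in the tree (tips plus internal
#' nodes).  The distance is zero when the two branches coincide, and
#' \code{1/nnodes} for adjacent branches.
#'
#' @param tree An \code{nr_tree}.
#' @param true_edge,inferred_edge Edge ids.
#' @return Normalized distance in \eqn{[0, 1]}.
#' @export
root_distance <- function(tree, true_edge, inferred_edge) {
  stopifnot(inherits(tree, "nr_tree"))
  e1 <- .check_edge(tree, true_edge)
  e2 <- .check_edge(tree, inferred_edge)
  if (e1 == e2) return(0)
  # topological (hop-count) distances between nodes
  hops <- function(s) {
    h <- rep(NA_integer_, tree$nnode)
    h[s] <- 0L
    po <- .postorder_side(tree, s, 0L)
    for (i in rev(seq_len(nrow(po))))
      h[po[i, "child"]] <- h[po[i, "parent"]] + 1L
    h
  }
  h1 <- hops(tree$edge[e1, 1L]); h2 <- hops(tree$edge[e1, 2L])
  ends2 <- tree$edge[e2, ]
  count <- min(h1[ends2], h2[ends2]) + 1L
  count / tree$nnode
}

#' Serialize a rooted tree to newick with per-branch annotations
#'
#' Writes the rooted (degree-2 root) view of the tree.  Annotations are
#' emitted as \code{[&key=value,...]} comments after the branch length of
#' the corresponding branch; the branch carrying the root shows its
#' annotation on both root-adjacent halves.  Branches without an entry in
#' \code{annotations} are left plain, which is how low-support candidates
#' are suppressed in exhaustive-mode reports.
#'
#' @param rooted An \code{nr_rooted}.
#' @param annotations Named list keyed by edge id (as character); each
#'   element is a named vector/list of numeric annotation fields (e.g.
#'   \code{LWR}, \code{beta}, \code{LL}).
#' @param digits Significant digits for lengths and annotation values.
#' @return A newick string; re-parses with [parse_newick()] (which strips
#'   the comments).
#' @export
write_newick_annotated <- function(rooted, annotations = list(), digits = 8) {
  stopifnot(inherits(rooted, "nr_rooted"))
  tree <- rooted$tree
  eid <- rooted$edge; beta <- rooted$beta; t <- tree$length[eid]
  fmt <- function(x) sprintf("%.*g", digits, as.numeric(x))
  ann_str <- function(e) {
    an <- annotations[[as.character(e)]]
    if (is.null(an) || !length(an)) return("")
    paste0("[&", paste0(names(an), "=", vapply(an, fmt, ""), collapse = ","), "]")
  }
  sub <- function(node, pe) {
    kids <- setdiff(tree$adj[[node]], pe)
    if (!length(kids)) return(tree$labels[node])
    parts <- vapply(kids, function(e) {
      child <- .other_end(tree, e, node)
      paste0(sub(child, e), ":", fmt(tree$length[e]), ann_str(e))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  a <- tree$edge[eid, 1L]; b <- tree$edge[eid, 2L]
  left <- paste0(sub(a, eid), ":", fmt(beta * t), ann_str(eid))
  right <- paste0(sub(b, eid), ":", fmt((1 - beta) * t), ann_str(eid))
  paste0("(", left, ",", right, ");")
}

#' @export
print.nr_tree <- function(x, ...) {
  cat("Unrooted binary tree:", x$ntips, "tips,", n_edges(x), "edges\n")
  cat("Tips:", paste(utils::head(x$labels, 6), collapse = ", "),
      if (x$ntips > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
print.nr_rooted <- function(x, ...) {
  t <- x$tree$length[x$edge]
  cat(sprintf("Rooted tree: root on edge %d at beta = %.4g (lengths %.4g + %.4g)\n",
              x$edge, x$beta, x$beta * t, (1 - x$beta) * t))
  invisible(x)
}
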