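# Independent oracles used to validate the likelihood and optimization
# machinery.  These deliberately avoid the package's pruning/optimizer code
# paths: rate matrices are exponentiated with Matrix::expm and likelihoods
# are computed by explicit enumeration over all internal-node states.

# Build the normalized UNREST rate matrix straight from the parameter
# definition (off-diagonals row-wise AC..TG, diagonal = -rowsum, rescaled to
# unit expected rate at stationarity).
oracle_build_q <- function(params) {
  Q <- matrix(0, 4, 4)
  k <- 1L
  for (x in 1:4) for (y in 1:4) {
    if (x == y) next
    Q[x, y] <- params$rates[k]
    k <- k + 1L
  }
  diag(Q) <- -rowSums(Q)
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  pi_hat <- Re(ev$vectors[, i]); pi_hat <- pi_hat / sum(pi_hat)
  Q / sum(pi_hat * -diag(Q))
}

# Rooted edge list (parent, child, length) with the root as node nnode+1.
oracle_rooted_edges <- function(rooted) {
  tree <- rooted$tree
  root <- tree$nnode + 1L
  a <- tree$edge[rooted$edge, 1L]; b <- tree$edge[rooted$edge, 2L]
  t <- tree$length[rooted$edge]
  out <- list(c(root, a, rooted$beta * t), c(root, b, (1 - rooted$beta) * t))
  walk <- function(node, banned_edge) {
    for (eid in tree$adj[[node]]) {
      if (eid %in% banned_edge) next
      ends <- tree$edge[eid, ]
      o <- if (ends[1] == node) ends[2] else ends[1]
      out[[length(out) + 1L]] <<- c(node, o, tree$length[eid])
      walk(o, eid)
    }
  }
  walk(a, rooted$edge)
  walk(b, rooted$edge)
  do.call(rbind, out)
}

# Log-likelihood by brute-force enumeration over the states of the root and
# every internal node; tips are summed analytically through their ambiguity
# masks.  Gamma/invariant classes are mixed with the model's class table.
oracle_log_likelihood <- function(rooted, params, msa) {
  tree <- rooted$tree
  pm <- if (inherits(msa, "nr_pmsa")) msa else compress_patterns(msa)
  ord <- match(tree$labels, pm$labels)
  Qn <- oracle_build_q(params)
  edges <- oracle_rooted_edges(rooted)
  root <- tree$nnode + 1L
  internal <- c(root, setdiff(unique(as.vector(edges[, 1:2])),
                              c(root, seq_len(tree$ntips))))
  cls <- site_rates(params)
  iupac <- nrroot:::.iupac_masks
  npat <- ncol(pm$patterns)
  # joint state assignments of root + internal nodes, vectorized over rows
  states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  col_of <- match(seq_len(tree$nnode + 1L), internal)
  # transition matrices depend only on (edge, class): compute them once
  Pcls <- lapply(seq_len(nrow(cls)), function(ci)
    lapply(seq_len(nrow(edges)), function(e)
      as.matrix(Matrix::expm(Qn * edges[e, 3] * cls$rate[ci]))))
  rootpr <- unname(params$freqs)[states[, col_of[root]]]
  ll <- 0
  for (j in seq_len(npat)) {
    tipmask <- lapply(seq_len(tree$ntips), function(i)
      as.numeric(iupac[pm$patterns[ord[i], j], ]))
    lik <- 0
    for (ci in seq_len(nrow(cls))) {
      P <- Pcls[[ci]]
      pr <- rootpr
      for (e in seq_len(nrow(edges))) {
        pnode <- edges[e, 1]; cnode <- edges[e, 2]
        ps <- states[, col_of[pnode]]
        pr <- pr * if (cnode <= tree$ntips)
          (P[[e]] %*% tipmask[[cnode]])[ps]
        else P[[e]][cbind(ps, states[, col_of[cnode]])]
      }
      lik <- lik + cls$prob[ci] * sum(pr)
    }
    ll <- ll + pm$weights[j] * log(lik)
  }
  ll
}

# Plain bisection root finder, the oracle for brent_root.
oracle_bisect <- function(f, a, b, tol = 1e-12, maxit = 200) {
  fa <- f(a); fb <- f(b)
  stopifnot(sign(fa) != sign(fb))
  for (i in seq_len(maxit)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm == 0 || (b - a) / 2 < tol) return(m)
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
  }
  (a + b) / 2
}

# Quadrature oracle for the discrete-gamma category means.
oracle_gamma_rates <- function(alpha, k) {
  breaks <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  r <- vapply(seq_len(k), function(i) {
    upper <- if (i == k) Inf else breaks[i + 1]
    k * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                  breaks[i], upper, rel.tol = 1e-10)$value
  }, numeric(1))
  r / mean(r)
}

# Reference Adler-32 values computed with zlib.
adler32_reference <- list(
  list(data = raw(0), value = 1),
  list(data = charToRaw("abc"), value = 38600999),
  list(data = charToRaw("Wikipedia"), value = 300286872),
  list(data = charToRaw(strrep("A", 10000)), value = 2277632920),
  list(data = charToRaw("ACGTACGT"), value = 165806655),
  list(data = charToRaw("root placement"), value = 701629854),
  list(data = as.raw(c(0, 1, 2, 255, 254)), value = 51053057),
  list(data = rep(as.raw(0:255), 3), value = 2690809488)
)
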