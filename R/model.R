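# UNREST+G+I substitution model: rate matrix construction, transition
# probabilities, and among-site rate classes.

.nuc <- c("A", "C", "G", "T")
.rate_names <- c("AC", "AG", "AT", "CA", "CG", "CT",
                 "GA", "GC", "GT", "TA", "TC", "TG")

#' Construct UNREST+G+I model parameters
#'
#' The UNREST model has 12 free off-diagonal rates \eqn{\sigma_{xy}}
#' (ordered AC, AG, AT, CA, CG, CT, GA, GC, GT, TA, TC, TG), so it is
#' generally non-reversible: likelihood depends on the root position, which
#' is what makes root inference possible.  Root base frequencies \eqn{\pi}
#' are free parameters, distinct from the stationary distribution of the
#' rate matrix.  Among-site rate variation uses \code{n_cats} discrete-gamma
#' categories with shape \code{alpha}, plus an optional proportion
#' \code{p_inv} of invariant sites.
#'
#' @param rates Numeric vector of 12 non-negative substitution rates.
#' @param freqs Root base frequencies over (A, C, G, T); must be positive
#'   and sum to 1.
#' @param alpha Gamma shape parameter (> 0); ignored when \code{n_cats = 1}.
#' @param n_cats Number of discrete-gamma rate categories (1 disables gamma).
#' @param p_inv Proportion of invariant sites in \eqn{[0, 1)}.
#' @return An object of class \code{nr_model}.
#' @export
model_params <- function(rates = rep(1 / 12, 12), freqs = rep(0.25, 4),
                         alpha = 1.0, n_cats = 1L, p_inv = 0) {
  rates <- as.numeric(rates)
  if (length(rates) != 12L || any(!is.finite(rates)) || any(rates < 0))
    stop("rates must be 12 finite non-negative numbers", call. = FALSE)
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(!is.finite(freqs)) || any(freqs <= 0) ||
      abs(sum(freqs) - 1) > 1e-8)
    stop("freqs must be 4 positive numbers summing to 1", call. = FALSE)
  freqs <- freqs / sum(freqs)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  n_cats <- as.integer(n_cats)
  if (is.na(n_cats) || n_cats < 1L) stop("n_cats must be >= 1", call. = FALSE)
  if (!is.finite(p_inv) || p_inv < 0 || p_inv >= 1)
    stop("p_inv must lie in [0, 1)", call. = FALSE)
  names(rates) <- .rate_names
  names(freqs) <- .nuc
  structure(list(rates = rates, freqs = freqs, alpha = alpha,
                 n_cats = n_cats, p_inv = p_inv),
            class = "nr_model")
}

#' Default model parameter initialization
#'
#' All 12 substitution rates start at \eqn{1/(4(4-1)) = 1/12}, base
#' frequencies at \eqn{1/4}, and the gamma shape at 1.0.  These are the
#' values the root search re-initializes from before optimizing.
#'
#' @inheritParams model_params
#' @return An object of class \code{nr_model}.
#' @export
default_params <- function(n_cats = 1L, p_inv = 0) {
  model_params(rates = rep(1 / 12, 12), freqs = rep(0.25, 4),
               alpha = 1.0, n_cats = n_cats, p_inv = p_inv)
}

#' Reversible (GTR-style) parameters expressed as UNREST rates
#'
#' Builds the detailed-balance rates \eqn{\sigma_{xy} = s_{xy} \pi_y} from
#' symmetric exchangeabilities \eqn{s} and a frequency vector \eqn{\pi}, and
#' sets the root frequencies to \eqn{\pi} (the stationary distribution of
#' the resulting matrix).  Under such parameters the likelihood is invariant
#' to root placement (the pulley principle), which makes this constructor
#' useful as a negative control for root inference.
#'
#' @param freqs Stationary base frequencies.
#' @param exch Six exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @inheritParams model_params
#' @return An object of class \code{nr_model}.
#' @export
reversible_params <- function(freqs, exch = rep(1, 6), alpha = 1.0,
                              n_cats = 1L, p_inv = 0) {
  stopifnot(length(freqs) == 4L, length(exch) == 6L, all(exch > 0))
  freqs <- freqs / sum(freqs)
  s <- matrix(0, 4, 4)
  s[upper.tri(s)] <- exch[c(1, 2, 4, 3, 5, 6)]  # fill columnwise: AC,AG,CG,AT,CT,GT
  s <- s + t(s)
  sigma <- sweep(s, 2L, freqs, `*`)   # sigma_xy = s_xy * pi_y
  rates <- as.vector(t(sigma))[c(2:4, 5, 7:8, 9:10, 12, 13:15)]
  model_params(rates = rates, freqs = freqs, alpha = alpha,
               n_cats = n_cats, p_inv = p_inv)
}

#' Build the normalized UNREST rate matrix
#'
#' Off-diagonal entries come from \code{params$rates}, diagonals are the
#' negative row sums, and the matrix is rescaled so that the expected
#' substitution rate at stationarity is 1:
#' \eqn{-\sum_x \hat\pi_x Q_{xx} = 1}, where \eqn{\hat\pi} is the stationary
#' distribution of \eqn{Q}.  This makes branch lengths interpretable as
#' expected substitutions per site.
#'
#' @param params An \code{nr_model}.
#' @return An object of class \code{nr_ratemat}: list with the 4x4 matrix
#'   \code{Q} and its stationary distribution \code{stationary}.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "nr_model"))
  if (all(params$rates == 0))
    stop("degenerate model: all substitution rates are zero", call. = FALSE)
  Q <- matrix(0, 4, 4, dimnames = list(.nuc, .nuc))
  Q[row(Q) != col(Q)] <- params$rates[c(4, 7, 10, 1, 8, 11, 2, 5, 12, 3, 6, 9)]
  # the index vector maps column-major off-diagonal positions
  # (CA,GA,TA,AC,GC,TC,AG,CG,TG,AT,CT,GT) onto the AC..TG rate order
  diag(Q) <- -rowSums(Q)
  pi_hat <- .stationary(Q)
  scale <- -sum(pi_hat * diag(Q))
  if (scale <= 0) stop("degenerate model: zero expected substitution rate",
                       call. = FALSE)
  Q <- Q / scale
  structure(list(Q = Q, stationary = pi_hat), class = "nr_ratemat")
}

# Stationary distribution: solve pi Q = 0 with sum(pi) = 1.
.stationary <- function(Q) {
  A <- rbind(t(Q), rep(1, 4))
  p <- qr.solve(A, c(0, 0, 0, 0, 1))
  p[p < 0 & p > -1e-12] <- 0
  if (any(p < 0))
    stop("rate matrix has no valid stationary distribution", call. = FALSE)
  p / sum(p)
}

# Eigendecomposition of Q with a conditioning check.  When the eigenvector
# matrix is ill-conditioned (possible for non-symmetric Q), transition
# matrices fall back to scaling-and-squaring via Matrix::expm.
.eig_decomp <- function(Q, cond_limit = 1e8) {
  ed <- tryCatch({
    e <- eigen(Q)
    Vinv <- solve(e$vectors)
    kappa <- max(colSums(Mod(e$vectors))) * max(colSums(Mod(Vinv)))
    list(Q = Q, values = e$values, V = e$vectors, Vinv = Vinv,
         ok = is.finite(kappa) && kappa < cond_limit)
  }, error = function(err) NULL)
  if (is.null(ed)) ed <- list(Q = Q, ok = FALSE)
  ed
}

# P(s) = exp(Q s) from a cached decomposition; s = t * r.
.pmat <- function(ed, s) {
  if (s <= 0) return(diag(4))
  P <- if (ed$ok) {
    Re(ed$V %*% (exp(ed$values * s) * ed$Vinv))
  } else {
    as.matrix(Matrix::expm(ed$Q * s))
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Transition probability matrix
#'
#' Computes \eqn{P(t) = \exp(Q r t)} for branch length \code{t} and rate
#' multiplier \code{r}, via eigendecomposition of the (generally
#' non-symmetric) rate matrix, with a scaling-and-squaring fallback when the
#' eigenvector matrix is ill-conditioned.  Rows sum to 1.
#'
#' @param Q An \code{nr_ratemat} from [build_rate_matrix()] (or a plain 4x4
#'   rate matrix with zero row sums).
#' @param t Branch length (expected substitutions per site), \eqn{\ge 0}.
#' @param r Rate multiplier, \eqn{\ge 0} (e.g. a gamma category rate).
#' @return A 4x4 row-stochastic matrix over (A, C, G, T).
#' @export
transition_matrix <- function(Q, t, r = 1) {
  Qm <- if (inherits(Q, "nr_ratemat")) Q$Q else as.matrix(Q)
  stopifnot(is.finite(t), t >= 0, is.finite(r), r >= 0)
  P <- .pmat(.eig_decomp(Qm), t * r)
  if (any(!is.finite(P)))
    stop("non-finite transition probabilities at t = ", t, ", r = ", r,
         call. = FALSE)
  dimnames(P) <- list(.nuc, .nuc)
  P
}

#' Discrete-gamma rate multipliers
#'
#' Discretizes a Gamma(\code{alpha}, \code{alpha}) distribution (mean 1)
#' into \code{k} categories of equal probability \eqn{1/k}, each represented
#' by its conditional mean, renormalized so the category mean is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of \code{k} rate multipliers with mean 1.
#' @export
discretize_gamma <- function(alpha, k) {
  stopifnot(is.finite(alpha), alpha > 0, k >= 1)
  k <- as.integer(k)
  if (k == 1L) return(1.0)
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1L),
                          shape = alpha, rate = alpha)
  # conditional mean per equal-probability bin:
  # E[X | a < X <= b] * (1/k) = (F_{alpha+1}(b) - F_{alpha+1}(a)) since mean = 1
  upper <- stats::pgamma(breaks[-1L], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(breaks[-(k + 1L)], shape = alpha + 1, rate = alpha)
  r <- k * (upper - lower)
  r / mean(r)
}

#' Among-site rate classes for UNREST+G+I
#'
#' Returns the mixture of rate classes implied by the model: an invariant
#' class (rate 0, probability \code{p_inv}) plus the discrete-gamma
#' categories, scaled so that the overall mean rate equals 1.
#'
#' @param params An \code{nr_model}.
#' @return A data frame with columns \code{rate}, \code{prob} and
#'   \code{invariant}; probabilities sum to 1.
#' @export
site_rates <- function(params) {
  stopifnot(inherits(params, "nr_model"))
  as.data.frame(.site_rate_list(params))
}

# data.frame-free version for the hot likelihood path
.site_rate_list <- function(params) {
  g <- discretize_gamma(params$alpha, params$n_cats)
  p_inv <- params$p_inv
  if (p_inv > 0) {
    list(rate = c(0, g / (1 - p_inv)),
         prob = c(p_inv, rep((1 - p_inv) / length(g), length(g))),
         invariant = c(TRUE, rep(FALSE, length(g))))
  } else {
    list(rate = g, prob = rep(1 / length(g), length(g)),
         invariant = rep(FALSE, length(g)))
  }
}

#' @export
print.nr_model <- function(x, ...) {
  cat("UNREST", if (x$n_cats > 1) paste0("+G", x$n_cats),
      if (x$p_inv > 0) "+I", "model parameters\n")
  cat("  rates:", paste(sprintf("%s=%.4g", names(x$rates), x$rates),
                        collapse = " "), "\n")
  cat("  freqs:", paste(sprintf("%s=%.4g", names(x$freqs), x$freqs),
                        collapse = " "), "\n")
  if (x$n_cats > 1) cat("  alpha:", format(x$alpha, digits = 4), "\n")
  if (x$p_inv > 0) cat("  p_inv:", format(x$p_inv, digits = 4), "\n")
  invisible(x)
}
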