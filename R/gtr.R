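#' GTR+Gamma+I model parameters
#'
#' @param freq Base frequencies, named \code{A,C,G,T}, positive, summing to 1.
#' @param rates Exchangeabilities \code{AC,AG,AT,CG,CT,GT} relative to
#'   \code{GT = 1} (six values; the last is conventionally 1).
#' @param alpha Gamma shape for among-site rate variation (> 0); ignored when
#'   \code{n_categories = 1}.
#' @param p_inv Proportion of invariant sites, in [0, 1).
#' @param n_categories Number of equal-probability discrete gamma categories.
#' @return Object of class \code{"gtr_params"}.
#' @export
gtr_params <- function(freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       rates = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1,
                                 GT = 1),
                       alpha = 1, p_inv = 0, n_categories = 1L) {
  freq <- freq[c("A", "C", "G", "T")]
  if (anyNA(freq) || any(freq <= 0) || abs(sum(freq) - 1) > 1e-8) {
    stop("freq must be positive, named A/C/G/T, and sum to 1")
  }
  rates <- rates[c("AC", "AG", "AT", "CG", "CT", "GT")]
  if (anyNA(rates) || any(rates <= 0)) stop("rates must be positive AC..GT")
  if (n_categories < 1L) stop("n_categories must be >= 1")
  if (n_categories > 1L && (!is.finite(alpha) || alpha <= 0)) {
    stop("alpha must be > 0")
  }
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  structure(list(freq = freq, rates = rates, alpha = alpha, p_inv = p_inv,
                 n_categories = as.integer(n_categories)),
            class = "gtr_params")
}

#' @export
print.gtr_params <- function(x, ...) {
  cat("<gtr_params> pi:", paste(sprintf("%s=%.3f", names(x$freq), x$freq),
                                collapse = " "), "\n",
      " rates:", paste(sprintf("%s=%.3f", names(x$rates), x$rates),
                       collapse = " "), "\n",
      " alpha:", x$alpha, " p_inv:", x$p_inv,
      " categories:", x$n_categories, "\n")
  invisible(x)
}

#' GTR rate matrix, normalized to mean rate 1
#'
#' Off-diagonal entries are \code{q_ij = f_ij * pi_j}; the matrix is scaled
#' so that the expected substitution rate at stationarity is 1, making
#' branch lengths expected substitutions per (variable) site.
#'
#' @param params A \code{"gtr_params"}.
#' @return 4x4 rate matrix over A, C, G, T.
#' @export
gtr_rate_matrix <- function(params) {
  b <- c("A", "C", "G", "T")
  f <- matrix(0, 4, 4, dimnames = list(b, b))
  f["A", "C"] <- params$rates[["AC"]]; f["A", "G"] <- params$rates[["AG"]]
  f["A", "T"] <- params$rates[["AT"]]; f["C", "G"] <- params$rates[["CG"]]
  f["C", "T"] <- params$rates[["CT"]]; f["G", "T"] <- params$rates[["GT"]]
  f <- f + t(f)
  q <- f * rep(params$freq, each = 4L)
  diag(q) <- -rowSums(q)
  mu <- -sum(params$freq * diag(q))
  q / mu
}

# eigen-decomposition of the reversible rate matrix via pi^(1/2) symmetrization
gtr_eigen <- function(params) {
  q <- gtr_rate_matrix(params)
  d <- sqrt(params$freq)
  b <- diag(d) %*% q %*% diag(1 / d)
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / d) %*% e$vectors,
       left = t(e$vectors) %*% diag(d))
}

#' Transition probability matrix P(t)
#'
#' @param params A \code{"gtr_params"} (or a precomputed eigendecomposition
#'   via the \code{eig} argument).
#' @param t Branch length (expected substitutions per site, >= 0).
#' @param eig Optional result of the internal eigendecomposition, to avoid
#'   recomputation in loops.
#' @return 4x4 stochastic matrix; rows sum to 1 and detailed balance
#'   \code{pi_i P_ij(t) = pi_j P_ji(t)} holds.
#' @export
transition_prob <- function(params, t, eig = NULL) {
  if (t < 0) stop("negative branch length")
  if (is.null(eig)) eig <- gtr_eigen(params)
  p <- eig$right %*% (exp(eig$values * t) * eig$left)
  p[p < 0] <- 0
  dimnames(p) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  p
}

#' Mean rates of equal-probability discrete gamma categories
#'
#' Category boundaries are the quantiles of Gamma(shape = alpha, rate =
#' alpha); each category is represented by its conditional mean, so the
#' category rates average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param n_categories Number of categories.
#' @return Numeric vector of category rates.
#' @export
gamma_category_rates <- function(alpha, n_categories) {
  if (n_categories == 1L) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = n_categories + 1L),
                          shape = alpha, rate = alpha)
  cum <- stats::pgamma(bounds, shape = alpha + 1, rate = alpha)
  n_categories * diff(cum)
}
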