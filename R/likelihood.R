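#' Compress an alignment into unique site patterns
#'
#' @param aln An \code{"alignment"}.
#' @return List of class \code{"site_patterns"}: \code{states} (character
#'   matrix, sequences x unique patterns) and \code{weights} (multiplicities
#'   summing to the alignment length).
#' @export
site_patterns <- function(aln) {
  m <- unclass(as_alignment(aln))
  if (ncol(m) == 0L) stop("empty alignment")
  key <- apply(m, 2L, paste, collapse = "")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  structure(list(states = m[, first, drop = FALSE], weights = w),
            class = "site_patterns")
}

# per-tip partial likelihood rows: npat x 4, IUPAC-aware, gap = all ones
tip_partials <- function(patterns, labels) {
  lapply(labels, function(lb) {
    s <- patterns$states[lb, ]
    out <- matrix(0, length(s), 4L,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    for (code in unique(s)) {
      allowed <- if (code == "-") c("A", "C", "G", "T") else IUPAC_CODES[[code]]
      if (is.null(allowed)) stop("bad alignment character: ", code)
      out[s == code, allowed] <- 1
    }
    out
  })
}

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log(exp(a - m) + exp(b - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

logsumexp_rows <- function(mat) {
  m <- do.call(pmax, c(as.data.frame(mat), list(na.rm = FALSE)))
  m + log(rowSums(exp(mat - m)))
}

# static description of the tree used by the pruning machinery
ltree_prepare <- function(tree, patterns) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, rownames(patterns$states))
  if (length(miss)) stop("tip absent from alignment: ", miss[[1L]])
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  kids <- children_list(tree)
  post <- unique(postorder_edges(tree)[, 1L])  # internal nodes, children-first
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  lengths <- rep(NA_real_, max(tree$edge))
  lengths[tree$edge[, 2L]] <- tree$edge.length
  list(n_tip = n_tip, n_node = max(tree$edge), kids = kids,
       internal_postorder = post, parent = parent, root = root_node(tree),
       lengths = lengths, tips = tip_partials(patterns, tree$tip.label),
       npat = length(patterns$weights), weights = patterns$weights)
}

rescale_rows <- function(mat) {
  m <- pmax(mat[, 1L], mat[, 2L], mat[, 3L], mat[, 4L])
  m[m <= 0] <- 1
  list(mat = mat / m, log = log(m))
}

# post-order conditional likelihoods for one rate category
down_pass <- function(lt, pmats) {
  D <- vector("list", lt$n_node)
  logsc <- vector("list", lt$n_node)
  for (i in seq_len(lt$n_tip)) {
    D[[i]] <- lt$tips[[i]]
    logsc[[i]] <- numeric(lt$npat)
  }
  for (v in lt$internal_postorder) {
    acc <- 1
    sc <- numeric(lt$npat)
    for (ch in lt$kids[[v]]) {
      acc <- acc * (D[[ch]] %*% t(pmats[[ch]]))
      sc <- sc + logsc[[ch]]
    }
    r <- rescale_rows(acc)
    D[[v]] <- r$mat
    logsc[[v]] <- sc + r$log
  }
  list(D = D, logsc = logsc)
}

# pattern log-likelihoods of the variable-rate mixture component
mixture_loglik_patterns <- function(lt, params, eig) {
  rates <- gamma_category_rates(params$alpha, params$n_categories)
  percat <- matrix(NA_real_, lt$npat, length(rates))
  for (k in seq_along(rates)) {
    pmats <- vector("list", lt$n_node)
    for (v in seq_len(lt$n_node)) {
      if (!is.na(lt$lengths[v])) {
        pmats[[v]] <- transition_prob(params, lt$lengths[v] * rates[k], eig)
      }
    }
    dp <- down_pass(lt, pmats)
    val <- as.vector(dp$D[[lt$root]] %*% params$freq)
    percat[, k] <- ifelse(val > 0, log(val), -Inf) + dp$logsc[[lt$root]]
  }
  logsumexp_rows(percat) - log(length(rates))
}

# stationary likelihood of a pattern being an invariant site
invariant_pattern_lik <- function(lt, params) {
  comp <- Reduce(`&`, lapply(lt$tips, function(m) m > 0))
  as.vector(comp %*% params$freq)
}

#' GTR+Gamma+I log-likelihood by Felsenstein pruning
#'
#' Post-order pruning with per-node scaling; gamma rate variation uses
#' equal-probability categories at their conditional mean rates; the site
#' likelihood is \code{p_inv * [invariant term] + (1 - p_inv) * [mean over
#' categories]}, where a site contributes the invariant term only if all its
#' observed bases are identical. Gaps and IUPAC ambiguities are treated as
#' missing data (partial likelihood 1 for every compatible base).
#'
#' @param tree Rooted \code{"phylo"} with branch lengths (expected
#'   substitutions/site).
#' @param aln An \code{"alignment"} (or \code{"site_patterns"}) whose labels
#'   cover the tree's tips.
#' @param params A \code{"gtr_params"}.
#' @return Total log-likelihood (single number).
#' @export
gtr_gamma_inv_loglik <- function(tree, aln, params) {
  patterns <- if (inherits(aln, "site_patterns")) aln else site_patterns(aln)
  lt <- ltree_prepare(tree, patterns)
  eig <- gtr_eigen(params)
  lvar <- mixture_loglik_patterns(lt, params, eig)
  if (params$p_inv > 0) {
    ivec <- invariant_pattern_lik(lt, params)
    ll <- logsumexp2(log(params$p_inv) + log(ivec),
                     log1p(-params$p_inv) + lvar)
  } else {
    ll <- lvar
  }
  sum(lt$weights * ll)
}

#' Empirical base frequencies of an alignment
#'
#' Counted over unambiguous A/C/G/T cells (gaps and ambiguity codes
#' excluded).
#'
#' @param aln An \code{"alignment"}.
#' @return Named numeric vector summing to 1.
#' @export
empirical_base_freq <- function(aln) {
  m <- unclass(as_alignment(aln))
  tab <- table(factor(m[m %in% c("A", "C", "G", "T")],
                      levels = c("A", "C", "G", "T")))
  out <- as.vector(tab) / sum(tab)
  names(out) <- c("A", "C", "G", "T")
  out
}
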