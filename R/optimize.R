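#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate ascent over branches: each branch length in turn is optimized
#' by bounded scalar search (golden-section/parabolic) holding the others
#' fixed, with conditional likelihoods cached and updated along the path to
#' the root, iterated until the log-likelihood improves by less than
#' \code{tol} (relative). A degree-2 root is collapsed first (for a
#' reversible model only the sum of the two root-adjacent branch lengths is
#' identifiable), so trees with three or more tips are fitted in
#' unrooted-equivalent form; patristic distances are unaffected.
#'
#' With \code{estimate_params = TRUE} the exchangeabilities, gamma shape and
#' invariant proportion are additionally optimized in an outer loop
#' (Nelder-Mead on log/logit scale), with base frequencies fixed at their
#' empirical values.
#'
#' @param tree \code{"phylo"} topology (branch lengths, if present, are the
#'   starting values; missing lengths start at 0.1).
#' @param aln An \code{"alignment"} covering the tree's tips.
#' @param params A \code{"gtr_params"}.
#' @param estimate_params Also fit exchangeabilities, alpha and p_inv.
#' @param tol Absolute log-likelihood convergence tolerance per sweep.
#' @param max_sweeps Maximum coordinate-ascent sweeps; exceeding it raises an
#'   error of class \code{"optim_nonconvergence"} carrying the best tree so
#'   far in its \code{tree} field.
#' @param min_len,max_len Bounds of the per-branch search interval.
#' @return The tree with ML branch lengths; attributes \code{loglik} and
#'   (when fitted) \code{params}.
#' @export
optimize_branch_lengths <- function(tree, aln, params,
                                    estimate_params = FALSE, tol = 1e-6,
                                    max_sweeps = 200L, min_len = 1e-8,
                                    max_len = 10) {
  if (length(tree$tip.label) < 2L) stop("need at least two tips")
  if (length(tree$tip.label) >= 3L && ape::is.rooted(tree)) {
    tree <- ape::reorder.phylo(ape::unroot(tree), order = "cladewise")
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  patterns <- if (inherits(aln, "site_patterns")) aln else site_patterns(aln)
  if (estimate_params) {
    a2 <- if (inherits(aln, "site_patterns")) aln$states else aln
    params$freq <- empirical_base_freq(as_alignment(a2))
    fit <- fit_branches(tree, patterns, params, tol, max_sweeps,
                        min_len, max_len)
    for (round in seq_len(10L)) {
      prev <- fit$loglik
      params <- fit_substitution_params(fit$tree, patterns, params)
      fit <- fit_branches(fit$tree, patterns, params, tol, max_sweeps,
                          min_len, max_len)
      if (fit$loglik - prev < max(tol, 1e-8)) break
    }
    out <- fit$tree
    attr(out, "loglik") <- fit$loglik
    attr(out, "params") <- params
    return(out)
  }
  fit <- fit_branches(tree, patterns, params, tol, max_sweeps,
                      min_len, max_len)
  out <- fit$tree
  attr(out, "loglik") <- fit$loglik
  out
}

fit_branches <- function(tree, patterns, params, tol, max_sweeps,
                         min_len, max_len) {
  lt <- ltree_prepare(tree, patterns)
  eig <- gtr_eigen(params)
  rates <- gamma_category_rates(params$alpha, params$n_categories)
  ncat <- length(rates)
  len <- lt$lengths
  use_inv <- params$p_inv > 0
  log_ivec <- if (use_inv) log(invariant_pattern_lik(lt, params)) else NULL

  pmat <- function(v, k) transition_prob(params, len[v] * rates[k], eig)
  all_pmats <- function(k) {
    out <- vector("list", lt$n_node)
    for (v in seq_len(lt$n_node)) {
      if (!is.na(len[v])) out[[v]] <- pmat(v, k)
    }
    out
  }
  D <- vector("list", ncat)
  logsc <- vector("list", ncat)
  refresh_all <- function() {
    for (k in seq_len(ncat)) {
      dp <- down_pass(modifyList(lt, list(lengths = len)), all_pmats(k))
      D[[k]] <<- dp$D
      logsc[[k]] <<- dp$logsc
    }
  }
  refresh_node <- function(v) {
    for (k in seq_len(ncat)) {
      acc <- 1
      sc <- numeric(lt$npat)
      for (ch in lt$kids[[v]]) {
        acc <- acc * (D[[k]][[ch]] %*% t(pmat(ch, k)))
        sc <- sc + logsc[[k]][[ch]]
      }
      r <- rescale_rows(acc)
      D[[k]][[v]] <<- r$mat
      logsc[[k]][[v]] <<- sc + r$log
    }
  }
  mix_site_loglik <- function(percat) {
    lvar <- logsumexp_rows(percat) - log(ncat)
    if (use_inv) {
      logsumexp2(log(params$p_inv) + log_ivec, log1p(-params$p_inv) + lvar)
    } else {
      lvar
    }
  }
  current_loglik <- function() {
    percat <- matrix(NA_real_, lt$npat, ncat)
    for (k in seq_len(ncat)) {
      val <- as.vector(D[[k]][[lt$root]] %*% params$freq)
      percat[, k] <- ifelse(val > 0, log(val), -Inf) + logsc[[k]][[lt$root]]
    }
    sum(lt$weights * mix_site_loglik(percat))
  }
  # context (likelihood of everything outside the subtree of `node`) per
  # category, built fresh along the root path using cached subtree partials
  context_for <- function(node) {
    path <- ancestors_of_parent(lt, node)
    H <- vector("list", ncat)
    hsc <- vector("list", ncat)
    for (k in seq_len(ncat)) {
      G <- matrix(rep(params$freq, each = lt$npat), lt$npat, 4L)
      gsc <- numeric(lt$npat)
      if (length(path) > 1L) {
        for (m in seq_len(length(path) - 1L)) {
          v <- path[m]
          u <- path[m + 1L]
          for (s in setdiff(lt$kids[[v]], u)) {
            G <- G * (D[[k]][[s]] %*% t(pmat(s, k)))
            gsc <- gsc + logsc[[k]][[s]]
          }
          G <- G %*% pmat(u, k)
          r <- rescale_rows(G)
          G <- r$mat
          gsc <- gsc + r$log
        }
      }
      p <- path[length(path)]
      for (s in setdiff(lt$kids[[p]], node)) {
        G <- G * (D[[k]][[s]] %*% t(pmat(s, k)))
        gsc <- gsc + logsc[[k]][[s]]
      }
      H[[k]] <- G
      hsc[[k]] <- gsc + logsc[[k]][[node]]
    }
    list(H = H, hsc = hsc)
  }
  edge_objective <- function(node, ctx) {
    function(t) {
      percat <- matrix(NA_real_, lt$npat, ncat)
      for (k in seq_len(ncat)) {
        p <- transition_prob(params, t * rates[k], eig)
        val <- rowSums((ctx$H[[k]] %*% p) * D[[k]][[node]])
        percat[, k] <- ifelse(val > 0, log(val), -Inf) + ctx$hsc[[k]]
      }
      sum(lt$weights * mix_site_loglik(percat))
    }
  }

  refresh_all()
  ll <- current_loglik()
  best <- list(len = len, loglik = ll)
  converged <- FALSE
  edge_nodes <- postorder_edges(tree)[, 2L]
  for (sweep in seq_len(max_sweeps)) {
    for (node in edge_nodes) {
      ctx <- context_for(node)
      obj <- edge_objective(node, ctx)
      opt <- stats::optimize(obj, c(min_len, max_len), maximum = TRUE,
                             tol = 1e-9)
      # keep the current value if the line search did not improve on it
      if (opt$objective > obj(len[node])) {
        len[node] <- opt$maximum
      }
      for (v in rev(ancestors_of_parent(lt, node))) refresh_node(v)
    }
    new_ll <- current_loglik()
    if (new_ll > best$loglik) best <- list(len = len, loglik = new_ll)
    if (abs(new_ll - ll) < tol) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  tree$edge.length <- best$len[tree$edge[, 2L]]
  if (!converged) {
    cond <- structure(
      class = c("optim_nonconvergence", "error", "condition"),
      list(message = paste("branch-length optimization did not converge in",
                           max_sweeps, "sweeps"),
           call = NULL, tree = tree, loglik = best$loglik))
    stop(cond)
  }
  list(tree = tree, loglik = best$loglik)
}

# root .. parent(node)
ancestors_of_parent <- function(lt, node) {
  path <- integer(0)
  v <- lt$parent[node]
  while (v != 0L) {
    path <- c(v, path)
    v <- lt$parent[v]
  }
  path
}

fit_substitution_params <- function(tree, patterns, params) {
  est_alpha <- params$n_categories > 1L
  est_pinv <- params$p_inv > 0
  theta <- c(log(params$rates[c("AC", "AG", "AT", "CG", "CT")]),
             if (est_alpha) log(params$alpha),
             if (est_pinv) stats::qlogis(min(max(params$p_inv, 1e-4), 0.95)))
  unpack <- function(th) {
    p <- params
    p$rates[c("AC", "AG", "AT", "CG", "CT")] <- exp(th[1:5])
    i <- 6L
    if (est_alpha) {
      p$alpha <- exp(th[i])
      i <- i + 1L
    }
    if (est_pinv) p$p_inv <- stats::plogis(th[i]) * 0.99
    p
  }
  fn <- function(th) {
    p <- tryCatch(unpack(th), error = function(e) NULL)
    if (is.null(p)) return(1e10)
    -gtr_gamma_inv_loglik(tree, patterns, p)
  }
  opt <- stats::optim(theta, fn, method = "Nelder-Mead",
                      control = list(maxit = 300L))
  unpack(opt$par)
}

#' Pairwise divergence table from a phylogram
#'
#' Patristic distances (sum of branch lengths on the connecting path) for
#' all tip pairs, sorted ascending.
#'
#' @param tree \code{"phylo"} with branch lengths.
#' @return Data frame with columns \code{tip_a}, \code{tip_b},
#'   \code{distance}.
#' @export
divergence_table <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- stats::cophenetic(tree)
  labs <- rownames(d)
  pairs <- utils::combn(labs, 2L)
  out <- data.frame(tip_a = pairs[1L, ], tip_b = pairs[2L, ],
                    distance = d[t(pairs)], stringsAsFactors = FALSE)
  out[order(out$distance, out$tip_a, out$tip_b), , drop = FALSE]
}
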