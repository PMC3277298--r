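# Independent oracles used across the suite. These deliberately use naive
# exhaustive computations so they cannot share bugs with the package's
# dynamic-programming implementations.

random_tree <- function(n_tips, lengths = TRUE) {
  tr <- ape::rtree(n_tips, rooted = TRUE,
                   tip.label = paste0("t", seq_len(n_tips)))
  if (!lengths) tr$edge.length <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

random_states <- function(tree, n_states, missing_prob = 0) {
  alpha <- as.character(seq_len(n_states) - 1L)
  s <- sample(alpha, length(tree$tip.label), replace = TRUE)
  if (missing_prob > 0) {
    s[runif(length(s)) < missing_prob] <- "?"
  }
  stats::setNames(s, tree$tip.label)
}

# exhaustive minimum parsimony cost over all internal labelings; tips with
# "?" (or ambiguity sets) contribute the per-edge minimum over allowed states
brute_force_parsimony <- function(tree, states, costs) {
  alphabet <- rownames(costs)
  k <- length(alphabet)
  n_tip <- length(tree$tip.label)
  internal <- setdiff(seq_len(max(tree$edge)), seq_len(n_tip))
  tip_allowed <- lapply(tree$tip.label, function(lb) {
    s <- states[[lb]]
    if (length(s) == 1L && s == "?") seq_len(k) else match(s, alphabet)
  })
  edges <- tree$edge
  best <- Inf
  grid <- rep(1L, length(internal))
  repeat {
    lab <- integer(max(tree$edge))
    lab[internal] <- grid
    cost <- 0
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L]
      ch <- edges[e, 2L]
      cost <- cost + if (ch <= n_tip) {
        min(costs[lab[p], tip_allowed[[ch]]])
      } else {
        costs[lab[p], lab[ch]]
      }
    }
    best <- min(best, cost)
    # next grid combination
    i <- 1L
    while (i <= length(grid)) {
      grid[i] <- grid[i] + 1L
      if (grid[i] <= k) break
      grid[i] <- 1L
      i <- i + 1L
    }
    if (i > length(grid)) break
  }
  best
}

# all cost-minimal internal labelings (tips resolved to their cheapest state
# given the parent), as a list of integer vectors indexed by node id
enumerate_mp_labelings <- function(tree, states, costs) {
  alphabet <- rownames(costs)
  k <- length(alphabet)
  n_tip <- length(tree$tip.label)
  internal <- setdiff(seq_len(max(tree$edge)), seq_len(n_tip))
  tip_allowed <- lapply(tree$tip.label, function(lb) {
    s <- states[[lb]]
    if (length(s) == 1L && s == "?") seq_len(k) else match(s, alphabet)
  })
  edges <- tree$edge
  out <- list()
  best <- Inf
  grid <- rep(1L, length(internal))
  repeat {
    lab <- integer(max(tree$edge))
    lab[internal] <- grid
    cost <- 0
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L]
      ch <- edges[e, 2L]
      cost <- cost + if (ch <= n_tip) {
        min(costs[lab[p], tip_allowed[[ch]]])
      } else {
        costs[lab[p], lab[ch]]
      }
    }
    if (cost < best - 1e-9) {
      best <- cost
      out <- list(lab)
    } else if (cost < best + 1e-9) {
      out[[length(out) + 1L]] <- lab
    }
    i <- 1L
    while (i <= length(grid)) {
      grid[i] <- grid[i] + 1L
      if (grid[i] <= k) break
      grid[i] <- 1L
      i <- i + 1L
    }
    if (i > length(grid)) break
  }
  list(cost = best, labelings = out)
}

# exhaustive GTR+Gamma+I likelihood by summing over all internal-node base
# assignments and rate categories (tiny trees only)
enum_loglik <- function(tree, aln, params) {
  aln <- as_alignment(aln)
  q_eig <- NULL
  rates <- gamma_category_rates(params$alpha, params$n_categories)
  n_tip <- length(tree$tip.label)
  internal <- setdiff(seq_len(max(tree$edge)), seq_len(n_tip))
  edges <- tree$edge
  lens <- stats::setNames(tree$edge.length, tree$edge[, 2L])
  root <- setdiff(unique(edges[, 1L]), edges[, 2L])
  bases <- c("A", "C", "G", "T")
  allowed <- function(chr) {
    if (chr == "-") bases else caenophylo:::IUPAC_CODES[[chr]]
  }
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  total <- 0
  for (col in seq_len(ncol(m))) {
    site_l_var <- 0
    for (r in rates) {
      pm <- lapply(stats::setNames(names(lens), names(lens)), function(nd)
        transition_prob(params, lens[[nd]] * r))
      # sum over internal assignments
      grid <- rep(1L, length(internal))
      s <- 0
      repeat {
        lab <- integer(max(tree$edge))
        lab[internal] <- grid
        lik <- params$freq[lab[root]]
        for (e in seq_len(nrow(edges))) {
          p <- edges[e, 1L]
          ch <- edges[e, 2L]
          pmat <- pm[[as.character(ch)]]
          lik <- lik * if (ch <= n_tip) {
            sum(pmat[lab[p], allowed(m[ch, col])])
          } else {
            pmat[lab[p], lab[ch]]
          }
        }
        s <- s + lik
        i <- 1L
        while (i <= length(grid)) {
          grid[i] <- grid[i] + 1L
          if (grid[i] <= 4L) break
          grid[i] <- 1L
          i <- i + 1L
        }
        if (i > length(grid)) break
      }
      site_l_var <- site_l_var + s / length(rates)
    }
    site_l <- site_l_var
    if (params$p_inv > 0) {
      comp <- Reduce(intersect, lapply(seq_len(n_tip),
                                       function(i) allowed(m[i, col])))
      inv <- if (length(comp)) sum(params$freq[comp]) else 0
      site_l <- params$p_inv * inv + (1 - params$p_inv) * site_l_var
    }
    total <- total + log(site_l)
  }
  unname(total)
}

tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- caenophylo:::children_list(tree)
  out <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= n_tip) out <- c(out, tree$tip.label[v]) else
      stack <- c(kids[[v]], stack)
  }
  out
}

is_clade <- function(tree, taxa) {
  setequal(tips_below(tree, mrca_node(tree, taxa)), taxa)
}

jc_params <- function() gtr_params()

random_alignment <- function(labels, n_cols, gap_prob = 0.1) {
  m <- matrix(sample(c("A", "C", "G", "T"), length(labels) * n_cols,
                     replace = TRUE), length(labels), n_cols,
              dimnames = list(labels, NULL))
  if (gap_prob > 0) {
    m[runif(length(m)) < gap_prob] <- "-"
  }
  as_alignment(m)
}

# ground-truth barcode-gap violations from a simulate_strain_dataset result:
# per-branch true event counts (substitutions + indel events) are summed
# along tree paths, then species are flagged exactly as the report would be
true_violations <- function(sim) {
  tr <- sim$strain_tree
  ev <- sim$record$events
  w <- stats::setNames(ev$substitutions + ev$indel_events, ev$node)
  path_cost <- function(a, b) {
    ia <- match(a, tr$tip.label)
    ib <- match(b, tr$tip.label)
    pa <- caenophylo:::ancestors_of(tr, ia)
    pb <- caenophylo:::ancestors_of(tr, ib)
    k <- max(which(pa[seq_len(min(length(pa), length(pb)))] ==
                     pb[seq_len(min(length(pa), length(pb)))]))
    nodes <- c(pa[-seq_len(k)], pb[-seq_len(k)])
    sum(w[as.character(nodes)])
  }
  sp <- stats::setNames(sim$species_map$species, sim$species_map$strain)
  strains <- sim$species_map$strain
  species <- unique(sp)
  pairs <- utils::combn(strains, 2)
  d <- vapply(seq_len(ncol(pairs)), function(i)
    path_cost(pairs[1, i], pairs[2, i]), numeric(1))
  sa <- sp[pairs[1, ]]
  sb <- sp[pairs[2, ]]
  out <- character(0)
  for (s in species) {
    intra <- d[sa == s & sb == s]
    if (!length(intra)) next
    inter <- d[(sa == s) != (sb == s)]
    if (length(inter) && max(intra) >= min(inter)) out <- c(out, s)
  }
  out
}
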