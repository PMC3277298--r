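RNG_ALGORITHM <- "Mersenne-Twister/Inversion (R base RNG), caenophylo v1"

new_simulation_record <- function(seed, parameters, outputs) {
  structure(c(list(seed = seed, rng = RNG_ALGORITHM,
                   parameters = parameters), outputs),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  cat("<simulation_record> seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a discrete character along a tree
#'
#' Symmetric-rates Markov evolution: events occur at the given rate per unit
#' branch length; each event moves to a uniformly chosen different state.
#' The root state is uniform over the alphabet. Every change is logged, so
#' parsimony estimates can be compared with the true number of events.
#'
#' @param tree Rooted \code{"phylo"} with branch lengths.
#' @param rate Expected number of change events per unit branch length.
#' @param n_states Alphabet size (states \code{"0"}, \code{"1"}, ...).
#' @param seed Integer seed; identical seeds reproduce outputs exactly.
#' @return A \code{"simulation_record"} with \code{tip_states} (named
#'   vector), \code{events} (data frame \code{node}, \code{from}, \code{to})
#'   and \code{n_events}.
#' @export
simulate_character <- function(tree, rate, n_states = 2L, seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  if (n_states < 2L) stop("need at least two states")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(seed)
  alphabet <- as.character(seq_len(n_states) - 1L)
  n_node <- max(tree$edge)
  state <- integer(n_node)
  r <- root_node(tree)
  state[r] <- sample.int(n_states, 1L)
  kids <- children_list(tree)
  lens <- rep(NA_real_, n_node)
  lens[tree$edge[, 2L]] <- tree$edge.length
  events <- list()
  for (v in node_preorder(tree)) {
    for (ch in kids[[v]]) {
      s <- state[v]
      n_ev <- stats::rpois(1L, rate * lens[ch])
      for (i in seq_len(n_ev)) {
        s_new <- sample(setdiff(seq_len(n_states), s), 1L)
        events[[length(events) + 1L]] <-
          list(node = ch, from = alphabet[s], to = alphabet[s_new])
        s <- s_new
      }
      state[ch] <- s
    }
  }
  ev <- if (length(events)) {
    data.frame(node = vapply(events, `[[`, 0L, "node"),
               from = vapply(events, `[[`, "", "from"),
               to = vapply(events, `[[`, "", "to"), stringsAsFactors = FALSE)
  } else {
    data.frame(node = integer(0), from = character(0), to = character(0))
  }
  tips <- stats::setNames(alphabet[state[seq_along(tree$tip.label)]],
                          tree$tip.label)
  new_simulation_record(seed,
                        list(rate = rate, n_states = n_states),
                        list(tip_states = tips, events = ev,
                             n_events = nrow(ev)))
}

# vectorized jump-chain substitution simulation along one branch;
# returns new bases and the number of substitution events
evolve_bases <- function(bases, site_rates, t, q) {
  leave <- -diag(q)
  n_events <- 0L
  t_rem <- rep(t, length(bases)) * site_rates
  active <- which(t_rem > 0)
  while (length(active)) {
    dt <- stats::rexp(length(active), leave[bases[active]])
    hit <- dt < t_rem[active]
    t_rem[active] <- t_rem[active] - dt
    jumped <- active[hit]
    n_events <- n_events + length(jumped)
    old <- bases[jumped]
    for (s in unique(old)) {
      idx <- jumped[old == s]
      pr <- q[s, ]
      pr[s] <- 0
      bases[idx] <- sample.int(4L, length(idx), replace = TRUE,
                               prob = pr / sum(pr))
    }
    active <- active[hit]
  }
  list(bases = bases, n_events = n_events)
}

draw_site_rates <- function(n, params, cat_rates) {
  r <- cat_rates[sample.int(length(cat_rates), n, replace = TRUE)]
  if (params$p_inv > 0) {
    r[stats::runif(n) < params$p_inv] <- 0
  }
  r
}

#' Simulate sequence evolution with substitutions and indels along a tree
#'
#' GTR+Gamma+I substitution simulation by explicit jump chains (so the true
#' per-branch event counts are known), plus insertion/deletion events placed
#' uniformly on branches at \code{indel_rate} events per unit branch length
#' (insertions and deletions equally likely, geometric lengths). Insertions
#' create new alignment columns, gapped in all lineages that never carried
#' them, so the returned object is the true multiple alignment.
#'
#' @param tree Rooted \code{"phylo"} with branch lengths.
#' @param params A \code{"gtr_params"}.
#' @param n_sites Number of root sequence sites.
#' @param indel_rate Indel events per unit branch length (0 = none).
#' @param mean_indel_len Mean of the geometric indel-length distribution.
#' @param seed Integer seed.
#' @return A \code{"simulation_record"} with \code{alignment} (the true MSA),
#'   \code{events} (per branch: \code{node}, \code{substitutions},
#'   \code{indel_events}) and \code{tree} (true branch lengths).
#' @export
simulate_alignment <- function(tree, params, n_sites, indel_rate = 0,
                               mean_indel_len = 3, seed = 1L) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (indel_rate < 0) stop("indel_rate must be >= 0")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  set.seed(seed)
  q <- gtr_rate_matrix(params)
  cat_rates <- gamma_category_rates(params$alpha, params$n_categories)
  bases4 <- c("A", "C", "G", "T")
  root_state <- list(
    keys = as.numeric(seq_len(n_sites)),
    bases = sample.int(4L, n_sites, replace = TRUE, prob = params$freq),
    rates = draw_site_rates(n_sites, params, cat_rates))
  kids <- children_list(tree)
  lens <- rep(NA_real_, max(tree$edge))
  lens[tree$edge[, 2L]] <- tree$edge.length
  n_tip <- length(tree$tip.label)
  tips <- vector("list", n_tip)
  ev_sub <- numeric(max(tree$edge))
  ev_ind <- numeric(max(tree$edge))

  evolve_branch <- function(st, t, node) {
    if (length(st$keys)) {
      sub <- evolve_bases(st$bases, st$rates, t, q)
      st$bases <- sub$bases
      ev_sub[node] <<- sub$n_events
    }
    n_ind <- stats::rpois(1L, indel_rate * t)
    ev_ind[node] <<- n_ind
    for (i in seq_len(n_ind)) {
      n <- length(st$keys)
      len <- stats::rgeom(1L, 1 / mean_indel_len) + 1L
      if (stats::runif(1) < 0.5 && n > 0L) {       # deletion
        start <- sample.int(n, 1L)
        drop <- start:min(n, start + len - 1L)
        st$keys <- st$keys[-drop]
        st$bases <- st$bases[-drop]
        st$rates <- st$rates[-drop]
      } else {                                      # insertion
        pos <- sample.int(n + 1L, 1L) - 1L
        left <- if (pos == 0L) (if (n) st$keys[1L] - 1 else 0) else st$keys[pos]
        right <- if (pos >= n) left + 1 else st$keys[pos + 1L]
        newk <- left + (right - left) * seq_len(len) / (len + 1)
        ins_at <- pos
        st$keys <- append(st$keys, newk, after = ins_at)
        st$bases <- append(st$bases,
                           sample.int(4L, len, replace = TRUE,
                                      prob = params$freq), after = ins_at)
        st$rates <- append(st$rates, draw_site_rates(len, params, cat_rates),
                           after = ins_at)
      }
    }
    st
  }
  recurse <- function(v, st) {
    if (v <= n_tip) {
      tips[[v]] <<- st
      return(invisible(NULL))
    }
    for (ch in kids[[v]]) {
      recurse(ch, evolve_branch(st, lens[ch], ch))
    }
  }
  r <- root_node(tree)
  if (r <= n_tip) stop("degenerate tree")
  recurse(r, root_state)

  all_keys <- sort(unique(unlist(lapply(tips, `[[`, "keys"))))
  m <- matrix("-", n_tip, length(all_keys),
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    m[i, match(tips[[i]]$keys, all_keys)] <- bases4[tips[[i]]$bases]
  }
  ev <- data.frame(node = tree$edge[, 2L],
                   substitutions = ev_sub[tree$edge[, 2L]],
                   indel_events = ev_ind[tree$edge[, 2L]])
  new_simulation_record(seed,
                        list(params = params, n_sites = n_sites,
                             indel_rate = indel_rate,
                             mean_indel_len = mean_indel_len),
                        list(alignment = as_alignment(m), events = ev,
                             tree = tree))
}

#' Simulate a multi-strain barcode panel on a species tree
#'
#' Grafts a random strain subtree (Yule-shaped topology, exponential branch
#' lengths scaled by \code{intra_scale}) onto each species tip, then runs
#' \code{\link{simulate_alignment}} on the grafted tree. This emulates a
#' barcode survey with small intra-specific and larger inter-specific
#' divergence, for exercising the barcode-gap analysis end to end.
#'
#' @param species_tree Rooted \code{"phylo"} with branch lengths
#'   (inter-species divergence).
#' @param strains_per_species Named integer vector: strains per species tip.
#' @param intra_scale Scale of intra-specific branch lengths.
#' @param params A \code{"gtr_params"}.
#' @param n_sites Alignment length at the root.
#' @param indel_rate Indel events per unit branch length.
#' @param mean_indel_len Mean geometric indel length.
#' @param seed Integer seed.
#' @return List with \code{alignment} (strain-labelled), \code{species_map}
#'   (data frame \code{strain}, \code{species}), \code{strain_tree} (the
#'   true grafted tree) and \code{record} (the simulation record).
#' @export
simulate_strain_dataset <- function(species_tree, strains_per_species,
                                    intra_scale, params, n_sites = 500L,
                                    indel_rate = 0, mean_indel_len = 3,
                                    seed = 1L) {
  if (intra_scale <= 0) stop("intra_scale must be > 0")
  sp <- species_tree$tip.label
  if (is.null(names(strains_per_species)) ||
      !all(sp %in% names(strains_per_species))) {
    stop("species without strain count")
  }
  set.seed(seed)
  nw <- write_newick(species_tree)
  map <- list()
  for (s in sp) {
    k <- strains_per_species[[s]]
    strains <- sprintf("%s_S%d", s, seq_len(k))
    map[[s]] <- data.frame(strain = strains, species = s,
                           stringsAsFactors = FALSE)
    frag <- if (k == 1L) {
      strains
    } else {
      sub <- ape::rtree(k, rooted = TRUE, tip.label = strains,
                        br = function(n) stats::rexp(n) * intra_scale)
      gsub(";$", "", write_newick(sub))
    }
    nw <- replace_tip_newick(nw, s, frag)
  }
  grafted <- parse_newick(nw)
  rec <- simulate_alignment(grafted, params, n_sites, indel_rate,
                            mean_indel_len,
                            seed = sample.int(.Machine$integer.max, 1L))
  list(alignment = rec$alignment, species_map = do.call(rbind, map),
       strain_tree = grafted, record = rec)
}

#' Seeded branch lengths emulating the genus phylogram
#'
#' The divergence phylogram has terminal branches that are, with few
#' exceptions, longer than the internal branches, with species divergences
#' spanning roughly 0.05-0.6 substitutions/site. This generator draws branch
#' lengths with that structure (terminal branches uniform on [0.05, 0.30],
#' internal branches uniform on [0.02, 0.12]) using the ambient RNG state,
#' for parameter-recovery experiments on a fixed topology.
#'
#' @param tree A \code{"phylo"} tree.
#' @return Numeric vector of branch lengths aligned with \code{tree$edge}.
#' @export
fixture_branch_lengths <- function(tree) {
  n_tip <- length(tree$tip.label)
  is_terminal <- tree$edge[, 2L] <= n_tip
  out <- numeric(nrow(tree$edge))
  out[is_terminal] <- stats::runif(sum(is_terminal), 0.05, 0.30)
  out[!is_terminal] <- stats::runif(sum(!is_terminal), 0.02, 0.12)
  out
}
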