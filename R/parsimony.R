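#' Read a discrete character matrix from TSV
#'
#' First column holds taxon names, remaining columns one discrete character
#' each. \code{"?"} marks missing/inapplicable states and is excluded from
#' the inferred state alphabet.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return An object of class \code{"character_matrix"}: a list with
#'   \code{cells} (character matrix, taxa in rows), \code{taxa},
#'   \code{characters} and \code{alphabets} (observed states per character).
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, fill = FALSE)
  if (ncol(df) < 2L) stop("need a taxon column plus at least one character")
  taxa <- df[[1L]]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon row: ", taxa[duplicated(taxa)][[1L]])
  }
  cells <- as.matrix(df[, -1L, drop = FALSE])
  rownames(cells) <- taxa
  new_character_matrix(cells)
}

new_character_matrix <- function(cells) {
  if (anyDuplicated(colnames(cells))) stop("duplicate character names")
  alphabets <- lapply(seq_len(ncol(cells)), function(j) {
    sort(unique(cells[cells[, j] != "?", j]))
  })
  names(alphabets) <- colnames(cells)
  structure(list(cells = cells, taxa = rownames(cells),
                 characters = colnames(cells), alphabets = alphabets),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("<character_matrix> ", length(x$taxa), " taxa x ",
      length(x$characters), " characters\n", sep = "")
  invisible(x)
}

#' Extract one character as a named state vector
#'
#' @param cm A \code{"character_matrix"}.
#' @param character Character name (column).
#' @return Named character vector of state tokens (may include \code{"?"}).
#' @export
character_states <- function(cm, character) {
  j <- match(character, cm$characters)
  if (is.na(j)) stop("unknown character: ", character)
  stats::setNames(cm$cells[, j], cm$taxa)
}

#' Unit cost matrix over a state alphabet
#' @param alphabet Character vector of states.
#' @return Square matrix with zero diagonal and unit off-diagonal costs.
#' @export
unit_cost_matrix <- function(alphabet) {
  k <- length(alphabet)
  m <- matrix(1, k, k, dimnames = list(alphabet, alphabet))
  diag(m) <- 0
  m
}

#' DNA cost matrix weighting transversions over transitions
#'
#' The weighted-parsimony convention used for the molecular analyses:
#' a transversion costs twice a transition by default.
#'
#' @param transition Cost of A<->G and C<->T changes.
#' @param transversion Cost of purine<->pyrimidine changes.
#' @return 4x4 cost matrix over A, C, G, T.
#' @export
dna_cost_matrix <- function(transition = 1, transversion = 2) {
  m <- matrix(transversion, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  m["A", "G"] <- m["G", "A"] <- transition
  m["C", "T"] <- m["T", "C"] <- transition
  diag(m) <- 0
  m
}

# tip state sets as logical matrix (n_tip x n_states); states may be a named
# vector of tokens or a named list of token vectors (ambiguity sets)
tip_state_sets <- function(tree, states, alphabet) {
  labs <- tree$tip.label
  if (is.list(states)) {
    miss <- setdiff(labs, names(states))
  } else {
    miss <- setdiff(labs, names(states))
  }
  if (length(miss)) stop("tip absent from character data: ", miss[[1L]])
  sets <- matrix(FALSE, length(labs), length(alphabet),
                 dimnames = list(labs, alphabet))
  for (i in seq_along(labs)) {
    s <- if (is.list(states)) states[[labs[i]]] else states[[labs[i]]]
    if (length(s) == 1L && s == "?") {
      sets[i, ] <- TRUE
    } else {
      if (!all(s %in% alphabet)) {
        stop("state not in alphabet: ", paste(setdiff(s, alphabet), collapse = ","))
      }
      sets[i, s] <- TRUE
    }
  }
  sets
}

observed_alphabet <- function(states) {
  if (is.list(states)) {
    sort(unique(unlist(states[vapply(states, function(s)
      !(length(s) == 1L && s == "?"), logical(1))])))
  } else {
    sort(unique(states[states != "?"]))
  }
}

# Sankoff bottom-up cost vectors; returns n_states x n_nodes matrix
sankoff_vectors <- function(tree, tipsets, costs) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  k <- ncol(tipsets)
  cv <- matrix(0, k, n_node, dimnames = list(colnames(tipsets), NULL))
  cv[, seq_len(n_tip)] <- ifelse(t(tipsets), 0, Inf)
  edges <- postorder_edges(tree)
  done <- rep(FALSE, n_node)
  kids <- children_list(tree)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    if (done[p]) next
    acc <- numeric(k)
    for (ch in kids[[p]]) {
      # min over child state t of costs[s, t] + cv[t, ch], for each s
      acc <- acc + apply(costs + rep(cv[, ch], each = k), 1L, min)
    }
    cv[, p] <- acc
    done[p] <- TRUE
  }
  cv
}

#' Fitch parsimony length of a character on a tree
#'
#' Minimum number of unordered unit-cost state changes over all ancestral
#' labelings. Binary nodes use Fitch set operations; trees with polytomies
#' fall back to Sankoff dynamic programming with unit costs (the two agree on
#' binary trees). Missing tips (\code{"?"}) carry the full alphabet.
#'
#' @param tree A rooted \code{"phylo"} tree.
#' @param states Named character vector of state tokens per tip (or a named
#'   list of token vectors for ambiguous tips).
#' @param alphabet Optional explicit state alphabet; defaults to the states
#'   observed in \code{states}.
#' @return Non-negative integer step count.
#' @export
fitch_length <- function(tree, states, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- observed_alphabet(states)
  if (!length(alphabet)) stop("no non-missing tip states")
  if (length(alphabet) == 1L) {
    tip_state_sets(tree, states, alphabet)  # validates tips present
    return(0L)
  }
  sets <- tip_state_sets(tree, states, alphabet)
  kids <- children_list(tree)
  if (any(lengths(kids)[lengths(kids) > 0] > 2L)) {
    cv <- sankoff_vectors(tree, sets, unit_cost_matrix(alphabet))
    return(as.integer(min(cv[, root_node(tree)])))
  }
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  setm <- matrix(FALSE, n_node, length(alphabet))
  setm[seq_len(n_tip), ] <- sets
  steps <- 0L
  edges <- postorder_edges(tree)
  done <- rep(FALSE, n_node)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    if (done[p]) next
    ch <- kids[[p]]
    inter <- setm[ch[1L], ] & setm[ch[2L], ]
    if (any(inter)) {
      setm[p, ] <- inter
    } else {
      setm[p, ] <- setm[ch[1L], ] | setm[ch[2L], ]
      steps <- steps + 1L
    }
    done[p] <- TRUE
  }
  steps
}

# Greedy preorder backtrace of Sankoff vectors. Changes are placed as close
# to the root as possible (accelerated transformation): at each branch, among
# cost-minimal child states, a state different from the parent's is preferred
# when available at no extra cost; remaining ties resolve by alphabet order.
# Nodes are visited in preorder, so equally early placements resolve to the
# smallest preorder node id.
backtrace_acctran <- function(tree, cv, costs, alphabet, stem_state = NULL) {
  k <- length(alphabet)
  n_node <- max(tree$edge)
  assign <- integer(n_node)
  changes <- list()
  r <- root_node(tree)
  if (is.null(stem_state)) {
    assign[r] <- which.min(cv[, r])
  } else {
    a <- match(stem_state, alphabet)
    tot <- costs[a, ] + cv[, r]
    m <- min(tot)
    cand <- which(tot <= m)
    pref <- setdiff(cand, a)
    assign[r] <- if (length(pref)) pref[[1L]] else cand[[1L]]
    if (assign[r] != a) {
      changes[[length(changes) + 1L]] <-
        list(node = r, from = alphabet[a], to = alphabet[assign[r]])
    }
  }
  kids <- children_list(tree)
  for (v in node_preorder(tree)) {
    a <- assign[v]
    for (ch in kids[[v]]) {
      tot <- costs[a, ] + cv[, ch]
      m <- min(tot)
      cand <- which(tot <= m)
      pref <- setdiff(cand, a)
      assign[ch] <- if (length(pref)) pref[[1L]] else cand[[1L]]
      if (assign[ch] != a) {
        changes[[length(changes) + 1L]] <-
          list(node = ch, from = alphabet[a], to = alphabet[assign[ch]])
      }
    }
  }
  node_states <- alphabet[assign]
  ch <- if (length(changes)) {
    data.frame(node = vapply(changes, `[[`, 0L, "node"),
               from = vapply(changes, `[[`, "", "from"),
               to = vapply(changes, `[[`, "", "to"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node = integer(0), from = character(0), to = character(0))
  }
  structure(list(node_states = node_states, changes = ch,
                 total_steps = sum(costs[cbind(match(ch$from, alphabet),
                                               match(ch$to, alphabet))])),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat("<reconstruction> total steps:", x$total_steps,
      "| changes:", nrow(x$changes), "\n")
  invisible(x)
}

#' Weighted parsimony (Sankoff) with an arbitrary cost matrix
#'
#' Dynamic programming over the tree computing the minimum total change cost,
#' plus one cost-minimal reconstruction resolved with the accelerated
#' transformation (ACCTRAN) convention.
#'
#' @inheritParams fitch_length
#' @param costs Square cost matrix with named rows/columns covering the
#'   character's alphabet; zero diagonal, non-negative entries.
#' @return List with \code{cost} (minimum total cost) and
#'   \code{reconstruction} (class \code{"reconstruction"}: per-node states,
#'   change events as \code{(node, from, to)} with \code{node} the child end
#'   of the branch, and \code{total_steps}).
#' @export
sankoff <- function(tree, states, costs) {
  alphabet <- rownames(costs)
  obs <- observed_alphabet(states)
  if (!all(obs %in% alphabet)) {
    stop("state not in cost matrix: ", setdiff(obs, alphabet)[[1L]])
  }
  if (any(diag(costs) != 0) || any(costs < 0)) {
    stop("cost matrix must have zero diagonal and non-negative costs")
  }
  sets <- tip_state_sets(tree, states, alphabet)
  cv <- sankoff_vectors(tree, sets, costs)
  rec <- backtrace_acctran(tree, cv, costs, alphabet)
  list(cost = min(cv[, root_node(tree)]), reconstruction = rec)
}

#' ACCTRAN-resolved most-parsimonious reconstruction
#'
#' Unit-cost parsimony with ambiguity resolved by accelerated transformation:
#' changes are assigned as close to the root as possible, deterministically
#' (preorder traversal; remaining ties by alphabet order).
#'
#' @inheritParams fitch_length
#' @return A \code{"reconstruction"} whose \code{total_steps} equals
#'   \code{fitch_length}.
#' @export
acctran <- function(tree, states, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- observed_alphabet(states)
  if (length(alphabet) < 2L) {
    tip_state_sets(tree, states, alphabet)
    return(structure(list(
      node_states = rep(alphabet[1L], max(tree$edge)),
      changes = data.frame(node = integer(0), from = character(0),
                           to = character(0)),
      total_steps = 0), class = "reconstruction"))
  }
  costs <- unit_cost_matrix(alphabet)
  sets <- tip_state_sets(tree, states, alphabet)
  cv <- sankoff_vectors(tree, sets, costs)
  backtrace_acctran(tree, cv, costs, alphabet)
}

#' Minimum-step reconstruction with the stem (root) state fixed
#'
#' Models a known ancestral condition: a virtual stem branch above the root
#' carries the fixed state, and the reconstruction below is cost-minimal
#' given that constraint, ACCTRAN-resolved. A state change on the stem is
#' recorded with \code{node} equal to the root id.
#'
#' @inheritParams fitch_length
#' @param root_state State token assumed for the stem species.
#' @return A \code{"reconstruction"}.
#' @export
root_constrained_reconstruction <- function(tree, states, root_state,
                                            alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(observed_alphabet(states), root_state)))
  }
  if (!root_state %in% alphabet) stop("root_state not in alphabet")
  costs <- unit_cost_matrix(alphabet)
  sets <- tip_state_sets(tree, states, alphabet)
  cv <- sankoff_vectors(tree, sets, costs)
  backtrace_acctran(tree, cv, costs, alphabet, stem_state = root_state)
}

#' Count change events of a given kind in a reconstruction
#'
#' @param rec A \code{"reconstruction"}.
#' @param from,to State tokens.
#' @return Number of branches with a \code{from -> to} change.
#' @export
count_events <- function(rec, from, to) {
  sum(rec$changes$from == from & rec$changes$to == to)
}

#' Minimum steps under a single-origin constraint
#'
#' For a binary character, the minimum total number of changes over all
#' reconstructions in which the derived state arises on exactly one branch.
#' The gain branch must be ancestral to every derived tip; the implementation
#' tries each branch on the root path of the derived tips' MRCA (plus the
#' virtual stem), fixes the gain there, forbids further gains below it, and
#' counts the minimal number of reversals by asymmetric-cost parsimony.
#'
#' @inheritParams fitch_length
#' @param derived_state The state whose origins are constrained to one.
#' @return Non-negative integer total step count (1 gain + reversals).
#' @export
constrained_single_origin_steps <- function(tree, states, derived_state) {
  alphabet <- observed_alphabet(states)
  if (!derived_state %in% alphabet) stop("no derived tips")
  if (length(alphabet) > 2L) stop("character must be binary")
  ancestral <- setdiff(alphabet, derived_state)
  if (!length(ancestral)) {
    # all tips derived: one gain on the stem
    return(1L)
  }
  sets <- tip_state_sets(tree, states, alphabet)
  derived_tips <- tree$tip.label[sets[, derived_state] &
                                   !sets[, ancestral]]
  if (!length(derived_tips)) stop("no derived tips")
  m <- mrca_node(tree, derived_tips)
  # asymmetric costs below the gain: reversals allowed, re-gains forbidden
  k <- length(alphabet)
  costs <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
  costs[ancestral, derived_state] <- Inf
  costs[derived_state, ancestral] <- 1
  cv <- sankoff_vectors(tree, sets, costs)
  candidates <- ancestors_of(tree, m)  # root .. m; gain on branch above each
  best <- Inf
  for (cnd in candidates) {
    below <- cv[derived_state, cnd]
    # everything outside the subtree of cnd is fixed ancestral: tips outside
    # are non-derived by construction (cnd is an ancestor of all derived
    # tips), so the outside cost is zero.
    best <- min(best, 1 + below)
  }
  as.integer(best)
}

#' Map every character of a matrix onto a tree
#'
#' For each character: Fitch length, minimum conceivable steps (observed
#' states minus one), a homoplasy flag, and the ACCTRAN change list. For
#' binary characters the state not assigned to the root is taken as derived,
#' and gains/losses are counted relative to it.
#'
#' @param tree A rooted \code{"phylo"} tree.
#' @param cm A \code{"character_matrix"} whose taxa cover the tree's tips.
#' @return List with \code{table} (one row per character: \code{character},
#'   \code{steps}, \code{min_steps}, \code{homoplasy}, \code{n_gains},
#'   \code{n_losses}) and \code{reconstructions} (named list).
#' @export
map_all_characters <- function(tree, cm) {
  rows <- vector("list", length(cm$characters))
  recs <- vector("list", length(cm$characters))
  names(recs) <- cm$characters
  for (i in seq_along(cm$characters)) {
    ch <- cm$characters[[i]]
    st <- character_states(cm, ch)
    alpha <- cm$alphabets[[ch]]
    steps <- fitch_length(tree, st, alphabet = alpha)
    min_steps <- max(length(alpha) - 1L, 0L)
    rec <- acctran(tree, st, alphabet = alpha)
    recs[[ch]] <- rec
    if (length(alpha) == 2L) {
      root_state <- rec$node_states[root_node(tree)]
      derived <- setdiff(alpha, root_state)
      n_gains <- count_events(rec, root_state, derived)
      n_losses <- count_events(rec, derived, root_state)
    } else {
      n_gains <- NA_integer_
      n_losses <- NA_integer_
    }
    rows[[i]] <- data.frame(character = ch, steps = steps,
                            min_steps = min_steps,
                            homoplasy = steps > min_steps,
                            n_gains = n_gains, n_losses = n_losses,
                            stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), reconstructions = recs)
}
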