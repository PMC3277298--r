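# -- rooted-subtree enumeration ----------------------------------------------
# candidate subtrees are nested lists (leaf = label); every rooted binary
# shape on the given tips is generated by inserting tips one at a time into
# every edge (including the stem), which enumerates all (2n-3)!! shapes.

subtree_newick <- function(t) {
  if (is.character(t)) return(t)
  paste0("(", subtree_newick(t[[1L]]), ",", subtree_newick(t[[2L]]), ")")
}

insert_everywhere <- function(t, tip) {
  out <- list(list(t, tip))  # on the stem
  if (!is.character(t)) {
    for (side in 1:2) {
      for (sub in insert_everywhere(t[[side]], tip)) {
        tt <- t
        tt[[side]] <- sub
        out[[length(out) + 1L]] <- tt
      }
    }
  }
  out
}

enumerate_rooted <- function(tips) {
  trees <- list(tips[[1L]])
  for (tip in tips[-1L]) {
    trees <- unlist(lapply(trees, insert_everywhere, tip = tip),
                    recursive = FALSE)
  }
  trees
}

replace_tip_newick <- function(newick, label, fragment) {
  pat <- paste0("(?<=[(,])", gsub("([][{}()*+?.\\\\^$|])", "\\\\\\1", label),
                "(?=[,);:])")
  out <- gsub(pat, fragment, newick, perl = TRUE)
  if (identical(out, newick)) stop("species tip not found: ", label)
  out
}

# substitution characters from alignment columns: unambiguous base or '?'
column_states <- function(aln) {
  m <- unclass(as_alignment(aln))
  m[!(m %in% c("A", "C", "G", "T"))] <- "?"
  m
}

#' Parsimony branch lengths on a species-constrained strain tree
#'
#' Replaces each tip of the species tree by the most-parsimonious resolved
#' subtree of that species' strains (exhaustive search over rooted
#' resolutions for up to \code{exhaustive_max} strains, greedy stepwise
#' addition beyond), then assigns every branch an integer length equal to the
#' number of changes mapped onto it under ACCTRAN, summed over all
#' substitution columns plus all indel presence/absence characters (one
#' change per gap, regardless of gap length). The total tree length
#' therefore equals the sum over characters of their parsimony lengths on
#' the chosen tree.
#'
#' Resolution ties break by enumeration order (tips added in lexicographic
#' strain order), making the output deterministic.
#'
#' @param species_tree Rooted \code{"phylo"} species tree.
#' @param species_map Data frame with columns \code{strain}, \code{species}.
#' @param aln An \code{"alignment"} whose rows are the strains.
#' @return A rooted \code{"phylo"} strain tree with integer step branch
#'   lengths (attribute \code{length_unit = "parsimony steps"}).
#' @export
strain_tree_branch_lengths <- function(species_tree, species_map, aln,
                                       exhaustive_max = 7L) {
  aln <- as_alignment(aln)
  strains <- rownames(aln)
  sp <- stats::setNames(species_map$species, species_map$strain)
  missing <- setdiff(strains, names(sp))
  if (length(missing)) stop("unmapped strain: ", missing[[1L]])
  sp <- sp[strains]
  by_species <- split(names(sp), sp)
  empty <- setdiff(species_tree$tip.label, names(by_species))
  if (length(empty)) stop("species with no strains: ", empty[[1L]])
  extra <- setdiff(names(by_species), species_tree$tip.label)
  if (length(extra)) stop("species not in tree: ", extra[[1L]])

  subst <- column_states(aln)
  indels <- indel_characters(aln)
  char_list <- c(
    lapply(seq_len(ncol(subst)), function(j)
      stats::setNames(subst[, j], strains)),
    lapply(indels$characters, function(ch) character_states(indels, ch))
  )
  # characters that can never change contribute nothing and are skipped
  informative <- vapply(char_list, function(st)
    length(observed_alphabet(st)) >= 2L, logical(1))
  char_list <- char_list[informative]

  # a character influences the choice of a species' resolution only if it is
  # variable (or partially missing) within that species
  active_for <- function(strain_set) {
    vapply(char_list, function(st) {
      s <- st[strain_set]
      length(unique(s)) > 1L || any(s == "?")
    }, logical(1))
  }

  resolution <- list()
  for (s in names(by_species)) {
    tips <- sort(by_species[[s]])
    if (length(tips) <= 2L) {
      resolution[[s]] <- if (length(tips) == 1L) tips[[1L]] else
        paste0("(", tips[[1L]], ",", tips[[2L]], ")")
    } else {
      resolution[[s]] <- NA  # placed below, scored in tree context
    }
  }
  base_newick <- write_newick(drop_lengths(species_tree))
  build_newick <- function(res) {
    nw <- base_newick
    for (s in names(res)) nw <- replace_tip_newick(nw, s, res[[s]])
    nw
  }
  score_tree <- function(tree, active) {
    sum(vapply(char_list[active], function(st)
      fitch_length(tree, st), numeric(1)))
  }
  # initial caterpillar resolutions for the multi-strain species
  for (s in names(by_species)) {
    tips <- sort(by_species[[s]])
    if (length(tips) > 2L && is.na(resolution[[s]])) {
      frag <- tips[[1L]]
      for (tp in tips[-1L]) frag <- paste0("(", frag, ",", tp, ")")
      resolution[[s]] <- frag
    }
  }
  # per-species optimisation against the rest of the tree held fixed
  for (s in names(by_species)) {
    tips <- sort(by_species[[s]])
    if (length(tips) <= 2L) next
    active <- active_for(tips)
    if (!any(active)) next
    others <- resolution
    if (length(tips) <= exhaustive_max) {
      candidates <- enumerate_rooted(as.list(tips))
      best <- NULL
      best_score <- Inf
      for (cand in candidates) {
        others[[s]] <- subtree_newick(cand)
        sc <- score_tree(parse_newick(paste0(build_newick(others), "")),
                         active)
        if (sc < best_score) {
          best_score <- sc
          best <- others[[s]]
        }
      }
      resolution[[s]] <- best
    } else {
      # greedy stepwise addition in lexicographic order
      struct <- tips[[1L]]
      for (tp in tips[-1L]) {
        cands <- insert_everywhere(struct, tp)
        best <- NULL
        best_score <- Inf
        for (cand in cands) {
          others[[s]] <- subtree_newick(cand)
          sc <- score_tree(parse_newick(build_newick(others)), active)
          if (sc < best_score) {
            best_score <- sc
            best <- cand
          }
        }
        struct <- best
      }
      resolution[[s]] <- subtree_newick(struct)
    }
  }
  tree <- parse_newick(build_newick(resolution))
  # ACCTRAN change counts per branch over all characters
  counts <- numeric(max(tree$edge))
  for (st in char_list) {
    rec <- acctran(tree, st)
    if (nrow(rec$changes)) {
      tab <- table(rec$changes$node)
      counts[as.integer(names(tab))] <- counts[as.integer(names(tab))] +
        as.integer(tab)
    }
  }
  tree$edge.length <- counts[tree$edge[, 2L]]
  attr(tree, "length_unit") <- "parsimony steps"
  tree
}

flatten_tips <- function(t) {
  if (is.character(t)) t else c(flatten_tips(t[[1L]]), flatten_tips(t[[2L]]))
}

drop_lengths <- function(tree) {
  tree$edge.length <- NULL
  tree
}
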