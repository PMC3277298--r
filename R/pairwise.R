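#' Classify the differences between two aligned sequences
#'
#' Columns where both sequences are gapped are dropped first. Remaining
#' columns where exactly one sequence is gapped are grouped into maximal runs
#' by which sequence carries the gap; each run counts as a single indel event
#' ("one change per gap, regardless of the length of the gap"). Base-base
#' columns with two distinct unambiguous bases are counted as a transition
#' (A<->G, C<->T) or transversion; columns involving an IUPAC ambiguity code
#' are skipped for substitution counting and tallied separately.
#'
#' @param a,b Aligned sequences of equal length (character scalars or rows of
#'   an \code{"alignment"}).
#' @return A list of class \code{"diff_summary"}: \code{transitions},
#'   \code{transversions}, \code{substitutions}, \code{indel_events},
#'   \code{ambiguous}, \code{both_gap_columns}, \code{compared_columns}.
#' @export
pairwise_differences <- function(a, b) {
  av <- if (length(a) > 1L) toupper(a) else strsplit(toupper(a), "")[[1L]]
  bv <- if (length(b) > 1L) toupper(b) else strsplit(toupper(b), "")[[1L]]
  if (length(av) != length(bv)) stop("sequences differ in length")
  both_gap <- av == "-" & bv == "-"
  av <- av[!both_gap]
  bv <- bv[!both_gap]
  gap_a <- av == "-"
  gap_b <- bv == "-"
  # indel events: maximal runs of one-gapped columns, per gapped sequence
  run_events <- function(g) {
    if (!any(g)) return(0L)
    r <- rle(g)
    sum(r$values)
  }
  indel_events <- run_events(gap_a) + run_events(gap_b)
  bb <- !gap_a & !gap_b
  pure <- c("A", "C", "G", "T")
  unamb <- bb & av %in% pure & bv %in% pure
  ambiguous <- sum(bb & !unamb)
  diffs <- unamb & av != bv
  ts <- sum(diffs & ((av == "A" & bv == "G") | (av == "G" & bv == "A") |
                       (av == "C" & bv == "T") | (av == "T" & bv == "C")))
  tv <- sum(diffs) - ts
  structure(list(transitions = ts, transversions = tv,
                 substitutions = ts + tv, indel_events = indel_events,
                 ambiguous = ambiguous,
                 both_gap_columns = sum(both_gap),
                 compared_columns = length(av)),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat("<diff_summary> ts:", x$transitions, " tv:", x$transversions,
      " indel events:", x$indel_events, " ambiguous:", x$ambiguous, "\n")
  invisible(x)
}

#' Pairwise difference table for a whole alignment
#'
#' @param aln An \code{"alignment"} with at least two sequences.
#' @return Data frame with one row per unordered pair: \code{strain_a},
#'   \code{strain_b}, \code{transitions}, \code{transversions},
#'   \code{substitutions}, \code{indel_events}, \code{ambiguous},
#'   \code{compared_columns}.
#' @export
all_pairwise <- function(aln) {
  aln <- as_alignment(aln)
  labs <- rownames(aln)
  if (length(labs) < 2L) stop("need at least two sequences")
  pairs <- utils::combn(labs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    d <- pairwise_differences(unclass(aln)[pairs[1L, i], ],
                              unclass(aln)[pairs[2L, i], ])
    data.frame(strain_a = pairs[1L, i], strain_b = pairs[2L, i],
               transitions = d$transitions, transversions = d$transversions,
               substitutions = d$substitutions,
               indel_events = d$indel_events, ambiguous = d$ambiguous,
               compared_columns = d$compared_columns,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# maximal gap runs per row: list of two-column matrices (start, end), 1-based
# inclusive alignment coordinates
gap_runs <- function(aln) {
  aln <- as_alignment(aln)
  lapply(seq_len(nrow(aln)), function(i) {
    g <- unclass(aln)[i, ] == "-"
    if (!any(g)) return(cbind(start = integer(0), end = integer(0)))
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  })
}

#' Binary presence/absence characters from shared gap runs
#'
#' Simple indel coding: every distinct maximal gap run coordinate pair
#' observed in any row becomes one binary character; a row is scored
#' "present" iff it is gapped across exactly that run. Used to let indels
#' contribute one parsimony step per gap.
#'
#' @param aln An \code{"alignment"}.
#' @return A \code{"character_matrix"} with characters named
#'   \code{indel_<start>_<end>} (1-based inclusive columns) and states
#'   \code{"present"}/\code{"absent"}; zero characters for gap-free input.
#' @export
indel_characters <- function(aln) {
  aln <- as_alignment(aln)
  runs <- gap_runs(aln)
  all_runs <- unique(do.call(rbind, runs))
  labs <- rownames(aln)
  if (is.null(all_runs) || nrow(all_runs) == 0L) {
    cells <- matrix(character(0), nrow = length(labs), ncol = 0L,
                    dimnames = list(labs, character(0)))
    return(new_character_matrix(cells))
  }
  all_runs <- all_runs[order(all_runs[, 1L], all_runs[, 2L]), , drop = FALSE]
  cells <- matrix("absent", length(labs), nrow(all_runs),
                  dimnames = list(labs, paste0("indel_", all_runs[, 1L], "_",
                                               all_runs[, 2L])))
  for (i in seq_along(labs)) {
    ri <- runs[[i]]
    if (nrow(ri)) {
      hit <- match(paste(ri[, 1L], ri[, 2L]),
                   paste(all_runs[, 1L], all_runs[, 2L]))
      cells[i, hit] <- "present"
    }
  }
  new_character_matrix(cells)
}

#' Read a strain-to-species map
#' @param path TSV with columns \code{strain} and \code{species} (header
#'   optional if exactly two columns).
#' @return Data frame with columns \code{strain}, \code{species}.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (!all(c("strain", "species") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, colClasses = "character")
    names(df) <- c("strain", "species")
  }
  df[, c("strain", "species")]
}

#' Barcode-gap report from a pairwise difference table
#'
#' The barcode-gap criterion for a marker: within every species, the largest
#' intra-specific distance should fall below the smallest distance to any
#' other species. Distance is substitutions + indel events (each indel run =
#' one event); the components are also reported so substitution-only
#' thresholds can be applied.
#'
#' @param diffs Data frame as produced by \code{\link{all_pairwise}}.
#' @param species_map Data frame with columns \code{strain}, \code{species}
#'   covering every strain in \code{diffs}.
#' @return List of class \code{"barcode_gap_report"}: \code{intra} (per
#'   species with >= 2 strains: max intra-specific substitutions, indel
#'   events and total), \code{inter} (per species pair: min total distance
#'   and its components), \code{violations} (species whose max intra >= min
#'   inter to any other species).
#' @export
barcode_gap_report <- function(diffs, species_map) {
  strains <- unique(c(diffs$strain_a, diffs$strain_b))
  sp <- stats::setNames(species_map$species, species_map$strain)
  missing <- setdiff(strains, names(sp))
  if (length(missing)) stop("unmapped strain: ", missing[[1L]])
  sa <- sp[diffs$strain_a]
  sb <- sp[diffs$strain_b]
  total <- diffs$substitutions + diffs$indel_events
  intra_idx <- which(sa == sb)
  intra <- if (length(intra_idx)) {
    agg <- lapply(split(intra_idx, sa[intra_idx]), function(ix) {
      j <- ix[which.max(total[ix])]
      data.frame(species = sa[j],
                 max_intra_substitutions = max(diffs$substitutions[ix]),
                 max_intra_indels = max(diffs$indel_events[ix]),
                 max_intra_total = total[j], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(species = character(0), max_intra_substitutions = integer(0),
               max_intra_indels = integer(0), max_intra_total = integer(0))
  }
  inter_idx <- which(sa != sb)
  key <- ifelse(sa < sb, paste(sa, sb, sep = "\r"), paste(sb, sa, sep = "\r"))
  inter <- if (length(inter_idx)) {
    agg <- lapply(split(inter_idx, key[inter_idx]), function(ix) {
      j <- ix[which.min(total[ix])]
      parts <- strsplit(key[j], "\r", fixed = TRUE)[[1L]]
      data.frame(species_a = parts[1L], species_b = parts[2L],
                 min_inter_substitutions = diffs$substitutions[j],
                 min_inter_indels = diffs$indel_events[j],
                 min_inter_total = total[j], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    out
  } else {
    data.frame(species_a = character(0), species_b = character(0),
               min_inter_substitutions = integer(0),
               min_inter_indels = integer(0), min_inter_total = integer(0))
  }
  violations <- character(0)
  for (i in seq_len(nrow(intra))) {
    s <- intra$species[i]
    rel <- inter[inter$species_a == s | inter$species_b == s, ]
    if (nrow(rel) && intra$max_intra_total[i] >= min(rel$min_inter_total)) {
      violations <- c(violations, s)
    }
  }
  structure(list(intra = intra, inter = inter, violations = violations),
            class = "barcode_gap_report")
}

#' @export
print.barcode_gap_report <- function(x, ...) {
  cat("<barcode_gap_report>", nrow(x$intra), "species with >=2 strains;",
      length(x$violations), "violation(s)\n")
  if (length(x$violations)) cat("  flagged:", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}
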