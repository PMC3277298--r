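IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ALN_ALPHABET <- c(names(IUPAC_CODES), "-")

#' Build an alignment object from sequences
#'
#' @param x Named character vector of equal-length aligned sequences over
#'   A/C/G/T, IUPAC ambiguity codes and \code{"-"} (case-insensitive).
#' @return An object of class \code{"alignment"}: a character matrix with one
#'   row per sequence and one column per alignment column (stored uppercase).
#' @export
as_alignment <- function(x) {
  if (inherits(x, "alignment")) return(x)
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x)) || any(!nzchar(names(x)))) {
      stop("sequences must carry unique non-empty labels")
    }
    if (length(unique(nchar(x))) != 1L) stop("sequences differ in length")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  bad <- setdiff(unique(as.vector(m)), ALN_ALPHABET)
  if (length(bad)) stop("disallowed alignment character: ", bad[[1L]])
  structure(m, class = c("alignment", class(m)))
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length) FASTA file.
#' @return An \code{"alignment"} object.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  as_alignment(stats::setNames(as.character(seqs), names(seqs)))
}

#' Write an alignment as FASTA
#' @param aln An \code{"alignment"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

aln_strings <- function(aln) {
  apply(unclass(as_alignment(aln)), 1L, paste, collapse = "")
}

#' Trim an alignment to the region between two conserved anchors
#'
#' Locates \code{anchor5} and then \code{anchor3} in a designated reference
#' row (gaps in the row are skipped during matching; at most
#' \code{max_mismatch} mismatches allowed, first occurrence wins) and returns
#' the alignment columns strictly between the two anchor matches, all rows.
#' This is how a fast-evolving marker such as ITS2 is cut out of an amplicon
#' alignment anchored in the flanking rRNA genes.
#'
#' @param aln An \code{"alignment"}.
#' @param anchor5,anchor3 DNA motifs (character scalars, no gaps).
#' @param max_mismatch Maximum number of mismatching positions per anchor.
#' @param reference Label or index of the reference row (default first row).
#' @return The trimmed \code{"alignment"}.
#' @export
trim_to_marker <- function(aln, anchor5, anchor3, max_mismatch = 2L,
                           reference = 1L) {
  aln <- as_alignment(aln)
  if (!nzchar(anchor5) || !nzchar(anchor3)) stop("anchors must be non-empty")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  ref <- unclass(aln)[reference, ]
  unga <- which(ref != "-")
  seq <- ref[unga]
  find_anchor <- function(motif, from) {
    pat <- strsplit(toupper(motif), "", fixed = TRUE)[[1L]]
    w <- length(pat)
    last <- length(seq) - w + 1L
    if (from > last) return(NULL)
    for (s in from:last) {
      if (sum(seq[s:(s + w - 1L)] != pat) <= max_mismatch) {
        return(c(start = s, end = s + w - 1L))
      }
    }
    NULL
  }
  m5 <- find_anchor(anchor5, 1L)
  if (is.null(m5)) stop("5' anchor not found in reference row")
  m3 <- find_anchor(anchor3, m5[["end"]] + 1L)
  if (is.null(m3)) stop("3' anchor not found downstream of the 5' anchor")
  first_col <- unga[m5[["end"]]] + 1L
  last_col <- unga[m3[["start"]]] - 1L
  if (first_col > last_col) stop("anchors are adjacent: empty marker region")
  structure(unclass(aln)[, first_col:last_col, drop = FALSE],
            class = class(aln))
}
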