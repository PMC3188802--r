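#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with a BLOSUM substitution matrix and
#' affine gap penalties (defaults: BLOSUM62, open 11, extend 1), the
#' conventional scoring for cross-species protein comparison. Alignment is
#' computed by \code{Biostrings::pairwiseAlignment}, which resolves score
#' ties deterministically.
#'
#' @param protein_a,protein_b Protein sequences (character scalars or
#'   \code{AAString}); must be non-empty and contain amino-acid letters
#'   only.
#' @param substitution Name of a substitution matrix shipped with
#'   Biostrings (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Affine gap penalties in score units.
#' @return list of class \code{protein_alignment}: the input sequences
#'   \code{a}, \code{b}; gapped strings \code{aligned_a}, \code{aligned_b}
#'   of equal length; \code{score}; and \code{map}, a data.frame of
#'   aligned residue position pairs (\code{pos_a}, \code{pos_b}).
#' @export
global_align <- function(protein_a, protein_b, substitution = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  a <- as.character(protein_a)
  b <- as.character(protein_b)
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", a) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", b))
    stop("non-amino-acid symbols in input")
  mat <- get(data(list = substitution, package = "Biostrings",
                  envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  va <- strsplit(al_a, "")[[1L]]
  vb <- strsplit(al_b, "")[[1L]]
  both <- va != "-" & vb != "-"
  map <- data.frame(pos_a = cumsum(va != "-")[both],
                    pos_b = cumsum(vb != "-")[both])
  structure(list(a = a, b = b, aligned_a = al_a, aligned_b = al_b,
                 score = Biostrings::score(pa), map = map),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment: score", x$score, "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}
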