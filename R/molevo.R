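# Nei-Gojobori style dN/dS: proportional site counting with stop-aware
# substitution-path enumeration and the one-parameter multiple-hit
# correction d = -3/4 ln(1 - 4p/3).

.ng_cache <- new.env(parent = emptyenv())

.codon_split <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori codon tables
#'
#' Per-codon synonymous site fractions and per-codon-pair synonymous /
#' nonsynonymous difference counts. Sites: at each codon position the
#' three possible single-nucleotide changes are classified; changes that
#' create a stop codon count as nonsynonymous. Differences: all orderings
#' of the differing positions are enumerated, paths passing through a stop
#' codon are discarded, and synonymous/nonsynonymous step counts are
#' averaged over the remaining paths (over all paths if every path is
#' blocked). Computed once and cached.
#'
#' @return list with \code{codons} (the 61 sense codons),
#'   \code{syn_sites} (named numeric), and 61x61 matrices \code{Sd},
#'   \code{Nd}.
#' @export
ng_codon_tables <- function() {
  if (!is.null(.ng_cache$tables)) return(.ng_cache$tables)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  nt <- c("A", "C", "G", "T")
  aa_of <- function(codon) unname(gc_tab[codon])
  syn_sites <- vapply(codons, function(cod) {
    ref <- aa_of(cod)
    v <- strsplit(cod, "")[[1L]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(nt, v[pos])) {
        w <- v; w[pos] <- b
        alt <- paste(w, collapse = "")
        if (aa_of(alt) != "*" && aa_of(alt) == ref) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  n <- length(codons)
  Sd <- matrix(0, n, n, dimnames = list(codons, codons))
  Nd <- matrix(0, n, n, dimnames = list(codons, codons))
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(n)) {
    vi <- strsplit(codons[i], "")[[1L]]
    for (j in seq_len(n)) {
      if (i == j) next
      vj <- strsplit(codons[j], "")[[1L]]
      diffs <- which(vi != vj)
      k <- length(diffs)
      paths <- perms[[k]]
      step_counts <- lapply(paths, function(ord) {
        cur <- vi
        syn <- 0; nonsyn <- 0; blocked <- FALSE
        for (pos in diffs[ord]) {
          prev_aa <- aa_of(paste(cur, collapse = ""))
          cur[pos] <- vj[pos]
          cur_codon <- paste(cur, collapse = "")
          cur_aa <- aa_of(cur_codon)
          if (cur_aa == "*") blocked <- TRUE
          if (cur_aa == prev_aa) syn <- syn + 1 else nonsyn <- nonsyn + 1
        }
        c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
      })
      m <- do.call(rbind, step_counts)
      use <- m[, "blocked"] == 0
      if (!any(use)) use <- rep(TRUE, nrow(m))
      Sd[i, j] <- mean(m[use, "syn"])
      Nd[i, j] <- mean(m[use, "nonsyn"])
    }
  }
  .ng_cache$tables <- list(codons = codons, syn_sites = syn_sites,
                           Sd = Sd, Nd = Nd)
  .ng_cache$tables
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned protein column becomes one codon column; protein gaps
#' become whole-codon gaps (\code{"---"}). Optionally masks repeat-derived
#' codon columns (significant amino-acid homopolymer residues) so they are
#' excluded from divergence counts, matching the convention of estimating
#' dN with repeat sequences excluded.
#'
#' @param cds_a,cds_b In-frame CDS character scalars (no stop codon), whose
#'   translations equal the aligned proteins.
#' @param alignment A \code{\link{global_align}} result.
#' @param mask_a,mask_b Optional integer vectors of 1-based residue
#'   positions to exclude (e.g. significant homopolymer runs).
#' @return list with aligned codon vectors \code{codons_a}, \code{codons_b}
#'   and logical \code{masked} per column.
#' @export
codon_align <- function(cds_a, cds_b, alignment,
                        mask_a = integer(), mask_b = integer()) {
  ca <- .codon_split(cds_a)
  cb <- .codon_split(cds_b)
  pa <- .translate_cds(cds_a)
  pb <- .translate_cds(cds_b)
  da <- gsub("-", "", alignment$aligned_a, fixed = TRUE)
  db <- gsub("-", "", alignment$aligned_b, fixed = TRUE)
  .check_translation(pa, da, "a")
  .check_translation(pb, db, "b")
  va <- strsplit(alignment$aligned_a, "")[[1L]]
  vb <- strsplit(alignment$aligned_b, "")[[1L]]
  ia <- cumsum(va != "-")
  ib <- cumsum(vb != "-")
  codons_a <- ifelse(va == "-", "---", ca[ia])
  codons_b <- ifelse(vb == "-", "---", cb[ib])
  masked <- (va != "-" & ia %in% mask_a) | (vb != "-" & ib %in% mask_b)
  list(codons_a = codons_a, codons_b = codons_b, masked = masked)
}

.translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

.check_translation <- function(translated, protein, label) {
  if (translated != protein) {
    va <- strsplit(translated, "")[[1L]]
    vb <- strsplit(protein, "")[[1L]]
    k <- min(length(va), length(vb))
    pos <- which(va[seq_len(k)] != vb[seq_len(k)])[1L]
    if (is.na(pos)) pos <- k + 1L
    stop("CDS translation does not match protein for sequence ", label,
         "; first difference at residue ", pos)
  }
}

#' Estimate dN (and dS) from a codon alignment
#'
#' Nei-Gojobori proportional counting: per-codon synonymous and
#' nonsynonymous site fractions are averaged over the two sequences;
#' observed differences are classified by enumerating minimal substitution
#' paths (multiple-hit codons average over unblocked paths); proportions
#' are corrected by \eqn{d = -3/4 \log(1 - 4p/3)}. Saturated proportions
#' (\eqn{p \ge 3/4}) give an undefined estimate, flagged rather than
#' returned as a number.
#'
#' @param alignment A codon alignment from \code{\link{codon_align}}, or a
#'   list with \code{codons_a}, \code{codons_b} (equal-length codon
#'   vectors, \code{"---"} for gaps) and optional \code{masked}.
#' @param min_codons Minimum comparable (ungapped, unmasked) codon pairs
#'   required; default 10.
#' @return list: \code{dN}, \code{dS} (NA when saturated), \code{pN},
#'   \code{pS}, \code{N}, \code{S}, \code{Nd}, \code{Sd},
#'   \code{n_codons}, \code{saturated_n}, \code{saturated_s}.
#' @export
estimate_dn <- function(alignment, min_codons = 10L) {
  tabs <- ng_codon_tables()
  a <- alignment$codons_a
  b <- alignment$codons_b
  masked <- alignment$masked
  if (is.null(masked)) masked <- rep(FALSE, length(a))
  stopifnot(length(a) == length(b), length(masked) == length(a))
  gap <- a == "---" | b == "---"
  stop_a <- !gap & !(a %in% tabs$codons)
  stop_b <- !gap & !(b %in% tabs$codons)
  if (any(stop_a | stop_b))
    stop("stop or invalid codon mid-sequence at aligned codon ",
         which(stop_a | stop_b)[1L])
  use <- !gap & !masked
  n_codons <- sum(use)
  if (n_codons < min_codons)
    stop("only ", n_codons, " comparable codon pairs (need >= ",
         min_codons, ")")
  a <- a[use]; b <- b[use]
  S <- (sum(tabs$syn_sites[a]) + sum(tabs$syn_sites[b])) / 2
  N <- 3 * n_codons - S
  idx <- cbind(match(a, tabs$codons), match(b, tabs$codons))
  Sd <- sum(tabs$Sd[idx])
  Nd <- sum(tabs$Nd[idx])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(dN = jc(pN), dS = jc(pS), pN = pN, pS = pS,
       N = N, S = S, Nd = Nd, Sd = Sd, n_codons = n_codons,
       saturated_n = pN >= 0.75, saturated_s = pS >= 0.75)
}

#' Conservation score of an aligned ortholog pair
#'
#' Identical aligned residue pairs divided by the length of the longer
#' unaligned sequence, so both point differences and non-aligned
#' (gapped or missing) portions reduce the score. This explicit formula is
#' this package's stand-in for conservation measures that penalize both
#' mismatch and unalignable sequence; it is 1 exactly when the two
#' sequences are identical.
#'
#' @param alignment A \code{\link{global_align}} result.
#' @return Score in [0, 1].
#' @export
conservation_score <- function(alignment) {
  va <- strsplit(alignment$aligned_a, "")[[1L]]
  vb <- strsplit(alignment$aligned_b, "")[[1L]]
  if (length(va) == 0L) stop("empty alignment")
  ident <- sum(va == vb & va != "-")
  longer <- max(sum(va != "-"), sum(vb != "-"))
  ident / longer
}
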