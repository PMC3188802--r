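# Amino-acid homopolymer runs and the composition-based chance model that
# decides which runs are longer than expected by chance.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Smallest run length longer than expected by chance
#'
#' Chance model: the expected number of runs of length >= L of an amino
#' acid with proteome frequency f, across a proteome of N residues, is
#' bounded by N * f^L; the threshold is the smallest L (>= 2) with
#' N * f^L <= alpha.
#'
#' @param f Amino-acid frequency in the proteome.
#' @param total_residues Proteome size N, residues.
#' @param alpha Significance level (default 0.01).
#' @return Integer threshold, or NA when f is 0 (no run of an absent amino
#'   acid can be called).
#' @export
min_run_len <- function(f, total_residues, alpha = 0.01) {
  if (is.na(f) || f <= 0) return(NA_integer_)
  if (f >= 1) return(NA_integer_)
  L <- 2L
  while (total_residues * f^L > alpha && L < 1000L) L <- L + 1L
  L
}

#' Per-amino-acid homopolymer significance thresholds
#'
#' Frequencies are computed from the supplied proteome; thresholds from
#' \code{\link{min_run_len}}. On compositions like the AT-rich
#' dictyostelid proteomes the thresholds fall in the 6-9 residue range
#' (runs "longer than expected by chance" are > 5 to > 9 residues
#' depending on the amino acid).
#'
#' @param proteome \code{AAStringSet} or character vector of protein
#'   sequences (>= 1,000 residues in total).
#' @param alpha Significance level (default 0.01).
#' @return data.frame: \code{amino_acid}, \code{frequency},
#'   \code{min_len}, \code{defined}.
#' @export
aa_run_thresholds <- function(proteome, alpha = 0.01) {
  seqs <- as.character(proteome)
  all_chars <- unlist(strsplit(seqs, ""))
  total <- length(all_chars)
  if (total < 1000L)
    stop("proteome too small (", total, " residues; need >= 1,000)")
  counts <- table(factor(all_chars, levels = .AA20))
  freqs <- as.numeric(counts) / total
  min_len <- vapply(freqs, min_run_len, integer(1),
                    total_residues = total, alpha = alpha)
  data.frame(amino_acid = .AA20, frequency = freqs,
             min_len = min_len, defined = !is.na(min_len),
             stringsAsFactors = FALSE)
}

.runs_of_protein <- function(seq) {
  v <- strsplit(seq, "")[[1L]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(amino_acid = r$values, start = ends - r$lengths + 1L,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Find amino-acid homopolymer runs
#'
#' All maximal single-amino-acid runs of length >= 2, flagged significant
#' when the run length reaches the amino acid's chance threshold. When CDS
#' sequences are supplied the backing codons are attached (and the CDS
#' translation is checked against the protein).
#'
#' @param proteins \code{AAStringSet} or named character vector.
#' @param thresholds data.frame from \code{\link{aa_run_thresholds}}.
#' @param cds Optional named character vector / \code{DNAStringSet} of
#'   in-frame CDS (no stop codon) for the same ids.
#' @param min_len Minimum run length to report (default 2).
#' @return data.frame: \code{protein_id}, \code{amino_acid}, \code{start}
#'   (1-based residue), \code{length}, \code{significant}, \code{codons}
#'   (comma-separated, NA without CDS).
#' @export
find_homopolymers <- function(proteins, thresholds, cds = NULL,
                              min_len = 2L) {
  seqs <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(seqs)))
    names(seqs) <- paste0("protein", seq_along(seqs))
  if (!is.null(cds)) cds <- setNames(as.character(cds), names(cds))
  thr <- setNames(thresholds$min_len, thresholds$amino_acid)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    runs <- .runs_of_protein(seqs[i])
    runs <- runs[runs$length >= min_len, , drop = FALSE]
    if (nrow(runs) == 0L) next
    tl <- thr[runs$amino_acid]
    runs$significant <- !is.na(tl) & runs$length >= tl
    runs$protein_id <- id
    if (!is.null(cds) && id %in% names(cds)) {
      .check_translation(.translate_cds(cds[[id]]), seqs[[i]], id)
      codons <- .codon_split(cds[[id]])
      runs$codons <- vapply(seq_len(nrow(runs)), function(j)
        paste(codons[seq.int(runs$start[j],
                             runs$start[j] + runs$length[j] - 1L)],
              collapse = ","), character(1))
    } else {
      runs$codons <- NA_character_
    }
    out[[i]] <- runs[, c("protein_id", "amino_acid", "start", "length",
                         "significant", "codons")]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(), amino_acid = character(),
                      start = integer(), length = integer(),
                      significant = logical(), codons = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Repeat density per amino acid
#'
#' Sum of the lengths of significant runs of each amino acid, divided by
#' the total length of coding sequence (in residues) and multiplied by
#' 1,000.
#'
#' @param runs data.frame from \code{\link{find_homopolymers}}.
#' @param total_residues Proteome size, residues (> 0).
#' @return Named numeric vector over the 20 amino acids, residues per
#'   1,000 residues.
#' @export
repeat_density <- function(runs, total_residues) {
  if (total_residues <= 0) stop("total_residues must be positive")
  sig <- runs[runs$significant, , drop = FALSE]
  dens <- vapply(.AA20, function(a)
    sum(sig$length[sig$amino_acid == a]) / total_residues * 1000,
    numeric(1))
  setNames(dens, .AA20)
}

#' Correlation between two per-amino-acid density vectors
#'
#' @param dens_a,dens_b Named numeric vectors over the same 20 amino
#'   acids.
#' @return list: \code{r} (Pearson), \code{p} (two-sided), \code{n},
#'   \code{degenerate} (TRUE when either vector has zero variance, in
#'   which case r and p are NA).
#' @export
density_correlation <- function(dens_a, dens_b) {
  stopifnot(length(dens_a) == length(dens_b))
  if (!is.null(names(dens_a)) && !is.null(names(dens_b)))
    stopifnot(all(names(dens_a) == names(dens_b)))
  if (stats::sd(dens_a) == 0 || stats::sd(dens_b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(dens_a),
                degenerate = TRUE))
  ct <- stats::cor.test(dens_a, dens_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(dens_a),
       degenerate = FALSE)
}

#' Codon diversity of one homopolymer run
#'
#' Distinct backing codons, and a normalized diversity in [0, 1]:
#' (distinct - 1) / (min(run length, codons available for the amino acid)
#' - 1), defined as 0 when the denominator is 0 (e.g. methionine runs).
#'
#' @param codons Character vector of codons backing the run, or the
#'   comma-separated \code{codons} field of
#'   \code{\link{find_homopolymers}}.
#' @return list: \code{distinct}, \code{diversity}.
#' @export
codon_diversity <- function(codons) {
  if (length(codons) == 1L && grepl(",", codons))
    codons <- strsplit(codons, ",")[[1L]]
  if (length(codons) == 0L || all(is.na(codons)))
    stop("no codons attached to this run")
  aas <- unique(unname(Biostrings::GENETIC_CODE[codons]))
  if (length(aas) != 1L || is.na(aas))
    stop("codons do not all translate to one amino acid")
  avail <- sum(Biostrings::GENETIC_CODE == aas)
  distinct <- length(unique(codons))
  denom <- min(length(codons), avail) - 1L
  list(distinct = distinct,
       diversity = if (denom <= 0L) 0 else (distinct - 1L) / denom)
}

#' Call cross-species homology of homopolymer runs
#'
#' A run pair is homologous when both runs are of the same amino acid and
#' their residue spans share at least \code{min_overlap} aligned columns
#' in the global alignment of the two ortholog proteins. Only significant
#' runs enter the calls. Reported fractions use significant runs in genes
#' with an ortholog as the denominator; runs in genes without a partner
#' are tallied separately against both the all-runs and ortholog-only
#' denominators.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b} (one-to-one
#'   ortholog pairs).
#' @param runs_a,runs_b Significant runs (\code{\link{find_homopolymers}}
#'   output, filtered to \code{significant}).
#' @param alignments Named list of \code{\link{global_align}} results, one
#'   per pair, named \code{<gene_a>|<gene_b>}.
#' @param min_overlap Minimum shared aligned columns (default 1).
#' @return list: \code{calls} data.frame (one row per run pair tested,
#'   with \code{homologous}), and per-species summaries \code{fractions}:
#'   counts of runs total / in ortholog genes / homologous, the fraction
#'   homologous, and the fraction of runs in genes lacking a partner.
#' @export
call_repeat_homology <- function(pairs, runs_a, runs_b, alignments,
                                 min_overlap = 1L) {
  if (any(!runs_a$significant) || any(!runs_b$significant))
    stop("runs must be restricted to significant ones")
  calls <- list()
  hom_a <- character(); hom_b <- character()
  for (r in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[r]; gb <- pairs$gene_b[r]
    key <- paste0(ga, "|", gb)
    aln <- alignments[[key]]
    ra <- runs_a[runs_a$protein_id == ga, , drop = FALSE]
    rb <- runs_b[runs_b$protein_id == gb, , drop = FALSE]
    if (nrow(ra) == 0L && nrow(rb) == 0L) next
    if (is.null(aln))
      stop("no alignment supplied for pair ", key)
    map <- aln$map
    for (i in seq_len(nrow(ra))) {
      span_a <- seq.int(ra$start[i], ra$start[i] + ra$length[i] - 1L)
      for (j in seq_len(nrow(rb))) {
        if (ra$amino_acid[i] != rb$amino_acid[j]) {
          shared <- 0L
        } else {
          span_b <- seq.int(rb$start[j], rb$start[j] + rb$length[j] - 1L)
          shared <- sum(map$pos_a %in% span_a & map$pos_b %in% span_b)
        }
        hom <- shared >= min_overlap
        if (hom) {
          hom_a <- c(hom_a, paste0(ga, ":", ra$start[i]))
          hom_b <- c(hom_b, paste0(gb, ":", rb$start[j]))
        }
        calls[[length(calls) + 1L]] <- data.frame(
          gene_a = ga, gene_b = gb,
          amino_acid_a = ra$amino_acid[i], start_a = ra$start[i],
          amino_acid_b = rb$amino_acid[j], start_b = rb$start[j],
          shared_columns = shared, homologous = hom,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(gene_a = character(), gene_b = character(),
               amino_acid_a = character(), start_a = integer(),
               amino_acid_b = character(), start_b = integer(),
               shared_columns = integer(), homologous = logical(),
               stringsAsFactors = FALSE)
  summarize <- function(runs, genes_with_orth, hom_keys) {
    n_total <- nrow(runs)
    in_orth <- runs$protein_id %in% genes_with_orth
    n_orth <- sum(in_orth)
    keys <- paste0(runs$protein_id, ":", runs$start)
    n_hom <- sum(keys %in% hom_keys)
    list(n_runs = n_total, n_runs_in_ortholog_genes = n_orth,
         n_homologous = n_hom,
         frac_homologous = if (n_orth > 0) n_hom / n_orth else NA_real_,
         frac_no_homolog_all = if (n_total > 0)
           (n_total - n_orth) / n_total else NA_real_)
  }
  list(calls = calls,
       fractions = list(
         a = summarize(runs_a, pairs$gene_a, unique(hom_a)),
         b = summarize(runs_b, pairs$gene_b, unique(hom_b))))
}

#' Compare a per-gene statistic between repeat-bearing and repeat-free
#' genes
#'
#' Two-sided two-sample test (Student's t or Mann-Whitney U) of a per-gene
#' value (e.g. dN, conservation score, expression) between genes with and
#' without significant amino-acid repeats.
#'
#' @param values Numeric per-gene statistic.
#' @param has_repeat Logical per-gene flag (same length).
#' @param test \code{"t"} or \code{"mannwhitney"}.
#' @return list: group \code{n}, \code{means}, \code{medians},
#'   \code{direction} (sign of with-repeat minus without),
#'   \code{p}, \code{degenerate} flag (both groups constant and equal).
#' @export
compare_by_repeat_status <- function(values, has_repeat,
                                     test = c("t", "mannwhitney")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(has_repeat))
  keep <- !is.na(values) & !is.na(has_repeat)
  values <- values[keep]; has_repeat <- has_repeat[keep]
  g1 <- values[has_repeat]; g0 <- values[!has_repeat]
  if (length(g1) < 2L || length(g0) < 2L)
    stop("each group needs at least 2 observations")
  degenerate <- stats::sd(values) == 0
  p <- if (degenerate) NA_real_ else if (test == "t")
    stats::t.test(g1, g0)$p.value
  else
    stats::wilcox.test(g1, g0, exact = FALSE, correct = TRUE)$p.value
  list(n = c(with_repeat = length(g1), without_repeat = length(g0)),
       means = c(with_repeat = mean(g1), without_repeat = mean(g0)),
       medians = c(with_repeat = stats::median(g1),
                   without_repeat = stats::median(g0)),
       direction = sign(mean(g1) - mean(g0)),
       p = p, test = test, degenerate = degenerate)
}
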