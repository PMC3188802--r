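# DUSE-anchored ncRNA screen: IUPAC motif scan, k-mer/DUSE enrichment,
# 5 bp stem + NSBR bulge structural filter, class assignment.

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a genome for an IUPAC-degenerate motif
#'
#' Forward-strand match start positions of a degenerate DNA pattern (e.g.
#' the DUSE, \code{WCCCAWAA} = [AT]CCCA[AT]AA). Subject bases are taken
#' literally (an assembly \code{N} never matches). With
#' \code{respect_mask}, matches overlapping masked positions are dropped.
#'
#' @param genome \code{DNAStringSet} (or single DNA character scalar).
#' @param pattern IUPAC pattern, length <= 50.
#' @param respect_mask Exclude matches overlapping masked bp.
#' @return data.frame: \code{scaffold_id}, \code{start}, \code{end}
#'   (1-based, closed).
#' @export
scan_motif <- function(genome, pattern, respect_mask = FALSE) {
  if (nchar(pattern) > 50L) stop("pattern longer than 50 bp")
  pat_chars <- strsplit(toupper(pattern), "")[[1L]]
  if (!all(pat_chars %in% .IUPAC))
    stop("invalid IUPAC code(s) in pattern: ",
         paste(unique(setdiff(pat_chars, .IUPAC)), collapse = ", "))
  if (is.character(genome)) {
    nm <- names(genome)
    if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- nm
  }
  out <- list()
  for (id in names(genome)) {
    m <- Biostrings::matchPattern(toupper(pattern), genome[[id]],
                                  fixed = c(pattern = FALSE,
                                            subject = TRUE))
    if (length(m) == 0L) next
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    if (respect_mask) {
      flags <- tryCatch(mask_flags(genome, id), error = function(e) NULL)
      if (!is.null(flags) && any(flags)) {
        keep <- vapply(seq_along(st), function(i)
          !any(flags[seq.int(st[i], en[i])]), logical(1))
        st <- st[keep]; en <- en[keep]
      }
    }
    if (length(st))
      out[[id]] <- data.frame(scaffold_id = id, start = st, end = en,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Rank k-mers by upstream-DUSE enrichment
#'
#' Every k-mer occurrence is tested for a DUSE match starting
#' \code{duse_window[1]}..\code{duse_window[2]} bp upstream. The null is
#' positional: the genome-wide probability that a uniformly placed
#' position has a DUSE in its upstream window. Each k-mer's with-DUSE
#' count is scored by an upper-tail binomial test against that
#' probability; k-mers are ranked by score (\eqn{-\log_{10} p}), ties
#' broken lexicographically.
#'
#' @param genome \code{DNAStringSet} or DNA character scalar (>= 10 kb
#'   recommended for a meaningful ranking).
#' @param k k-mer length (default 8).
#' @param duse_window Upstream window, bp before the k-mer start
#'   (default \code{c(40, 90)}).
#' @param duse_pattern IUPAC DUSE motif (default \code{WCCCAWAA}).
#' @param respect_mask Exclude k-mer occurrences overlapping masked bp.
#' @param min_count Only rank k-mers with at least this many occurrences.
#' @return data.frame sorted by rank: \code{kmer}, \code{n_occ},
#'   \code{n_with_duse}, \code{expected}, \code{score}, \code{p_value};
#'   attribute \code{p0} is the positional null probability.
#' @export
kmer_duse_enrichment <- function(genome, k = 8L,
                                 duse_window = c(40L, 90L),
                                 duse_pattern = "WCCCAWAA",
                                 respect_mask = TRUE, min_count = 1L) {
  if (length(duse_window) != 2L || duse_window[1L] > duse_window[2L] ||
      duse_window[1L] < 1L)
    stop("malformed duse_window")
  if (is.character(genome)) {
    nm <- names(genome)
    if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- nm
  }
  duse <- scan_motif(genome, duse_pattern, respect_mask = respect_mask)
  tot <- numeric(4^k)
  with_d <- numeric(4^k)
  n_valid_pos <- 0
  n_pos_with_duse <- 0
  code <- c(A = 0, C = 1, G = 2, T = 3)
  for (id in names(genome)) {
    v <- strsplit(as.character(genome[[id]]), "")[[1L]]
    n <- length(v)
    if (n < k) next
    valid <- v %in% names(code)
    if (respect_mask) {
      flags <- tryCatch(mask_flags(genome, id), error = function(e) NULL)
      if (!is.null(flags)) valid <- valid & !flags
    }
    codes <- unname(code[v]); codes[is.na(codes)] <- 0
    np <- n - k + 1L
    ids <- numeric(np)
    okk <- rep(TRUE, np)
    for (j in 0:(k - 1L)) {
      ids <- ids * 4 + codes[seq.int(1L + j, np + j)]
      okk <- okk & valid[seq.int(1L + j, np + j)]
    }
    # upstream-DUSE indicator per position
    d_ind <- numeric(n)
    ds <- duse$start[duse$scaffold_id == id]
    d_ind[ds] <- 1
    cs <- c(0, cumsum(d_ind))
    lo <- pmax(seq_len(np) - duse_window[2L], 1L)
    hi <- pmax(pmin(seq_len(np) - duse_window[1L], n), 0L)
    has_d <- hi >= 1L & (cs[hi + 1L] - cs[lo]) > 0
    use <- which(okk)
    n_valid_pos <- n_valid_pos + length(use)
    n_pos_with_duse <- n_pos_with_duse + sum(has_d[use])
    tot <- tot + tabulate(ids[use] + 1L, nbins = 4^k)
    wu <- use[has_d[use]]
    if (length(wu))
      with_d <- with_d + tabulate(ids[wu] + 1L, nbins = 4^k)
  }
  p0 <- if (n_valid_pos > 0) n_pos_with_duse / n_valid_pos else 0
  keep <- which(tot >= min_count)
  if (length(keep) == 0L)
    return(structure(data.frame(kmer = character(), n_occ = integer(),
                                n_with_duse = integer(),
                                expected = numeric(), score = numeric(),
                                p_value = numeric()), p0 = p0))
  nt <- c("A", "C", "G", "T")
  decode <- function(idx) {
    idx <- idx - 1L
    vapply(idx, function(x) {
      s <- character(k)
      for (j in k:1) { s[j] <- nt[x %% 4 + 1L]; x <- x %/% 4 }
      paste(s, collapse = "")
    }, character(1))
  }
  pv <- stats::pbinom(with_d[keep] - 1, tot[keep], p0,
                      lower.tail = FALSE)
  res <- data.frame(kmer = decode(keep),
                    n_occ = as.integer(tot[keep]),
                    n_with_duse = as.integer(with_d[keep]),
                    expected = tot[keep] * p0,
                    score = -log10(pmax(pv, .Machine$double.xmin)),
                    p_value = pv,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$score, res$kmer), ]
  rownames(res) <- NULL
  structure(res, p0 = p0)
}

#' Structural filter for DUSE-anchored ncRNA candidates
#'
#' A candidate is emitted at an anchor (a k-mer occurrence, typically of
#' one of the enriched NSBR 8-mers) when (i) a DUSE match starts within
#' the upstream window, and (ii) a 5 bp 5' stem beginning within
#' \code{stem5_offset} bp upstream of (or at) the anchor has its exact
#' reverse complement 40-70 bp downstream of the stem's end. All
#' qualifying stem placements are emitted. The NSBR bulge
#' (\code{CCTTACAGCCAA}) immediately 3' of the 5' stem is recorded.
#'
#' @param genome \code{DNAStringSet} or DNA character scalar.
#' @param anchors data.frame with \code{scaffold_id}, \code{start} (e.g.
#'   from \code{\link{scan_motif}} of an 8-mer), or an integer vector of
#'   positions for a single-scaffold genome.
#' @param duse_window DUSE start offset bounds upstream of the anchor.
#' @param duse_pattern IUPAC DUSE motif.
#' @param stem_len Stem length, bp (default 5).
#' @param stem_sep Allowed separation between 5' stem end and 3' stem
#'   start, bp (default \code{c(40, 70)}).
#' @param stem5_offset How far upstream of the anchor the 5' stem may
#'   begin (default 15).
#' @param bulge_pattern The NSBR bulge sequence.
#' @return data.frame of candidates: \code{scaffold_id},
#'   \code{anchor_start}, \code{duse_start}, \code{duse_gap} (bp between
#'   DUSE end and stem start), \code{stem5_start}, \code{stem5},
#'   \code{stem3_start}, \code{stem3}, \code{stem_separation},
#'   \code{bulge_present}, \code{assigned_class} (\code{"putative"}).
#' @export
stem_filter <- function(genome, anchors, duse_window = c(40L, 90L),
                        duse_pattern = "WCCCAWAA", stem_len = 5L,
                        stem_sep = c(40L, 70L), stem5_offset = 15L,
                        bulge_pattern = "CCTTACAGCCAA") {
  if (is.character(genome)) {
    nm <- names(genome)
    if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- nm
  }
  if (!is.data.frame(anchors)) {
    if (length(genome) != 1L)
      stop("positional anchors need a single-scaffold genome")
    anchors <- data.frame(scaffold_id = names(genome)[1L],
                          start = as.integer(anchors))
  }
  duse <- scan_motif(genome, duse_pattern)
  out <- list()
  for (r in seq_len(nrow(anchors))) {
    id <- anchors$scaffold_id[r]
    a <- anchors$start[r]
    s <- as.character(genome[[id]])
    n <- nchar(s)
    if (a < 1L || a > n) {
      warning("anchor at ", a, " out of bounds on ", id, "; skipped")
      next
    }
    ds <- duse$start[duse$scaffold_id == id]
    ds_in <- ds[a - ds >= duse_window[1L] & a - ds <= duse_window[2L]]
    if (!length(ds_in)) next
    duse_start <- max(ds_in)   # the DUSE closest to the anchor
    for (q in seq.int(max(1L, a - stem5_offset), a)) {
      if (q + stem_len - 1L > n) next
      stem5 <- substr(s, q, q + stem_len - 1L)
      if (grepl("[^ACGT]", stem5)) next
      rc <- .revcomp(stem5)
      for (sep in seq.int(stem_sep[1L], stem_sep[2L])) {
        p3 <- q + stem_len + sep
        if (p3 + stem_len - 1L > n) break
        if (substr(s, p3, p3 + stem_len - 1L) == rc) {
          bulge <- substr(s, q + stem_len,
                          q + stem_len + nchar(bulge_pattern) - 1L)
          out[[length(out) + 1L]] <- data.frame(
            scaffold_id = id, anchor_start = a,
            duse_start = duse_start,
            duse_gap = q - (duse_start + nchar(duse_pattern)),
            stem5_start = q, stem5 = stem5,
            stem3_start = p3, stem3 = rc,
            stem_separation = sep,
            bulge_present = identical(bulge, bulge_pattern),
            assigned_class = "putative",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(scaffold_id = character(), anchor_start = integer(),
                      duse_start = integer(), duse_gap = integer(),
                      stem5_start = integer(), stem5 = character(),
                      stem3_start = integer(), stem3 = character(),
                      stem_separation = integer(),
                      bulge_present = logical(),
                      assigned_class = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Assign ncRNA classes from 5' stem sequences
#'
#' Known stem-to-class assignments (e.g. \code{GTTGA} = class I,
#' \code{GCTCG} = class II in one species); anything else stays putative.
#'
#' @param candidates data.frame from \code{\link{stem_filter}}.
#' @param class_stems Named character vector, stem5 -> class label.
#' @return \code{candidates} with \code{assigned_class} filled.
#' @export
assign_class <- function(candidates,
                         class_stems = c(GTTGA = "classI",
                                         GCTCG = "classII")) {
  cls <- class_stems[candidates$stem5]
  candidates$assigned_class <- ifelse(is.na(cls), "putative",
                                      unname(cls))
  candidates
}

#' Export ncRNA candidates as GFF3
#'
#' One \code{ncRNA} feature per candidate, spanning 5' stem through 3'
#' stem, with stems, bulge and class as attributes.
#'
#' @param candidates data.frame from \code{\link{stem_filter}}.
#' @param path Output path.
#' @param stem_len Stem length used in the screen.
#' @return \code{path}, invisibly.
#' @export
export_ncrna_gff3 <- function(candidates, path, stem_len = 5L) {
  rows <- sprintf(paste0(
    "%s\tdictycomp\tncRNA\t%d\t%d\t.\t+\t.\t",
    "ID=ncrna%d;stem5=%s;stem3=%s;separation=%d;bulge=%s;class=%s;",
    "duse_start=%d"),
    candidates$scaffold_id, candidates$stem5_start,
    candidates$stem3_start + stem_len - 1L,
    seq_len(nrow(candidates)), candidates$stem5, candidates$stem3,
    candidates$stem_separation,
    ifelse(candidates$bulge_present, "present", "absent"),
    candidates$assigned_class, candidates$duse_start)
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
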