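# Simple-sequence-repeat detection with unit-length-specific minimum copy
# numbers (mono >= 10, di >= 7, tri >= 5, tetra >= 4, penta and longer
# >= 3 copies).

.canonical_rotation <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(unit)
  rots <- vapply(seq_len(k), function(i)
    paste0(substr(unit, i, k), substr(unit, 1L, i - 1L)), character(1))
  min(rots)
}

.is_primitive <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  divs <- which(k %% seq_len(k - 1L) == 0L)
  for (d in divs) {
    if (strrep(substr(unit, 1L, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeat tracts
#'
#' Scans the forward strand of each scaffold for maximal tandem repeats of
#' unit length 1-20 bp. A tract qualifies when its whole-copy count meets
#' the unit-length-specific minimum (defaults: 10 for mononucleotides, 7
#' for dinucleotides, 5 for trinucleotides, 4 for tetranucleotides, 3 for
#' pentanucleotide and longer motifs); a fractional trailing unit counts
#' toward tract length but not toward qualification. Tracts whose unit is
#' itself a repetition of a shorter unit are reported only at the shortest
#' unit length; the reported unit is the lexicographically least rotation.
#' Masked (soft-masked or \code{N}) positions terminate tracts so repeats
#' never cross assembly gaps. A motif and its reverse complement are
#' distinct units.
#'
#' @param genome A \code{DNAStringSet} (e.g. from
#'   \code{\link{read_genome_fasta}}) or a single DNA character scalar.
#' @param min_copies Numeric vector of length 20: minimum whole copies per
#'   unit length.
#' @return data.frame: \code{scaffold_id}, \code{start}, \code{end}
#'   (1-based, closed), \code{unit_length}, \code{unit}, \code{copies}
#'   (possibly fractional), \code{coding} (NA until
#'   \code{\link{classify_coding}}), sorted by scaffold then position.
#' @export
find_ssr_tracts <- function(genome, min_copies = c(10, 7, 5, 4, rep(3, 16))) {
  stopifnot(length(min_copies) == 20L, all(min_copies >= 1))
  if (is.character(genome)) {
    nm <- names(genome)
    if (is.null(nm)) nm <- paste0("seq", seq_along(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- nm
  }
  out <- vector("list", length(genome))
  for (s in seq_along(genome)) {
    id <- names(genome)[s]
    chars <- as.character(genome[[s]])
    if (grepl("[^ACGTN]", toupper(chars)))
      stop("non-DNA alphabet in scaffold '", id, "'")
    v <- strsplit(toupper(chars), "")[[1L]]
    n <- length(v)
    ok <- v != "N"
    mask <- tryCatch(mask_flags(genome, id), error = function(e) NULL)
    if (!is.null(mask)) ok <- ok & !mask
    res <- list()
    for (k in 1:20) {
      min_len <- (min_copies[k] - 1) * k   # required eq-run length
      if (n < min_copies[k] * k) next
      eq <- v[seq_len(n - k)] == v[seq.int(k + 1L, n)] &
        ok[seq_len(n - k)] & ok[seq.int(k + 1L, n)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= min_len)
      for (h in hit) {
        i <- starts[h]
        L <- r$lengths[h]
        total <- L + k
        if (total %/% k < min_copies[k]) next
        unit <- paste(v[seq.int(i, i + k - 1L)], collapse = "")
        if (!.is_primitive(unit)) next
        res[[length(res) + 1L]] <- data.frame(
          scaffold_id = id, start = i, end = i + total - 1L,
          unit_length = k, unit = .canonical_rotation(unit),
          copies = total / k, stringsAsFactors = FALSE)
      }
    }
    if (length(res)) {
      df <- do.call(rbind, res)
      df <- df[order(df$start, df$unit_length), ]
      out[[s]] <- df
    }
  }
  tracts <- do.call(rbind, out)
  if (is.null(tracts))
    tracts <- data.frame(scaffold_id = character(), start = integer(),
                         end = integer(), unit_length = integer(),
                         unit = character(), copies = numeric(),
                         stringsAsFactors = FALSE)
  tracts$coding <- rep(NA, nrow(tracts))
  rownames(tracts) <- NULL
  tracts
}

#' Classify repeat tracts as coding or non-coding
#'
#' A tract is coding when its span intersects any CDS interval by at least
#' one bp (half-open touching does not count: a tract ending where a CDS
#' begins is non-coding).
#'
#' @param tracts data.frame from \code{\link{find_ssr_tracts}}.
#' @param models \code{\link{gene_models}} on the same assembly, or
#'   \code{NULL} (all tracts non-coding, with a warning).
#' @return \code{tracts} with the \code{coding} column filled.
#' @export
classify_coding <- function(tracts, models = NULL) {
  if (is.null(models)) {
    warning("no gene models supplied; all tracts classified non-coding")
    tracts$coding <- FALSE
    return(tracts)
  }
  if (nrow(tracts) == 0L) {
    tracts$coding <- logical(0)
    return(tracts)
  }
  cds <- models$cds
  cds$scaffold_id <- models$genes$scaffold_id[
    match(cds$gene_id, models$genes$gene_id)]
  # a scaffold without genes is fine, but zero overlap between the two
  # scaffold universes means the tracts and models are from different
  # assemblies
  if (!any(tracts$scaffold_id %in% models$genes$scaffold_id))
    stop("tract scaffold ids do not match the gene models")
  coding <- logical(nrow(tracts))
  for (id in unique(tracts$scaffold_id)) {
    ti <- which(tracts$scaffold_id == id)
    ci <- which(cds$scaffold_id == id)
    if (!length(ci)) next
    tr <- IRanges::IRanges(tracts$start[ti], tracts$end[ti])
    cr <- IRanges::IRanges(cds$start[ci], cds$end[ci])
    coding[ti] <- IRanges::overlapsAny(tr, cr, minoverlap = 1L)
  }
  tracts$coding <- coding
  tracts
}

#' Summarize repeat tracts for one genome
#'
#' @param tracts data.frame from \code{\link{find_ssr_tracts}} (one
#'   genome).
#' @param genome_bp Total genome length in bp (> 0).
#' @param summed_bp Count overlapping tract bp once (union, default) or
#'   sum tract lengths.
#' @param hist_binwidth Tract-length histogram bin width in bp.
#' @return list: \code{per_unit} (counts by unit length, coding and
#'   non-coding, with an is-multiple-of-3 flag), \code{genome_fraction},
#'   \code{n_long} (tracts strictly longer than 100 bp),
#'   \code{tract_lengths}, \code{hist} (binned tract-length counts),
#'   \code{n_tracts}.
#' @export
ssr_summary <- function(tracts, genome_bp, summed_bp = FALSE,
                        hist_binwidth = 10L) {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  lens <- tracts$end - tracts$start + 1L
  if (summed_bp) {
    in_tract <- sum(lens)
  } else {
    in_tract <- 0L
    for (id in unique(tracts$scaffold_id)) {
      ti <- tracts$scaffold_id == id
      in_tract <- in_tract + sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(tracts$start[ti], tracts$end[ti]))))
    }
  }
  coding <- tracts$coding
  if (all(is.na(coding))) coding <- rep(FALSE, nrow(tracts))
  per_unit <- data.frame(unit_length = 1:20)
  per_unit$n_coding <- vapply(1:20, function(k)
    sum(tracts$unit_length == k & coding, na.rm = TRUE), integer(1))
  per_unit$n_noncoding <- vapply(1:20, function(k)
    sum(tracts$unit_length == k & !coding, na.rm = TRUE), integer(1))
  per_unit$multiple_of_3 <- per_unit$unit_length %% 3L == 0L
  breaks <- seq(0L, max(c(lens, 0L)) + hist_binwidth, by = hist_binwidth)
  h <- if (length(lens)) table(cut(lens, breaks)) else table(factor())
  list(per_unit = per_unit,
       genome_fraction = in_tract / genome_bp,
       n_long = sum(lens > 100L),
       tract_lengths = lens,
       hist = h,
       n_tracts = nrow(tracts))
}

#' Write repeat tracts as TSV (and optionally BED)
#' @param tracts data.frame from \code{\link{find_ssr_tracts}}.
#' @param path Output TSV path.
#' @param bed_path Optional BED path (0-based half-open, per BED).
#' @return \code{path}, invisibly.
#' @export
write_ssr_tsv <- function(tracts, path, bed_path = NULL) {
  utils::write.table(tracts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(tracts$scaffold_id,
                                 IRanges::IRanges(tracts$start, tracts$end),
                                 name = tracts$unit)
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(path)
}
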