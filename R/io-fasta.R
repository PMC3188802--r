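#' Read a (possibly soft-masked) genome FASTA
#'
#' Residues are uppercased on input; lowercase letters are taken to mark
#' soft-masked positions and are recorded as masked ranges. With
#' \code{hard_mask = TRUE}, runs of \code{N} are additionally treated as
#' masked (the hard-mask convention for assemblies whose repeats were
#' replaced rather than lowercased).
#'
#' @param path Path to a FASTA file of DNA sequences.
#' @param hard_mask Also mask \code{N} runs? Default \code{FALSE}.
#' @return A \code{DNAStringSet}, uppercased, with
#'   \code{metadata(x)$mask}: a named list of \code{IRanges} of masked
#'   positions per scaffold.
#' @export
read_genome_fasta <- function(path, hard_mask = FALSE) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L)
    stop("FASTA file '", path, "' contains no records")
  ids <- names(raw)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("FASTA record with empty header in '", path, "'")
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate scaffold id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(raw) == 0L))
    stop("empty FASTA record(s) in '", path, "': ",
         paste(ids[Biostrings::width(raw) == 0L], collapse = ", "))
  chars <- as.character(raw)
  mask <- lapply(chars, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    lower <- v %in% c("a", "c", "g", "t", "n")
    if (hard_mask) lower <- lower | v %in% c("N", "n")
    as(lower, "IRanges")
  })
  names(mask) <- ids
  up <- toupper(chars)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad))
    stop("non-DNA characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  genome <- Biostrings::DNAStringSet(up)
  names(genome) <- ids
  S4Vectors::metadata(genome)$mask <- mask
  genome
}

#' Write a genome FASTA with soft-masked (lowercase) regions
#'
#' Inverse of \code{\link{read_genome_fasta}}: masked ranges recorded in
#' \code{metadata(x)$mask} are written in lowercase.
#'
#' @param genome A \code{DNAStringSet} as returned by
#'   \code{\link{read_genome_fasta}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  mask <- S4Vectors::metadata(genome)$mask
  chars <- as.character(genome)
  if (!is.null(mask)) {
    for (id in names(chars)) {
      mr <- mask[[id]]
      if (!is.null(mr) && length(mr) > 0L) {
        v <- strsplit(chars[[id]], "", fixed = TRUE)[[1L]]
        idx <- unlist(mapply(seq.int, IRanges::start(mr), IRanges::end(mr),
                             SIMPLIFY = FALSE))
        v[idx] <- tolower(v[idx])
        chars[[id]] <- paste(v, collapse = "")
      }
    }
  }
  out <- Biostrings::BStringSet(chars)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Per-position mask flags for one scaffold
#'
#' @param genome A genome from \code{\link{read_genome_fasta}}.
#' @param scaffold_id Scaffold name.
#' @return Logical vector, \code{TRUE} at masked positions.
#' @export
mask_flags <- function(genome, scaffold_id) {
  if (!scaffold_id %in% names(genome))
    stop("unknown scaffold '", scaffold_id, "'")
  n <- Biostrings::width(genome)[match(scaffold_id, names(genome))]
  flags <- logical(n)
  mr <- S4Vectors::metadata(genome)$mask[[scaffold_id]]
  if (!is.null(mr) && length(mr) > 0L)
    flags[unlist(mapply(seq.int, IRanges::start(mr), IRanges::end(mr),
                        SIMPLIFY = FALSE))] <- TRUE
  flags
}

#' Read a protein or CDS FASTA
#'
#' @param path FASTA path.
#' @param type \code{"AA"} (default) or \code{"DNA"}.
#' @return An \code{AAStringSet} or \code{DNAStringSet}, names truncated at
#'   the first whitespace; duplicate ids are an error.
#' @export
read_seq_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  stopifnot(file.exists(path))
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id(s) in '", path, "'")
  x
}
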