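#' Construct a set of gene models
#'
#' Internal container for gene coordinates: a \code{genes} table and a
#' \code{cds} table whose parts are ranked 5' to 3' on the coding strand.
#' All coordinates are 1-based, closed (GFF3 convention, kept internally).
#'
#' @param genes data.frame with columns \code{gene_id}, \code{scaffold_id},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"} or \code{"-"}).
#' @param cds data.frame with columns \code{gene_id}, \code{start},
#'   \code{end}; parts are sorted and ranked internally.
#' @return An object of class \code{gene_models}.
#' @export
gene_models <- function(genes, cds) {
  stopifnot(is.data.frame(genes), is.data.frame(cds),
            all(c("gene_id", "scaffold_id", "start", "end", "strand") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(cds)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
               collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(cds$gene_id %in% genes$gene_id))
    stop("CDS part(s) reference unknown gene id(s)")
  # order parts 5'->3' on the coding strand and assign rank
  strand <- genes$strand[match(cds$gene_id, genes$gene_id)]
  ord <- order(cds$gene_id, ifelse(strand == "+", 1L, -1L) * cds$start)
  cds <- cds[ord, c("gene_id", "start", "end")]
  cds$rank <- stats::ave(seq_len(nrow(cds)), cds$gene_id,
                         FUN = seq_along)
  rownames(genes) <- rownames(cds) <- NULL
  for (g in unique(cds$gene_id)) {
    p <- cds[cds$gene_id == g, ]
    gi <- genes[genes$gene_id == g, ]
    if (any(p$start < gi$start) || any(p$end > gi$end))
      stop("CDS part outside gene span for '", g, "'")
    p <- p[order(p$start), ]
    if (nrow(p) > 1L && any(p$start[-1L] <= p$end[-nrow(p)]))
      stop("overlapping CDS parts for '", g, "'")
  }
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$cds), "CDS parts on",
      length(unique(x$genes$scaffold_id)), "scaffold(s)\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Accepts gene/mRNA/CDS feature hierarchies (CDS parented by an mRNA that
#' is parented by a gene, or CDS directly under a gene). Coordinates are
#' kept 1-based closed. Minus-strand CDS parts are ranked 5' to 3' on the
#' coding strand.
#'
#' @param path GFF3 path.
#' @param genome Optional genome (\code{DNAStringSet}); when supplied,
#'   scaffold ids are checked and out-of-bounds CDS coordinates are an
#'   error.
#' @return A \code{\link{gene_models}} object.
#' @export
read_gff3 <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(gr$Parent, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, character(1))
  is_gene <- type == "gene"
  is_mrna <- type == "mRNA"
  is_cds <- type == "CDS"
  if (!any(is_gene)) stop("no gene features in '", path, "'")
  genes <- data.frame(
    gene_id = id[is_gene],
    scaffold_id = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = IRanges::start(gr)[is_gene],
    end = IRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    stringsAsFactors = FALSE)
  # map CDS -> gene through mRNA where needed
  mrna2gene <- setNames(parent[is_mrna], id[is_mrna])
  cds_parent <- parent[is_cds]
  cds_gene <- ifelse(cds_parent %in% names(mrna2gene),
                     mrna2gene[cds_parent], cds_parent)
  cds <- data.frame(gene_id = unname(cds_gene),
                    start = IRanges::start(gr)[is_cds],
                    end = IRanges::end(gr)[is_cds],
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    unknown <- setdiff(genes$scaffold_id, names(genome))
    if (length(unknown))
      stop("GFF3 references unknown scaffold(s): ",
           paste(unknown, collapse = ", "))
    len <- setNames(Biostrings::width(genome), names(genome))
    glen <- len[genes$scaffold_id[match(cds$gene_id, genes$gene_id)]]
    if (any(cds$end > glen) || any(cds$start < 1L))
      stop("CDS coordinates outside scaffold bounds in '", path, "'")
  }
  gene_models(genes, cds)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (one mRNA per gene).
#'
#' @param models A \code{\link{gene_models}} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  cds <- models$cds
  strand_of <- setNames(g$strand, g$gene_id)
  scaf_of <- setNames(g$scaffold_id, g$gene_id)
  rows <- c(
    sprintf("%s\tdictycomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$scaffold_id, g$start, g$end, g$strand, g$gene_id),
    sprintf("%s\tdictycomp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
            g$scaffold_id, g$start, g$end, g$strand, g$gene_id, g$gene_id),
    sprintf("%s\tdictycomp\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
            scaf_of[cds$gene_id], cds$start, cds$end,
            strand_of[cds$gene_id], cds$gene_id, cds$gene_id))
  # keep features grouped and sorted for readability
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Extract the spliced CDS sequence of one gene
#'
#' Parts are concatenated in 5'-to-3' coding order; minus-strand genes are
#' reverse-complemented.
#'
#' @param genome Genome \code{DNAStringSet}.
#' @param models \code{\link{gene_models}}.
#' @param gene_id Gene id.
#' @return A character scalar (DNA).
#' @export
extract_cds <- function(genome, models, gene_id) {
  gi <- models$genes[models$genes$gene_id == gene_id, ]
  if (nrow(gi) != 1L) stop("unknown gene '", gene_id, "'")
  p <- models$cds[models$cds$gene_id == gene_id, ]
  p <- p[order(p$start), ]
  seqs <- vapply(seq_len(nrow(p)), function(i)
    as.character(Biostrings::subseq(genome[[gi$scaffold_id]],
                                    p$start[i], p$end[i])),
    character(1))
  s <- paste(seqs, collapse = "")
  if (gi$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}
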