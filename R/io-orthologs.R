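#' Read an ortholog-pair table
#'
#' A TSV with columns \code{gene_a}, \code{gene_b}, \code{relation}
#' (\code{one_to_one} or \code{inparalog_group_member}). One-to-one rows
#' must use each gene at most once in each genome; violations are an error
#' listing the offending ids. Ortholog inference itself is upstream of this
#' package: tables are consumed, never computed.
#'
#' @param path TSV path.
#' @param models_a,models_b Optional \code{\link{gene_models}} for the two
#'   genomes; when given, every gene id must resolve.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{relation}.
#' @export
read_ortholog_table <- function(path, models_a = NULL, models_b = NULL) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    warning("ortholog table '", path, "' is empty")
    return(data.frame(gene_a = character(), gene_b = character(),
                      relation = character(), stringsAsFactors = FALSE))
  }
  need <- c("gene_a", "gene_b", "relation")
  if (!all(need %in% names(tab)))
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  bad_rel <- setdiff(unique(tab$relation),
                     c("one_to_one", "inparalog_group_member"))
  if (length(bad_rel))
    stop("unknown relation value(s): ", paste(bad_rel, collapse = ", "))
  oo <- tab[tab$relation == "one_to_one", ]
  dup_a <- unique(oo$gene_a[duplicated(oo$gene_a)])
  dup_b <- unique(oo$gene_b[duplicated(oo$gene_b)])
  if (length(dup_a) || length(dup_b))
    stop("one_to_one rows reuse gene id(s): ",
         paste(c(dup_a, dup_b), collapse = ", "))
  if (!is.null(models_a)) {
    missing_a <- setdiff(tab$gene_a, models_a$genes$gene_id)
    if (length(missing_a))
      stop("gene_a id(s) absent from genome A models: ",
           paste(utils::head(missing_a, 5L), collapse = ", "))
  }
  if (!is.null(models_b)) {
    missing_b <- setdiff(tab$gene_b, models_b$genes$gene_id)
    if (length(missing_b))
      stop("gene_b id(s) absent from genome B models: ",
           paste(utils::head(missing_b, 5L), collapse = ", "))
  }
  tab
}

#' Write an ortholog-pair table
#' @param tab data.frame as from \code{\link{read_ortholog_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_ortholog_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
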