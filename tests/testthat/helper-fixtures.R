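# Small in-code fixtures shared across test files.

write_tmp_fasta <- function(seqs, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}

# a tiny two-gene GFF3 (one plus, one minus strand with two CDS parts)
write_tiny_gff3 <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\ttest\tgene\t1\t9\t.\t+\t.\tID=gplus",
    "s1\ttest\tmRNA\t1\t9\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "s1\ttest\tCDS\t1\t9\t.\t+\t0\tID=gplus.cds;Parent=gplus.t1",
    "s1\ttest\tgene\t20\t40\t.\t-\t.\tID=gminus",
    "s1\ttest\tmRNA\t20\t40\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "s1\ttest\tCDS\t20\t25\t.\t-\t0\tID=gminus.cds1;Parent=gminus.t1",
    "s1\ttest\tCDS\t30\t40\t.\t-\t0\tID=gminus.cds2;Parent=gminus.t1"),
    path)
  path
}

write_tmp_orthologs <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# an ortholog map from two order vectors (pair index -> position), one
# scaffold per genome
make_map <- function(order_a, order_b,
                     scaffold_a = "sA", chrom_b = "cB") {
  n <- length(order_a)
  stopifnot(length(order_b) == n)
  ids <- sprintf("p%02d", seq_len(n))
  ortholog_map(data.frame(
    gene_a = ids, gene_b = sub("p", "q", ids),
    scaffold_a = scaffold_a, pos_a = match(seq_len(n), order_a),
    chrom_b = chrom_b, pos_b = match(seq_len(n), order_b),
    stringsAsFactors = FALSE))
}

# random multi-scaffold map for property tests
random_map <- function(n, n_scaf_a = 1L, n_scaf_b = 1L) {
  ids <- sprintf("p%02d", seq_len(n))
  scaf_a <- sort(sample(paste0("sA", seq_len(n_scaf_a)), n, TRUE))
  scaf_b_assign <- sample(paste0("cB", seq_len(n_scaf_b)), n, TRUE)
  pos_a <- stats::ave(seq_len(n), scaf_a, FUN = function(x)
    sample(seq_along(x)))
  ord_b <- order(scaf_b_assign, sample(n))
  pos_b <- stats::ave(seq_len(n), scaf_b_assign, FUN = function(x)
    sample(seq_along(x)))
  ortholog_map(data.frame(
    gene_a = ids, gene_b = sub("p", "q", ids),
    scaffold_a = scaf_a, pos_a = pos_a,
    chrom_b = scaf_b_assign, pos_b = pos_b,
    stringsAsFactors = FALSE))
}

codon_vec <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

ungapped_codon_alignment <- function(cds_a, cds_b) {
  list(codons_a = codon_vec(cds_a), codons_b = codon_vec(cds_b))
}

# small, fast simulation settings reused across tests
tiny_sim <- function(...) {
  sim_config(n_genes = 40L, n_scaffolds_a = 2L, n_scaffolds_b = 2L,
             rearrangement_ops = 3L, n_ncrna_loci = 3L,
             gene_len_codons = c(80L, 150L),
             intergenic_len = c(200L, 400L), ...)
}
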