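# Synteny blocks: single-linkage clustering of 1:1 ortholog pairs under a
# window parameter w, counted in the ortholog-restricted gene order of
# both genomes, with permutation nulls.

#' Build the ordered ortholog map
#'
#' Restricts each genome to genes with a one-to-one ortholog and indexes
#' them in genomic order per scaffold (genome A) / chromosome (genome B).
#' Genes without a 1:1 partner are invisible to the synteny analysis:
#' "intervening genes" are counted in this restricted order.
#'
#' @param models_a,models_b \code{\link{gene_models}} of the two genomes.
#' @param orthologs Ortholog table (see
#'   \code{\link{read_ortholog_table}}); only \code{one_to_one} rows are
#'   used.
#' @return data.frame of class \code{ortholog_map}: \code{gene_a},
#'   \code{gene_b}, \code{scaffold_a}, \code{pos_a}, \code{chrom_b},
#'   \code{pos_b} (positions 1-based, contiguous per scaffold).
#' @export
ordered_ortholog_map <- function(models_a, models_b, orthologs) {
  oo <- orthologs[orthologs$relation == "one_to_one", , drop = FALSE]
  ga <- models_a$genes
  gb <- models_b$genes
  missing_a <- setdiff(oo$gene_a, ga$gene_id)
  missing_b <- setdiff(oo$gene_b, gb$gene_id)
  if (length(missing_a) || length(missing_b))
    stop("ortholog pair gene(s) missing from gene models: ",
         paste(utils::head(c(missing_a, missing_b), 5L), collapse = ", "))
  index_genome <- function(g, keep) {
    g <- g[g$gene_id %in% keep, , drop = FALSE]
    g <- g[order(g$scaffold_id, g$start), , drop = FALSE]
    g$pos <- stats::ave(seq_len(nrow(g)), g$scaffold_id, FUN = seq_along)
    g
  }
  ia <- index_genome(ga, oo$gene_a)
  ib <- index_genome(gb, oo$gene_b)
  map <- data.frame(
    gene_a = oo$gene_a, gene_b = oo$gene_b,
    scaffold_a = ia$scaffold_id[match(oo$gene_a, ia$gene_id)],
    pos_a = ia$pos[match(oo$gene_a, ia$gene_id)],
    chrom_b = ib$scaffold_id[match(oo$gene_b, ib$gene_id)],
    pos_b = ib$pos[match(oo$gene_b, ib$gene_id)],
    stringsAsFactors = FALSE)
  class(map) <- c("ortholog_map", "data.frame")
  map
}

#' Construct an ortholog map directly from positions
#'
#' Convenience constructor for analyses and tests that already have the
#' restricted orders.
#'
#' @param df data.frame with \code{gene_a}, \code{gene_b},
#'   \code{scaffold_a}, \code{pos_a}, \code{chrom_b}, \code{pos_b}.
#' @return An \code{ortholog_map}.
#' @export
ortholog_map <- function(df) {
  need <- c("gene_a", "gene_b", "scaffold_a", "pos_a", "chrom_b", "pos_b")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$gene_a) || anyDuplicated(df$gene_b))
    stop("map genes must be uniquely paired (one-to-one)")
  for (s in unique(df$scaffold_a)) {
    p <- sort(df$pos_a[df$scaffold_a == s])
    if (!identical(as.integer(p), seq_along(p)))
      stop("pos_a not contiguous from 1 on scaffold ", s)
  }
  for (s in unique(df$chrom_b)) {
    p <- sort(df$pos_b[df$chrom_b == s])
    if (!identical(as.integer(p), seq_along(p)))
      stop("pos_b not contiguous from 1 on chromosome ", s)
  }
  df <- df[, need]
  class(df) <- c("ortholog_map", "data.frame")
  df
}

#' Build synteny blocks by single-linkage clustering
#'
#' Two ortholog pairs are linked when (i) their genome-A genes fall on the
#' same scaffold with at most \code{w} intervening ortholog-bearing genes,
#' and (ii) their genome-B partners fall on the same chromosome with at
#' most \code{w} intervening ortholog-bearing genes. Blocks are connected
#' components of the link graph with at least two members; linkage is
#' orientation-free, so reversed segments cluster. With
#' \code{strict_order = TRUE} links additionally require the two genomes'
#' orders to run in a consistent direction.
#'
#' @param map An \code{ortholog_map}.
#' @param w Window: maximum intervening ortholog-bearing genes (>= 0).
#' @param strict_order Require direction consistency (default FALSE).
#' @return list of class \code{synteny_blocks}: \code{members} (the map
#'   plus \code{block_id}, NA for unclustered pairs) and \code{blocks}
#'   (per-block size and location summary).
#' @export
build_blocks <- function(map, w, strict_order = FALSE) {
  stopifnot(w >= 0)
  n <- nrow(map)
  edges <- list()
  groups <- split(seq_len(n), paste(map$scaffold_a, map$chrom_b, sep = "\r"))
  for (g in groups) {
    if (length(g) < 2L) next
    g <- g[order(map$pos_a[g])]
    pa <- map$pos_a[g]; pb <- map$pos_b[g]
    for (i in seq_along(g)) {
      j <- i + 1L
      while (j <= length(g) && pa[j] - pa[i] <= w + 1L) {
        linked <- abs(pb[j] - pb[i]) <= w + 1L
        # strict mode: only co-oriented runs (B order increasing with A)
        if (strict_order) linked <- linked && pb[j] > pb[i]
        if (linked)
          edges[[length(edges) + 1L]] <- c(g[i], g[j])
        j <- j + 1L
      }
    }
  }
  if (length(edges)) {
    em <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(em, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership[seq_len(n)]
  } else {
    comp <- seq_len(n)
  }
  sizes <- table(comp)
  keep <- names(sizes)[sizes >= 2L]
  block_id <- match(as.character(comp), keep)
  members <- as.data.frame(map)
  members$block_id <- block_id
  in_blk <- !is.na(block_id)
  blocks <- if (any(in_blk)) {
    agg <- split(which(in_blk), block_id[in_blk])
    data.frame(
      block_id = as.integer(names(agg)),
      scaffold_a = vapply(agg, function(i) map$scaffold_a[i[1L]],
                          character(1)),
      chrom_b = vapply(agg, function(i) map$chrom_b[i[1L]], character(1)),
      n_pairs = lengths(agg),
      start_a = vapply(agg, function(i) min(map$pos_a[i]), numeric(1)),
      end_a = vapply(agg, function(i) max(map$pos_a[i]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(block_id = integer(), scaffold_a = character(),
               chrom_b = character(), n_pairs = integer(),
               start_a = numeric(), end_a = numeric(),
               stringsAsFactors = FALSE)
  }
  structure(list(members = members, blocks = blocks, w = w),
            class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks: w =", x$w, ";", nrow(x$blocks), "blocks covering",
      sum(!is.na(x$members$block_id)), "of", nrow(x$members), "pairs\n")
  invisible(x)
}

#' Participation and size statistics of a block set
#'
#' @param blocks A \code{synteny_blocks} result.
#' @return list: \code{participation} (fraction of ortholog pairs in any
#'   block; pairs and genes coincide for a 1:1 map, both are reported),
#'   \code{mean_size}, \code{max_size} (0 with \code{no_blocks} flag when
#'   there are none), \code{n_blocks}, \code{n_genes_in_blocks}.
#' @export
block_stats <- function(blocks) {
  m <- blocks$members
  n <- nrow(m)
  in_blk <- sum(!is.na(m$block_id))
  nb <- nrow(blocks$blocks)
  list(participation = if (n > 0) in_blk / n else 0,
       participation_genes = if (n > 0) in_blk / n else 0,
       mean_size = if (nb > 0) mean(blocks$blocks$n_pairs) else 0,
       max_size = if (nb > 0) max(blocks$blocks$n_pairs) else 0,
       n_blocks = nb, n_genes_in_blocks = in_blk,
       no_blocks = nb == 0L)
}

.permute_map_once <- function(map, whole_genome = FALSE) {
  out <- map
  if (whole_genome) {
    slots_a <- sample(nrow(map))
    out$scaffold_a <- map$scaffold_a[slots_a]
    out$pos_a <- map$pos_a[slots_a]
    slots_b <- sample(nrow(map))
    out$chrom_b <- map$chrom_b[slots_b]
    out$pos_b <- map$pos_b[slots_b]
  } else {
    for (s in unique(map$scaffold_a)) {
      i <- which(map$scaffold_a == s)
      out$pos_a[i] <- map$pos_a[i][sample(length(i))]
    }
    for (s in unique(map$chrom_b)) {
      i <- which(map$chrom_b == s)
      out$pos_b[i] <- map$pos_b[i][sample(length(i))]
    }
  }
  out
}

#' Scramble gene order for the permutation control
#'
#' Gene order within each scaffold (genome A) and chromosome (genome B)
#' is independently, uniformly permuted; scaffold membership and the
#' pairing itself are unchanged. \code{whole_genome = TRUE} instead
#' shuffles genes across scaffolds, preserving per-scaffold gene counts.
#'
#' @param map An \code{ortholog_map}.
#' @param seed Integer seed.
#' @param whole_genome Shuffle across scaffolds (default FALSE).
#' @return A permuted \code{ortholog_map}.
#' @export
permute_map <- function(map, seed, whole_genome = FALSE) {
  set.seed(seed)
  .permute_map_once(map, whole_genome)
}

#' Null distribution of block participation under scrambled gene order
#'
#' @param map An \code{ortholog_map}.
#' @param w Window parameter.
#' @param n_perm Number of permutations (>= 2).
#' @param seed Integer seed (recorded in the result).
#' @param whole_genome Passed to the scramble.
#' @return list of class \code{null_summary}: \code{participation_mean},
#'   \code{participation_sd}, \code{participation} (per permutation),
#'   \code{n_permutations}, \code{seed}.
#' @export
null_distribution <- function(map, w, n_perm = 100L, seed = 1L,
                              whole_genome = FALSE) {
  if (n_perm < 2L) stop("n_perm must be >= 2")
  set.seed(seed)
  parts <- vapply(seq_len(n_perm), function(i) {
    pm <- .permute_map_once(map, whole_genome)
    block_stats(build_blocks(pm, w))$participation
  }, numeric(1))
  structure(list(participation_mean = mean(parts),
                 participation_sd = stats::sd(parts),
                 participation = parts,
                 n_permutations = n_perm, seed = seed),
            class = c("null_summary", "list"))
}

#' Select the window parameter w
#'
#' Scans w from 0 to \code{w_max}; real participation growth
#' (participation(w) - participation(w-1)) is compared with the growth of
#' permuted controls, and the chosen w is the largest whose growth exceeds
#' the null growth mean by at least \code{k_sd} null SDs (w = 0 is judged
#' on its level rather than growth). When no w qualifies the map is
#' flagged as showing no significant synteny.
#'
#' @param map An \code{ortholog_map}.
#' @param w_max Largest window scanned (>= 1).
#' @param n_perm Permutations per window.
#' @param seed Integer seed.
#' @param k_sd Significance rule in null SDs (default 2).
#' @return list: \code{w} (chosen, NA when nothing qualifies),
#'   \code{no_significant_synteny}, and \code{table} with real and null
#'   participation and growth per w.
#' @export
select_w <- function(map, w_max = 20L, n_perm = 100L, seed = 1L,
                     k_sd = 2) {
  stopifnot(w_max >= 1L)
  ws <- 0:w_max
  real <- vapply(ws, function(w)
    block_stats(build_blocks(map, w))$participation, numeric(1))
  set.seed(seed)
  null_mat <- matrix(NA_real_, n_perm, length(ws))
  for (i in seq_len(n_perm)) {
    pm <- .permute_map_once(map)
    null_mat[i, ] <- vapply(ws, function(w)
      block_stats(build_blocks(pm, w))$participation, numeric(1))
  }
  null_mean <- colMeans(null_mat)
  null_sd <- apply(null_mat, 2L, stats::sd)
  g_real <- c(NA, diff(real))
  g_null <- t(apply(null_mat, 1L, function(x) c(NA, diff(x))))
  g_null_mean <- colMeans(g_null)
  g_null_sd <- apply(g_null, 2L, stats::sd)
  signif <- logical(length(ws))
  signif[1L] <- real[1L] > null_mean[1L] + k_sd * null_sd[1L]
  for (i in seq_along(ws)[-1L])
    signif[i] <- !is.na(g_real[i]) &&
      g_real[i] > g_null_mean[i] + k_sd * g_null_sd[i]
  chosen <- if (any(signif)) ws[max(which(signif))] else NA_integer_
  list(w = chosen,
       no_significant_synteny = !any(signif),
       table = data.frame(w = ws, participation = real,
                          null_mean = null_mean, null_sd = null_sd,
                          growth = g_real, null_growth_mean = g_null_mean,
                          null_growth_sd = g_null_sd,
                          significant = signif))
}

#' Gene-wise false positive rate of the block analysis
#'
#' The fraction of real block participation expected by chance: null mean
#' participation over real participation.
#'
#' @param real_participation Real participation (> 0).
#' @param null A \code{null_summary} from \code{\link{null_distribution}}.
#' @return FPR as a proportion.
#' @export
fpr_estimate <- function(real_participation, null) {
  if (real_participation <= 0)
    stop("false positive rate undefined at zero real participation")
  null$participation_mean / real_participation
}

#' Write synteny blocks as TSV (and optionally BED)
#'
#' The TSV mirrors a block list: one member pair per row with its block,
#' gene ids and restricted-order positions.
#'
#' @param blocks A \code{synteny_blocks} result.
#' @param path TSV output path.
#' @param models_a Optional genome-A \code{\link{gene_models}} for BED
#'   coordinates.
#' @param bed_path Optional BED path.
#' @return \code{path}, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path, models_a = NULL,
                             bed_path = NULL) {
  m <- blocks$members[!is.na(blocks$members$block_id), , drop = FALSE]
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path) && !is.null(models_a) && nrow(m) > 0L) {
    g <- models_a$genes
    st <- g$start[match(m$gene_a, g$gene_id)]
    en <- g$end[match(m$gene_a, g$gene_id)]
    agg_start <- tapply(st, m$block_id, min)
    agg_end <- tapply(en, m$block_id, max)
    scaf <- tapply(m$scaffold_a, m$block_id, function(x) x[1L])
    gr <- GenomicRanges::GRanges(as.character(scaf),
      IRanges::IRanges(as.integer(agg_start), as.integer(agg_end)),
      name = paste0("block", names(agg_start)))
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(path)
}
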