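test_that("perfectly conserved, reversed and swapped orders cluster as
           expected at w = 0", {
  # identical orders: one block of 10
  m <- make_map(1:10, 1:10)
  st <- block_stats(build_blocks(m, 0L))
  expect_equal(st$n_blocks, 1L)
  expect_equal(st$max_size, 10)
  expect_equal(st$participation, 1)
  # full reversal preserves adjacency
  mr <- make_map(1:10, 10:1)
  str_ <- block_stats(build_blocks(mr, 0L))
  expect_equal(str_$n_blocks, 1L)
  expect_equal(str_$participation, 1)
  # (1,2,3,4) vs (2,1,4,3): two two-gene blocks
  ms <- make_map(1:4, c(2L, 1L, 4L, 3L))
  bs <- build_blocks(ms, 0L)
  expect_equal(block_stats(bs)$n_blocks, 2L)
  expect_equal(sort(bs$blocks$n_pairs), c(2L, 2L))
})

test_that("blocks equal the explicit link-matrix components oracle on
           random instances", {
  set.seed(12)
  for (rep in 1:300) {
    n <- sample(4:12, 1L)
    m <- random_map(n, sample(1:2, 1L), sample(1:2, 1L))
    w <- sample(0:3, 1L)
    got <- build_blocks(m, w)
    want <- oracle_blocks(m, w)
    expect_equal(sum(!is.na(got$members$block_id)),
                 sum(want$in_block))
    expect_equal(nrow(got$blocks), want$n_blocks)
    # same partition: members share a block id iff oracle components agree
    gm <- got$members$block_id
    for (i in seq_len(n - 1L)) {
      same_got <- !is.na(gm[i]) & !is.na(gm[i + 1L]) &
        gm[i] == gm[i + 1L]
      same_want <- want$in_block[i] && want$in_block[i + 1L] &&
        want$membership[i] == want$membership[i + 1L]
      expect_equal(same_got, same_want)
    }
  }
})

test_that("participation is non-decreasing in w and invariant to
           scaffold reversal", {
  set.seed(5)
  m <- random_map(40, 2L, 2L)
  parts <- vapply(0:6, function(w)
    block_stats(build_blocks(m, w))$participation, numeric(1))
  expect_true(all(diff(parts) >= 0))
  # reversing one genome's orders leaves blocks unchanged
  mrev <- m
  for (s in unique(m$scaffold_a)) {
    i <- m$scaffold_a == s
    mrev$pos_a[i] <- max(m$pos_a[i]) + 1L - m$pos_a[i]
  }
  for (w in c(0L, 2L)) {
    a <- build_blocks(m, w); b <- build_blocks(mrev, w)
    expect_equal(sort(table(a$members$block_id)),
                 sort(table(b$members$block_id)), ignore_attr = TRUE)
  }
})

test_that("intervening genes are counted in the ortholog-restricted
           order", {
  # w = 1 links pairs separated by one ortholog-bearing gene
  m <- make_map(1:5, c(1L, 3L, 5L, 2L, 4L))
  st0 <- block_stats(build_blocks(m, 0L))
  st1 <- block_stats(build_blocks(m, 1L))
  expect_lte(st0$participation, st1$participation)
  expect_equal(st1$participation, 1)
})

test_that("permutation is seeded, per-scaffold, and leaves single-gene
           scaffolds untouched", {
  m <- random_map(30, 3L, 2L)
  p1 <- permute_map(m, 7L)
  p2 <- permute_map(m, 7L)
  expect_identical(p1, p2)
  expect_identical(p1$scaffold_a, m$scaffold_a)
  expect_identical(p1$gene_b, m$gene_b)
  single <- ortholog_map(data.frame(
    gene_a = "x", gene_b = "y", scaffold_a = "s", pos_a = 1L,
    chrom_b = "c", pos_b = 1L, stringsAsFactors = FALSE))
  expect_identical(permute_map(single, 3L), single)
})

test_that("uniform permutation preserves each adjacency with
           probability 2/n", {
  n <- 2000L
  m <- make_map(seq_len(n), seq_len(n))
  set.seed(77)
  n_perm <- 60L
  frac <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pm <- dictycomp:::.permute_map_once(m)
    pb <- pm$pos_b
    adj <- abs(pb[seq_len(n - 1L) + 1L] - pb[seq_len(n - 1L)]) == 1L
    frac[i] <- mean(adj)
  }
  p_adj <- 2 / n
  mc_sd <- sqrt(p_adj * (1 - p_adj) / (n - 1)) / sqrt(n_perm)
  expect_lt(abs(mean(frac) - p_adj), 3 * mc_sd + 1e-6)
})

test_that("null distribution mean for n = 4 at w = 0 equals the
           exhaustive value 2/3", {
  m <- make_map(1:4, 1:4)
  perms <- matrix(c(1,2,3,4, 1,2,4,3, 1,3,2,4, 1,3,4,2, 1,4,2,3,
                    1,4,3,2, 2,1,3,4, 2,1,4,3, 2,3,1,4, 2,3,4,1,
                    2,4,1,3, 2,4,3,1, 3,1,2,4, 3,1,4,2, 3,2,1,4,
                    3,2,4,1, 3,4,1,2, 3,4,2,1, 4,1,2,3, 4,1,3,2,
                    4,2,1,3, 4,2,3,1, 4,3,1,2, 4,3,2,1),
                  ncol = 4L, byrow = TRUE)
  parts <- apply(perms, 1L, function(ord) {
    mm <- m
    mm$pos_b <- ord
    block_stats(build_blocks(mm, 0L))$participation
  })
  expect_equal(mean(parts), 2 / 3, tolerance = 1e-12)
  # the sampled null agrees with the exhaustive mean
  null <- null_distribution(m, 0L, n_perm = 400L, seed = 10L)
  expect_lt(abs(null$participation_mean - 2 / 3),
            3 * null$participation_sd / sqrt(400) + 0.02)
  expect_error(null_distribution(m, 0L, n_perm = 1L), "n_perm")
})

test_that("rearrangement breakpoints produce r + 1 blocks at w = 0 on a
           single-scaffold pair", {
  for (r in c(1L, 3L, 5L)) {
    ds <- generate_dataset(
      sim_config(n_genes = 40L, n_scaffolds_a = 1L, n_scaffolds_b = 1L,
                 rearrangement_ops = r, gene_turnover = 0,
                 n_ncrna_loci = 0L, slippage_rate = 0,
                 homopolymer_rate = 0, gene_len_codons = c(60L, 90L),
                 intergenic_len = c(150L, 250L), seed = 50L + r),
      file.path(tempdir(), paste0("synt_r", r)))
    map <- ordered_ortholog_map(
      read_gff3(ds$paths[["gff_a"]]), read_gff3(ds$paths[["gff_b"]]),
      read_ortholog_table(ds$paths[["orthologs"]]))
    st <- block_stats(build_blocks(map, 0L))
    expect_equal(st$n_blocks, r + 1L)
    expect_equal(length(ds$truth$rearrangement_cuts), r)
  }
})

test_that("w selection saturates at 0 for identical orders and flags
           random maps", {
  m <- make_map(1:30, 1:30)
  sel <- select_w(m, w_max = 4L, n_perm = 40L, seed = 3L)
  expect_equal(sel$w, 0L)
  expect_false(sel$no_significant_synteny)
  set.seed(99)
  mr <- make_map(1:40, sample(40))
  selr <- select_w(mr, w_max = 4L, n_perm = 40L, seed = 3L)
  expect_true(selr$no_significant_synteny || selr$w == 0L)
})

test_that("w selection tracks the spacing of interleaved blocks", {
  # genome B interleaves blocks at spacing s: participation only grows
  # once w reaches the spacing, so larger spacing gives larger chosen w
  interleave <- function(s, n = 60L) {
    stopifnot(n %% s == 0L)
    # B order 1, n/s+1, 2*n/s+1, ..., 2, ...: A-neighbours sit s apart
    ord <- as.vector(t(matrix(seq_len(n), ncol = s)))
    make_map(seq_len(n), ord)
  }
  chosen <- vapply(c(2L, 5L), function(s)
    select_w(interleave(s, 60L), w_max = 8L, n_perm = 30L,
             seed = 4L)$w, integer(1))
  expect_true(chosen[2] > chosen[1])
})

test_that("false positive rate is the null/real participation ratio", {
  null <- structure(list(participation_mean = 0.058,
                         participation_sd = 0.004,
                         n_permutations = 100L, seed = 1L),
                    class = c("null_summary", "list"))
  expect_equal(fpr_estimate(0.76, null), 0.058 / 0.76)
  expect_equal(fpr_estimate(0.76, null), 0.076, tolerance = 0.01)
  null0 <- null; null0$participation_mean <- 0
  expect_equal(fpr_estimate(0.5, null0), 0)
  nullr <- null; nullr$participation_mean <- 0.5
  expect_equal(fpr_estimate(0.5, nullr), 1)
  expect_error(fpr_estimate(0, null), "undefined")
})

test_that("the ordered map construction rejects unresolvable genes", {
  gpath <- write_tiny_gff3()
  models <- read_gff3(gpath)
  orth <- data.frame(gene_a = "gplus", gene_b = "missing",
                     relation = "one_to_one", stringsAsFactors = FALSE)
  expect_error(ordered_ortholog_map(models, models, orth), "missing")
})
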