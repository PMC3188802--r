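test_that("chance-model thresholds match direct evaluation of
           N * f^L <= alpha", {
  # oracle: evaluate the expectation over L = 2..30 directly
  direct <- function(f, N, alpha) {
    for (L in 2:30) if (N * f^L <= alpha) return(L)
    NA_integer_
  }
  expect_equal(min_run_len(0.1, 6.4e6, 0.01), 9L)
  expect_equal(direct(0.1, 6.4e6, 0.01), 9L)
  expect_equal(min_run_len(0.02, 6.4e6, 0.01), 6L)
  expect_equal(direct(0.02, 6.4e6, 0.01), 6L)
  for (f in c(0.005, 0.03, 0.07, 0.12)) {
    expect_equal(min_run_len(f, 6.4e6, 0.01), direct(f, 6.4e6, 0.01))
  }
  expect_true(is.na(min_run_len(0, 6.4e6, 0.01)))
})

test_that("thresholds from a proteome reflect its composition and flag
           absent amino acids", {
  set.seed(1)
  # 10% N, 2% C, rest spread over other amino acids; no W at all
  pool <- c(rep("N", 10), rep("C", 2), rep(c("A", "L", "K", "I", "S",
                                             "T", "E", "D"), 11))
  prot <- paste(sample(pool, 20000, TRUE), collapse = "")
  thr <- aa_run_thresholds(prot)
  expect_false(thr$defined[thr$amino_acid == "W"])
  # more frequent amino acids need longer runs
  expect_gt(thr$min_len[thr$amino_acid == "N"],
            thr$min_len[thr$amino_acid == "C"])
  expect_error(aa_run_thresholds("ACDEF"), "too small")
})

test_that("maximal runs are found with significance and codons", {
  thr <- data.frame(amino_acid = c("N", "Q"), frequency = c(.1, .05),
                    min_len = c(9L, 6L), defined = TRUE)
  runs <- find_homopolymers(c(p1 = "MNNNNNNNNNNK"), thr)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$length, 10L)
  expect_true(runs$significant)
  runs8 <- find_homopolymers(c(p1 = "MNNNNNNNNK"), thr)
  expect_equal(runs8$length, 8L)
  expect_false(runs8$significant)
  # codons attached and checked against the protein
  rq <- find_homopolymers(c(p = "MQQQ"), thr,
                          cds = c(p = "ATGCAACAGCAA"))
  expect_equal(rq$codons, "CAA,CAG,CAA")
  expect_error(find_homopolymers(c(p = "MQQQ"), thr,
                                 cds = c(p = "ATGCAACAGCAT")),
               "first difference at residue 4")
})

test_that("runs agree with a brute-force scanner on random proteins", {
  brute <- function(s) {
    v <- strsplit(s, "")[[1L]]
    out <- NULL
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      if (j - i + 1L >= 2L)
        out <- rbind(out, data.frame(amino_acid = v[i], start = i,
                                     length = j - i + 1L))
      i <- j + 1L
    }
    out
  }
  thr <- data.frame(amino_acid = c("A", "N", "Q"), frequency = .05,
                    min_len = 6L, defined = TRUE)
  set.seed(9)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "N", "Q", "K", "L"), 300, TRUE,
                      prob = c(.3, .3, .2, .1, .1)), collapse = "")
    got <- find_homopolymers(c(p = s), thr)
    want <- brute(s)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    expect_equal(got$amino_acid, want$amino_acid)
  }
})

test_that("repeat density uses significant runs only and conserves
           total length", {
  runs <- data.frame(protein_id = "p", amino_acid = c("N", "N", "S"),
                     start = c(1L, 20L, 40L), length = c(10L, 15L, 4L),
                     significant = c(TRUE, TRUE, FALSE),
                     codons = NA_character_)
  dens <- repeat_density(runs, 5000L)
  expect_equal(unname(dens["N"]), 5)
  expect_equal(unname(dens["S"]), 0)
  expect_equal(sum(dens) * 5000 / 1000, sum(runs$length[runs$significant]))
  one <- repeat_density(runs[1L, ], 1000L)
  expect_equal(unname(one["N"]), 10)
  expect_error(repeat_density(runs, 0L), "positive")
})

test_that("density correlation behaves like Pearson r", {
  x <- setNames(seq(0.1, 2, length.out = 20),
                strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]])
  expect_equal(density_correlation(x, x)$r, 1)
  expect_equal(density_correlation(x, 2 * x)$r, 1)
  expect_lt(density_correlation(x, setNames(rev(unname(x)),
                                            names(x)))$r, 0)
  expect_true(density_correlation(x, setNames(rep(1, 20),
                                              names(x)))$degenerate)
})

test_that("codon diversity normalizes by available codons", {
  expect_equal(codon_diversity(c("AAT", "AAT", "AAT")),
               list(distinct = 1L, diversity = 0))
  d <- codon_diversity(c("AAT", "AAC", "AAT", "AAC"))
  expect_equal(d$distinct, 2L)
  expect_equal(d$diversity, 1)   # both asparagine codons used
  # methionine has one codon: diversity 0 by convention
  expect_equal(codon_diversity(c("ATG", "ATG"))$diversity, 0)
  expect_error(codon_diversity(character()), "no codons")
  expect_error(codon_diversity(c("AAT", "ATG")), "one amino acid")
})

test_that("repeat homology needs same amino acid and aligned overlap", {
  thr <- data.frame(amino_acid = c("N", "Q"), frequency = .05,
                    min_len = 5L, defined = TRUE)
  pairs <- data.frame(gene_a = "ga", gene_b = "gb",
                      stringsAsFactors = FALSE)
  # identical proteins with an identical N run: homologous
  p <- "MKLNNNNNNKL"
  runs_a <- find_homopolymers(c(ga = p), thr)
  runs_b <- find_homopolymers(c(gb = p), thr)
  aln <- list(`ga|gb` = global_align(p, p))
  res <- call_repeat_homology(pairs, runs_a[runs_a$significant, ],
                              runs_b[runs_b$significant, ], aln)
  expect_true(all(res$calls$homologous))
  expect_equal(res$fractions$a$frac_homologous, 1)
  # runs of different amino acids at the same aligned position: not
  pq <- "MKLQQQQQQKL"
  runs_bq <- find_homopolymers(c(gb = pq), thr)
  alnq <- list(`ga|gb` = global_align(p, pq))
  resq <- call_repeat_homology(pairs, runs_a[runs_a$significant, ],
                               runs_bq[runs_bq$significant, ], alnq)
  expect_false(any(resq$calls$homologous))
  # run aligned wholly to a gap: not homologous
  pshort <- "MKLKL"
  runs_bs <- find_homopolymers(c(gb = pshort), thr)
  alns <- list(`ga|gb` = global_align(p, pshort))
  ress <- call_repeat_homology(pairs, runs_a[runs_a$significant, ],
                               runs_bs[runs_bs$significant, ], alns)
  expect_false(any(ress$calls$homologous))
})

test_that("repeat homology fractions are symmetric under species swap", {
  thr <- data.frame(amino_acid = "N", frequency = .05, min_len = 5L,
                    defined = TRUE)
  pa <- c(g1 = "MNNNNNNAAK", g2 = "MKKLLLAAAK")
  pb <- c(h1 = "MNNNNNNAAK", h2 = "MKKNNNNNNK")
  pairs <- data.frame(gene_a = c("g1", "g2"), gene_b = c("h1", "h2"),
                      stringsAsFactors = FALSE)
  runs_a <- find_homopolymers(pa, thr); runs_a <- runs_a[runs_a$significant, ]
  runs_b <- find_homopolymers(pb, thr); runs_b <- runs_b[runs_b$significant, ]
  al <- list(`g1|h1` = global_align(pa[["g1"]], pb[["h1"]]),
             `g2|h2` = global_align(pa[["g2"]], pb[["h2"]]))
  fwd <- call_repeat_homology(pairs, runs_a, runs_b, al)
  pairs_r <- data.frame(gene_a = c("h1", "h2"), gene_b = c("g1", "g2"),
                        stringsAsFactors = FALSE)
  al_r <- list(`h1|g1` = global_align(pb[["h1"]], pa[["g1"]]),
               `h2|g2` = global_align(pb[["h2"]], pa[["g2"]]))
  rev <- call_repeat_homology(pairs_r, runs_b, runs_a, al_r)
  expect_equal(fwd$fractions$a, rev$fractions$b)
  expect_equal(fwd$fractions$b, rev$fractions$a)
})

test_that("group comparison reports direction and detects large shifts", {
  set.seed(4)
  v <- c(rnorm(50), rnorm(50) + 3)
  flag <- rep(c(FALSE, TRUE), each = 50)
  res_t <- compare_by_repeat_status(v, flag, "t")
  expect_lt(res_t$p, 1e-3)
  expect_equal(res_t$direction, 1)
  res_w <- compare_by_repeat_status(v, flag, "mannwhitney")
  expect_lt(res_w$p, 1e-3)
  deg <- compare_by_repeat_status(rep(1, 20), rep(c(TRUE, FALSE), 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(compare_by_repeat_status(1:5, c(TRUE, rep(FALSE, 4))),
               "at least 2")
})

test_that("planted homopolymers are recovered exactly from the
           synthetic proteomes", {
  ds <- generate_dataset(tiny_sim(homopolymer_rate = 1.2, seed = 31L),
                         file.path(tempdir(), "hp_recov"))
  for (sp in c("a", "b")) {
    prot <- read_seq_fasta(ds$paths[[paste0("proteins_", sp)]])
    thr <- aa_run_thresholds(prot)
    runs <- find_homopolymers(prot, thr)
    sig <- runs[runs$significant, ]
    tru <- ds$truth$homopolymers
    tru <- tru[tru$species == sp, ]
    expect_gt(nrow(tru), 0L)
    expect_setequal(
      paste(sig$protein_id, sig$start, sig$length, sig$amino_acid),
      paste(tru$protein_id, tru$start, tru$length, tru$amino_acid))
  }
})
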