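test_that("minimum copy thresholds are sharp at the boundary", {
  # mononucleotide: 10 copies in, 9 out
  expect_equal(nrow(find_ssr_tracts(c(s = strrep("A", 10)))), 1L)
  expect_equal(nrow(find_ssr_tracts(c(s = strrep("A", 9)))), 0L)
  # trinucleotide: 5 copies qualify
  t3 <- find_ssr_tracts(c(s = paste0("T", strrep("ACG", 5), "T")))
  expect_equal(nrow(t3), 1L)
  expect_equal(t3$copies, 5)
  expect_equal(t3$unit, "ACG")
  expect_equal(nrow(find_ssr_tracts(c(s = paste0("T", strrep("ACG", 4),
                                                 "T")))), 0L)
  # dinucleotide boundary at 7
  expect_equal(nrow(find_ssr_tracts(c(s = paste0("G", strrep("AT", 7),
                                                 "G")))), 1L)
  expect_equal(nrow(find_ssr_tracts(c(s = paste0("G", strrep("AT", 6),
                                                 "G")))), 0L)
})

test_that("tracts are maximal, canonical-phase, and fractional tails
           count toward length but not qualification", {
  # 5 whole CGA copies plus 2 extra bases: copies fractional
  t <- find_ssr_tracts(c(s = paste0("TT", strrep("CGA", 5), "CG", "TT")))
  expect_equal(nrow(t), 1L)
  expect_equal(t$end - t$start + 1L, 17L)
  expect_equal(t$copies, 17 / 3)
  expect_equal(t$unit, "ACG")   # lexicographically least rotation
  # 4 whole copies + partial does not reach 5 whole copies
  t2 <- find_ssr_tracts(c(s = paste0("TT", strrep("CGA", 4), "CG", "TT")))
  expect_equal(nrow(t2), 0L)
})

test_that("units that repeat a shorter unit are reported at the shortest
           length only", {
  t <- find_ssr_tracts(c(s = paste0("C", strrep("A", 20), "C")))
  expect_equal(t$unit_length, 1L)
  t2 <- find_ssr_tracts(c(s = paste0("C", strrep("AT", 10), "C")))
  expect_equal(t2$unit_length, 2L)
})

test_that("masked and N positions terminate tracts", {
  # 12 As with an N in the middle: neither side reaches 10
  expect_equal(nrow(find_ssr_tracts(c(s = paste0(strrep("A", 6), "N",
                                                 strrep("A", 6))))), 0L)
  # soft-mask splits a 20-A run the same way
  path <- write_tmp_fasta(list(s = paste0(strrep("A", 9), "aa",
                                          strrep("A", 9))))
  g <- read_genome_fasta(path)
  expect_equal(nrow(find_ssr_tracts(g)), 0L)
})

test_that("detector agrees with the brute-force scanner on random
           AT-rich sequence", {
  for (seed in 1:4) {
    set.seed(seed)
    s <- paste(sample(c("A", "T", "C", "G"), 5000, TRUE,
                      prob = c(0.39, 0.39, 0.11, 0.11)), collapse = "")
    got <- find_ssr_tracts(c(chr = s))
    want <- oracle_ssr_scan(s)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$unit, want$unit)
    expect_equal(got$copies, want$copies)
  }
})

test_that("lowering a min-copies entry never removes a tract", {
  set.seed(42)
  s <- paste(sample(c("A", "T", "C", "G"), 8000, TRUE,
                    prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
  base <- find_ssr_tracts(c(chr = s))
  lowered <- c(8, 5, 4, 3, rep(2, 16))
  more <- find_ssr_tracts(c(chr = s), lowered)
  key <- function(df) paste(df$start, df$unit_length)
  expect_true(all(key(base) %in% key(more)))
})

test_that("output is invariant under scaffold order", {
  set.seed(3)
  s1 <- paste(sample(c("A", "T", "G", "C"), 2000, TRUE,
                     prob = c(.4, .4, .1, .1)), collapse = "")
  s2 <- paste0(strrep("A", 12), strrep("TTG", 6))
  a <- find_ssr_tracts(c(x = s1, y = s2))
  b <- find_ssr_tracts(c(y = s2, x = s1))
  key <- function(df) sort(paste(df$scaffold_id, df$start, df$unit))
  expect_equal(key(a), key(b))
})

test_that("coding classification uses >= 1 bp overlap on closed
           intervals", {
  tracts <- data.frame(scaffold_id = "s1", start = 100L, end = 129L,
                       unit_length = 1L, unit = "A", copies = 30,
                       coding = NA)
  models_ov <- gene_models(
    data.frame(gene_id = "g", scaffold_id = "s1", start = 120L,
               end = 300L, strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g", start = 120L, end = 300L))
  expect_true(classify_coding(tracts, models_ov)$coding)
  models_ab <- gene_models(
    data.frame(gene_id = "g", scaffold_id = "s1", start = 130L,
               end = 300L, strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g", start = 130L, end = 300L))
  expect_false(classify_coding(tracts, models_ab)$coding)
  expect_warning(out <- classify_coding(tracts, NULL), "non-coding")
  expect_false(out$coding)
  models_other <- gene_models(
    data.frame(gene_id = "g", scaffold_id = "sX", start = 1L,
               end = 50L, strand = "+", stringsAsFactors = FALSE),
    data.frame(gene_id = "g", start = 1L, end = 50L))
  expect_error(classify_coding(tracts, models_other), "do not match")
})

test_that("summary computes union fraction and strict >100 bp count", {
  tracts <- data.frame(
    scaffold_id = c("s", "s", "s"),
    start = c(1L, 1L, 500L), end = c(44L, 44L, 600L),
    unit_length = c(1L, 1L, 1L), unit = "A",
    copies = c(44, 44, 101), coding = FALSE)
  summ <- ssr_summary(tracts[1L, ], 1000L)
  expect_equal(summ$genome_fraction, 0.044)
  # identical overlapping tracts counted once under union semantics
  summ2 <- ssr_summary(tracts[1:2, ], 1000L)
  expect_equal(summ2$genome_fraction, 0.044)
  summ2s <- ssr_summary(tracts[1:2, ], 1000L, summed_bp = TRUE)
  expect_equal(summ2s$genome_fraction, 0.088)
  # 101 bp tract counts as long, 100 bp does not
  expect_equal(ssr_summary(tracts, 1000L)$n_long, 1L)
  t100 <- tracts[3L, ]; t100$end <- 599L
  expect_equal(ssr_summary(t100, 1000L)$n_long, 0L)
  expect_error(ssr_summary(tracts, 0L), "positive")
})

test_that("every planted tract is recovered exactly and exclusively", {
  ds <- generate_dataset(tiny_sim(slippage_rate = 1.2, seed = 21L),
                         file.path(tempdir(), "ssr_recov"))
  genome <- read_genome_fasta(ds$paths[["genome_a"]])
  got <- find_ssr_tracts(genome)
  tru <- ds$truth$repeats
  expect_gt(nrow(tru), 0L)
  key <- function(s, st, k, len) paste(s, st, k, len)
  expect_setequal(
    key(got$scaffold_id, got$start, got$unit_length,
        got$end - got$start + 1L),
    key(tru$scaffold_id, tru$start, tru$unit_length, tru$length))
})
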