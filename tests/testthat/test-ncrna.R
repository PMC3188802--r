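test_that("the DUSE motif matches its degenerate instantiations only", {
  g <- c(s = "TTACCCAAAATTTCCCATAATTGCCCAAAA")
  hits <- scan_motif(g, "WCCCAWAA")
  expect_equal(hits$start, c(3L, 13L))   # ACCCAAAA and TCCCATAA
  expect_equal(nrow(scan_motif(c(s = "GCCCAAAA"), "WCCCAWAA")), 0L)
  expect_error(scan_motif(g, "WCCCAZAA"), "IUPAC")
})

test_that("masked positions exclude motif matches when asked", {
  path <- write_tmp_fasta(list(s = "TTacccaaaaTTACCCAAAA"))
  g <- read_genome_fasta(path)
  all_hits <- scan_motif(g, "WCCCAWAA", respect_mask = FALSE)
  expect_equal(nrow(all_hits), 2L)
  unmasked <- scan_motif(g, "WCCCAWAA", respect_mask = TRUE)
  expect_equal(unmasked$start, 13L)
  # an N in the subject never matches
  expect_equal(nrow(scan_motif(c(s = "ACCCANAA"), "WCCCAWAA")), 0L)
})

test_that("a planted always-DUSE k-mer ranks first in the enrichment
           table", {
  set.seed(6)
  bg <- function(n) paste(sample(c("A", "T", "G", "C"), n, TRUE,
                                 prob = c(.4, .4, .1, .1)),
                          collapse = "")
  # plant GATTCCGA with a DUSE 63 bp upstream, 30 times
  locus <- function() paste0("ACCCAAAA", bg(55L), "GATTCCGA")
  geno <- paste0(bg(500L),
                 paste(vapply(1:30, function(i)
                   paste0(locus(), bg(120L)), character(1)),
                   collapse = ""))
  enr <- kmer_duse_enrichment(c(s = geno), min_count = 5L)
  expect_equal(enr$kmer[1L], "GATTCCGA")
  expect_equal(enr$n_with_duse[enr$kmer == "GATTCCGA"], 30L)
  # no DUSE anywhere: all scores at baseline
  set.seed(8)
  flat <- gsub("CCCA", "CGTA", bg(20000L))
  enr0 <- kmer_duse_enrichment(c(s = flat), min_count = 5L)
  expect_equal(attr(enr0, "p0"), 0)
  expect_true(all(enr0$n_with_duse == 0L))
  expect_error(kmer_duse_enrichment(c(s = geno),
                                    duse_window = c(90L, 40L)),
               "malformed")
})

test_that("the structural filter accepts the canonical constructed locus
           and rejects broken ones", {
  # deterministic flanks chosen so no chance 5' stem / reverse-complement
  # pair exists besides the constructed one
  build <- function(stem5 = "GAATT", sep = 50L, stem3 = NULL,
                    bulge = "CCTTACAGCCAA") {
    if (is.null(stem3)) stem3 <- dictycomp:::.revcomp(stem5)
    spacer <- strrep("T", sep - nchar(bulge))
    paste0(strrep("G", 40L), "ACCCAAAA",
           paste0(strrep("GT", 31L), "G"),     # 63 bp
           stem5, bulge, spacer, stem3, strrep("G", 60L))
  }
  anchor <- 40L + 8L + 63L + 5L + 1L
  good <- build()
  cand <- stem_filter(c(s = good), anchor)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$stem5, "GAATT")
  expect_equal(cand$stem3, "AATTC")
  expect_equal(cand$stem_separation, 50L)
  expect_true(cand$bulge_present)
  # separation beyond 70 bp: rejected
  far <- build(sep = 80L)
  expect_equal(nrow(stem_filter(c(s = far), anchor)), 0L)
  # broken complementarity: rejected
  broken <- build(stem3 = "AATTG")
  expect_equal(nrow(stem_filter(c(s = broken), anchor)), 0L)
  # no DUSE upstream: rejected
  no_duse <- sub("ACCCAAAA", "ACGGATCA", good, fixed = TRUE)
  expect_equal(nrow(stem_filter(c(s = no_duse), anchor)), 0L)
  # stem3 reverse-complement invariant on all emitted candidates
  expect_equal(cand$stem3, dictycomp:::.revcomp(cand$stem5))
  expect_warning(stem_filter(c(s = good), 10000L), "out of bounds")
})

test_that("class assignment follows the 5' stem lookup", {
  cand <- data.frame(stem5 = c("GTTGA", "GCTCG", "GAATT"),
                     assigned_class = "putative",
                     stringsAsFactors = FALSE)
  out <- assign_class(cand)
  expect_equal(out$assigned_class, c("classI", "classII", "putative"))
  out2 <- assign_class(cand, class_stems = setNames(character(),
                                                    character()))
  expect_equal(out2$assigned_class, rep("putative", 3L))
})

test_that("planted ncRNA loci are recovered exactly once each, with
           classes", {
  ds <- generate_dataset(tiny_sim(n_ncrna_loci = 6L, seed = 61L),
                         file.path(tempdir(), "nc_recov"))
  genome <- read_genome_fasta(ds$paths[["genome_a"]])
  anchors <- scan_motif(genome, "CCTTACAG")
  cands <- assign_class(stem_filter(genome, anchors))
  tru <- ds$truth$ncrna
  expect_equal(nrow(cands), nrow(tru))
  expect_setequal(
    paste(cands$scaffold_id, cands$anchor_start, cands$stem5_start,
          cands$stem3_start),
    paste(tru$scaffold_id, tru$anchor_start, tru$stem5_start,
          tru$stem3_start))
  m <- match(paste(cands$scaffold_id, cands$anchor_start),
             paste(tru$scaffold_id, tru$anchor_start))
  expect_equal(cands$assigned_class[tru$class[m] == "classI"],
               rep("classI", sum(tru$class[m] == "classI")))
  expect_true(all(cands$bulge_present))
  expect_true(all(cands$stem_separation >= 40L &
                    cands$stem_separation <= 70L))
  # results invariant to scaffold order
  rev_g <- genome[rev(seq_along(genome))]
  S4Vectors::metadata(rev_g)$mask <-
    S4Vectors::metadata(genome)$mask[rev(seq_along(genome))]
  cands_rev <- stem_filter(rev_g, scan_motif(rev_g, "CCTTACAG"))
  expect_setequal(paste(cands$scaffold_id, cands$anchor_start),
                  paste(cands_rev$scaffold_id, cands_rev$anchor_start))
})

test_that("the stem rule's chance hit rate on planted-free sequence
           matches the analytic expectation", {
  # with a single stem placement (the anchor itself), a chance candidate
  # needs the 5-mer's reverse complement at one of the 31 allowed
  # separations; per-base complement-match probability is
  # sum_b p(b) p(comp(b)), so p5 = 0.34^5 here and
  # P(candidate) ~ 1 - (1 - p5)^31
  set.seed(13)
  probs <- c(A = .4, T = .4, G = .1, C = .1)
  bg <- function(n) paste(sample(names(probs), n, TRUE, probs),
                          collapse = "")
  n_anchor <- 400L
  hits <- 0L
  for (i in seq_len(n_anchor)) {
    s <- paste0(bg(40L), "ACCCAAAA", bg(63L), bg(150L))
    anchor <- 40L + 8L + 63L + 5L + 1L
    got <- stem_filter(c(s = s), anchor, stem5_offset = 0L)
    hits <- hits + as.integer(nrow(got) > 0L)
  }
  p_comp <- sum(probs * probs[c("T", "A", "C", "G")])
  p5 <- p_comp^5
  p_cand <- 1 - (1 - p5)^31L
  se <- sqrt(p_cand * (1 - p_cand) / n_anchor)
  expect_lt(abs(hits / n_anchor - p_cand), 4 * se + 0.02)
})
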