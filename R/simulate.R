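# Synthetic paired-genome generator with planted, recorded ground truth:
# AT-rich two-genome pairs with a planted ortholog map, countable
# rearrangements, slippage repeat tracts, homopolymer-bearing proteins
# with controlled dN, DUSE+stem ncRNA loci, and negative-binomial
# stage-structured expression counts.

.STOPS <- c("TAA", "TAG", "TGA")

# sample() that never falls into the 1:n expansion trap
.resample <- function(x, size, ...) x[sample.int(length(x), size, ...)]
.HP_AA <- c("N", "Q", "S", "T")   # dominant dictyostelid homopolymers

#' Simulation configuration
#'
#' Defaults are the package's fixed study conditions: an AT-rich
#' (77.6% A+T) pair of ~300-gene genomes with moderate rearrangement and
#' turnover, slippage repeats, homopolymer-bearing proteins in two dN
#' classes tied to a social/vegetative expression split, and a dozen
#' planted DUSE/stem ncRNA loci.
#'
#' @param ... Named overrides; unknown keys are rejected.
#' @return list of class \code{sim_config}.
#'
#' @section Keys:
#' \describe{
#'   \item{n_genes}{Genes per genome (300).}
#'   \item{n_scaffolds_a, n_scaffolds_b}{Scaffold counts (4, 6).}
#'   \item{at_fraction}{Target A+T content (0.776).}
#'   \item{rearrangement_ops}{Rearrangement breakpoints planted in the
#'     genome-B gene order (8).}
#'   \item{gene_turnover}{Fraction of genes unique to each species
#'     (0.15).}
#'   \item{slippage_rate}{Expected repeat tracts per kb of intergenic
#'     sequence (0.4).}
#'   \item{slippage_geometric_p}{Geometric parameter for extra copies
#'     beyond the qualifying minimum (0.5).}
#'   \item{homopolymer_rate}{Expected planted runs per protein (0.5).}
#'   \item{homopolymer_share}{Probability a planted run is placed at the
#'     homologous position of the ortholog as well (0.2).}
#'   \item{dn_low, dn_high}{Per-class nonsynonymous divergence targets
#'     (0.15, 0.35).}
#'   \item{social_fraction}{Fraction of ortholog pairs in the social
#'     class (0.5); social genes get \code{dn_high}.}
#'   \item{social_effect}{Difference in expected social index between the
#'     classes (0.3).}
#'   \item{nb_dispersion}{Negative-binomial dispersion of counts (0.5).}
#'   \item{n_ncrna_loci}{Planted DUSE/stem ncRNA loci in genome A (12).}
#'   \item{gene_len_codons, intergenic_len}{Uniform length ranges.}
#'   \item{scrub_background}{Reject background sequence containing chance
#'     repeat tracts, homopolymer runs >= 6, DUSE matches or NSBR anchor
#'     8-mers, so planted truth is exhaustive (TRUE).}
#'   \item{seed}{Integer seed (1).}
#' }
#' @export
sim_config <- function(...) {
  defaults <- list(
    n_genes = 300L, n_scaffolds_a = 4L, n_scaffolds_b = 6L,
    at_fraction = 0.776,
    rearrangement_ops = 8L, gene_turnover = 0.15,
    slippage_rate = 0.4, slippage_geometric_p = 0.5,
    homopolymer_rate = 0.5, homopolymer_share = 0.2,
    dn_low = 0.15, dn_high = 0.35,
    social_fraction = 0.5, social_effect = 0.3,
    nb_dispersion = 0.5,
    n_ncrna_loci = 12L,
    gene_len_codons = c(100L, 300L),
    intergenic_len = c(300L, 600L),
    scrub_background = TRUE,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  props <- c(cfg$at_fraction, cfg$gene_turnover, cfg$social_fraction,
             cfg$social_effect, cfg$homopolymer_share,
             cfg$slippage_geometric_p)
  if (any(props < 0 | props > 1))
    stop("proportions must lie in [0, 1]")
  if (cfg$n_genes < 2L || cfg$n_scaffolds_a < 1L || cfg$n_scaffolds_b < 1L)
    stop("counts must be positive")
  n_orth <- cfg$n_genes - round(cfg$n_genes * cfg$gene_turnover)
  if (cfg$rearrangement_ops > 0 && n_orth < 2L * (cfg$rearrangement_ops + 1L))
    stop("infeasible config: ", cfg$rearrangement_ops,
         " rearrangements need at least ",
         2L * (cfg$rearrangement_ops + 1L), " ortholog genes")
  structure(cfg, class = c("sim_config", "list"))
}

# -- low-level sequence generation ------------------------------------------

.rand_nt <- function(n, at) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2))
}

# excluding stop codons depletes A+T relative to iid base sampling;
# calibrate the per-base bias so the sense-codon composition hits the
# target A+T fraction
.bias_cache <- new.env(parent = emptyenv())
.codon_nt_bias <- function(target) {
  key <- sprintf("%.6f", target)
  if (!is.null(.bias_cache[[key]])) return(.bias_cache[[key]])
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  splits <- strsplit(sense, "")
  at_count <- vapply(splits, function(v) sum(v %in% c("A", "T")),
                     numeric(1)) / 3
  f <- function(x) {
    p <- c(A = x / 2, T = x / 2, C = (1 - x) / 2, G = (1 - x) / 2)
    w <- vapply(splits, function(v) prod(p[v]), numeric(1))
    sum(w / sum(w) * at_count) - target
  }
  root <- if (target <= 0 || target >= 1) target else
    stats::uniroot(f, c(max(1e-3, target - 0.02),
                        min(0.999, target + 0.15)))$root
  .bias_cache[[key]] <- root
  root
}

.gen_codons <- function(n_codons, at) {
  at <- .codon_nt_bias(at)
  repeat {
    m <- matrix(.rand_nt(3L * n_codons, at), nrow = 3L)
    codons <- paste0(m[1L, ], m[2L, ], m[3L, ])
    bad <- codons %in% .STOPS
    if (!any(bad)) return(codons)
    codons[bad] <- vapply(seq_len(sum(bad)), function(i) {
      repeat {
        cc <- paste(.rand_nt(3L, at), collapse = "")
        if (!cc %in% .STOPS) return(cc)
      }
    }, character(1))
    return(codons)
  }
}

# qualifying-tract scan used for scrubbing and truth validation (start,
# unit length, total length of every maximal qualifying tract)
.naive_scan_tracts <- function(v, min_copies = c(10, 7, 5, 4, rep(3, 16))) {
  n <- length(v)
  out <- list()
  for (k in 1:20) {
    if (n < min_copies[k] * k) next
    eq <- v[seq_len(n - k)] == v[seq.int(k + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values & r$lengths >= (min_copies[k] - 1) * k)) {
      total <- r$lengths[h] + k
      if (total %/% k < min_copies[k]) next
      unit <- paste(v[seq.int(starts[h], starts[h] + k - 1L)],
                    collapse = "")
      if (!.is_primitive(unit)) next
      out[[length(out) + 1L]] <- c(starts[h], k, total)
    }
  }
  if (!length(out))
    return(matrix(integer(), ncol = 3L,
                  dimnames = list(NULL, c("start", "k", "len"))))
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "k", "len")
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

.duse_regex <- "[AT]CCCA[AT]AA"
.ANCHOR8 <- c("CCTTACAG", "CTTACAGC")

.background_dirty <- function(s) {
  v <- strsplit(s, "")[[1L]]
  if (nrow(.naive_scan_tracts(v)) > 0L) return(TRUE)
  if (grepl(.duse_regex, s)) return(TRUE)
  if (any(vapply(.ANCHOR8, function(a) grepl(a, s, fixed = TRUE),
                 logical(1)))) return(TRUE)
  FALSE
}

.gen_intergenic <- function(len, at, scrub) {
  repeat {
    s <- paste(.rand_nt(len, at), collapse = "")
    if (!scrub || !.background_dirty(s)) return(s)
  }
}

.protein_of <- function(codons) {
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

.gene_dirty <- function(codons, scrub) {
  if (!scrub) return(FALSE)
  s <- paste(codons, collapse = "")
  v <- strsplit(s, "")[[1L]]
  if (nrow(.naive_scan_tracts(v)) > 0L) return(TRUE)
  if (any(vapply(.ANCHOR8, function(a) grepl(a, s, fixed = TRUE),
                 logical(1)))) return(TRUE)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(rle(aa)$lengths >= 6L)) return(TRUE)
  FALSE
}

.gen_gene <- function(n_codons, at, scrub) {
  repeat {
    codons <- .gen_codons(n_codons, at)
    if (!.gene_dirty(codons, scrub)) return(codons)
  }
}

# -- divergence to a dN target ----------------------------------------------

.diverge_codons <- function(codons, target_dn, at = 0.776) {
  tabs <- ng_codon_tables()
  n <- length(codons)
  S <- sum(tabs$syn_sites[codons])
  N <- 3 * n - S
  p_target <- 0.75 * (1 - exp(-4 * target_dn / 3))
  m <- min(n, stats::rpois(1L, p_target * N))
  if (m == 0L) return(codons)
  idx <- sample(n, m)
  nt <- c("A", "C", "G", "T")
  # weight replacement bases by the genome's AT-biased mutation spectrum
  # so divergence does not drift the composition away from the target
  base_p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2,
              T = at / 2)
  for (i in idx) {
    v <- strsplit(codons[i], "")[[1L]]
    aa0 <- unname(Biostrings::GENETIC_CODE[codons[i]])
    cands <- character(); wts <- numeric()
    for (pos in 1:3) for (b in setdiff(nt, v[pos])) {
      w <- v; w[pos] <- b
      alt <- paste(w, collapse = "")
      aa1 <- unname(Biostrings::GENETIC_CODE[alt])
      if (aa1 != "*" && aa1 != aa0) {
        cands <- c(cands, alt)
        wts <- c(wts, base_p[[b]])
      }
    }
    if (length(cands))
      codons[i] <- cands[[sample.int(length(cands), 1L,
                                     prob = wts)]]
  }
  codons
}

# -- homopolymer planting ----------------------------------------------------

.codons_for_aa <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

.gen_run_codons <- function(aa, len) {
  pool <- .codons_for_aa(aa)
  out <- character(len)
  streak <- 0L
  for (i in seq_len(len)) {
    pick <- sample(pool, 1L)
    if (i > 1L && pick == out[i - 1L]) streak <- streak + 1L
    else streak <- 1L
    if (streak >= 4L && length(pool) > 1L) {
      pick <- sample(setdiff(pool, out[i - 1L]), 1L)
      streak <- 1L
    }
    out[i] <- pick
  }
  out
}

# insert a homopolymer run into a codon vector; returns NULL if no valid
# position (flanking residues must differ from the run's amino acid and
# the modified CDS must stay clean); `runs` are previously planted runs
# in this protein, tolerated by the cleanliness check
# insertion before codon `pos` must not split an existing planted run
.pos_inside_runs <- function(pos, runs) {
  for (r in runs) {
    if (pos > r$start && pos < r$start + r$length) return(TRUE)
  }
  FALSE
}

.insert_run <- function(codons, aa, len, scrub, runs = list()) {
  aa_seq <- unname(Biostrings::GENETIC_CODE[codons])
  n <- length(codons)
  positions <- .resample(2:n, min(30L, n - 1L))
  for (pos in positions) {      # run inserted before codon `pos`
    if (aa_seq[pos - 1L] == aa || aa_seq[pos] == aa) next
    if (.pos_inside_runs(pos, runs)) next
    for (try in 1:5) {
      run <- .gen_run_codons(aa, len)
      cand <- append(codons, run, after = pos - 1L)
      if (!.gene_dirty_run_aware2(cand, runs, pos, len, scrub))
        return(list(codons = cand, start = pos))
    }
  }
  NULL
}

# -- ncRNA locus construction ------------------------------------------------

.make_ncrna_locus <- function(cfg, class_draw) {
  stem5 <- switch(class_draw,
                  classI = "GTTGA",
                  classII = "GCTCG",
                  paste(sample(c("A", "C", "G", "T"), 5L, replace = TRUE),
                        collapse = ""))
  duse <- paste0(sample(c("A", "T"), 1L), "CCCA",
                 sample(c("A", "T"), 1L), "AA")
  sep <- sample(40:70, 1L)
  bulge <- "CCTTACAGCCAA"
  spacer1 <- paste(.rand_nt(63L, cfg$at_fraction), collapse = "")
  spacer2 <- paste(.rand_nt(sep - nchar(bulge), cfg$at_fraction),
                   collapse = "")
  stem3 <- .revcomp(stem5)
  locus <- paste0(duse, spacer1, stem5, bulge, spacer2, stem3)
  list(locus = locus, stem5 = stem5, stem3 = stem3, sep = sep,
       class = class_draw,
       # 1-based offsets within the locus string
       duse_off = 1L, stem5_off = 8L + 63L + 1L,
       anchor_off = 8L + 63L + 5L + 1L,
       stem3_off = 8L + 63L + 5L + sep + 1L)
}

# validate that within the assembled segment exactly the planted stem
# placement qualifies for the planted anchor
.validate_ncrna_in_context <- function(s, anchor, stem5_start,
                                       stem3_start) {
  n <- nchar(s)
  duse_pos <- c()
  mm <- gregexpr(.duse_regex, s)[[1L]]
  if (mm[1L] != -1L) duse_pos <- as.integer(mm)
  in_win <- duse_pos[anchor - duse_pos >= 40L & anchor - duse_pos <= 90L]
  if (length(in_win) != 1L) return(FALSE)
  hits <- 0L
  for (q in seq.int(max(1L, anchor - 15L), anchor)) {
    if (q + 4L > n) next
    st <- substr(s, q, q + 4L)
    if (grepl("[^ACGT]", st)) next
    rc <- .revcomp(st)
    for (sep in 40:70) {
      p3 <- q + 5L + sep
      if (p3 + 4L > n) break
      if (substr(s, p3, p3 + 4L) == rc) {
        hits <- hits + 1L
        if (!(q == stem5_start && p3 == stem3_start)) return(FALSE)
      }
    }
  }
  hits == 1L
}

# -- rearrangement planning --------------------------------------------------

.plan_rearrangement <- function(n_orth, r) {
  if (r == 0L)
    return(list(cuts = integer(), order = seq_len(n_orth),
                perm = 1L, flips = FALSE))
  # cuts between genes i and i+1; segments must keep >= 2 genes
  repeat {
    cuts <- sort(.resample(2:(n_orth - 2L), r))
    if (r == 1L || min(diff(cuts)) >= 2L) break
  }
  bounds <- c(0L, cuts, n_orth)
  segs <- lapply(seq_len(r + 1L), function(i)
    seq.int(bounds[i] + 1L, bounds[i + 1L]))
  for (attempt in 1:1000) {
    perm <- sample(r + 1L)
    flips <- sample(c(TRUE, FALSE), r + 1L, replace = TRUE)
    placed <- lapply(seq_len(r + 1L), function(i) {
      sg <- segs[[perm[i]]]
      if (flips[i]) rev(sg) else sg
    })
    ok <- TRUE
    for (i in seq_len(r)) {
      left <- placed[[i]][length(placed[[i]])]
      right <- placed[[i + 1L]][1L]
      if (abs(left - right) == 1L) { ok <- FALSE; break }
    }
    if (ok)
      return(list(cuts = cuts, order = unlist(placed), perm = perm,
                  flips = flips))
  }
  stop("could not plan a rearrangement without rejoining a cut")
}

# -- scaffold assembly -------------------------------------------------------

# genes: data.frame(gene_id, seq (oriented genomic CDS), strand)
.assemble_scaffold <- function(scaffold_id, genes, cfg, plant_tracts,
                               ncrna_classes, min_copies) {
  n_genes <- nrow(genes)
  for (attempt in 1:50) {
    n_seg <- n_genes + 1L
    seg_lens <- sample(seq.int(cfg$intergenic_len[1L],
                               cfg$intergenic_len[2L]),
                       n_seg, replace = TRUE)
    segs <- vapply(seg_lens, .gen_intergenic, character(1),
                   at = cfg$at_fraction, scrub = cfg$scrub_background)
    tract_truth <- list()
    ncrna_truth <- list()
    # choose segments for ncRNA loci (at most one per segment), the rest
    # may receive slippage tracts
    ncrna_seg <- if (length(ncrna_classes))
      sample(n_seg, length(ncrna_classes)) else integer()
    for (j in seq_along(ncrna_seg)) {
      si <- ncrna_seg[j]
      for (tries in 1:50) {
        loc <- .make_ncrna_locus(cfg, ncrna_classes[j])
        off <- sample(seq.int(1L, nchar(segs[si]) + 1L -
                                0L), 1L)
        cand <- paste0(substr(segs[si], 1L, off - 1L), loc$locus,
                       substr(segs[si], off, nchar(segs[si])))
        anchor <- off - 1L + loc$anchor_off
        if (.validate_ncrna_in_context(cand, anchor,
                                       off - 1L + loc$stem5_off,
                                       off - 1L + loc$stem3_off)) {
          segs[si] <- cand
          ncrna_truth[[j]] <- data.frame(
            seg = si, anchor_local = anchor,
            duse_local = off - 1L + loc$duse_off,
            stem5_local = off - 1L + loc$stem5_off,
            stem3_local = off - 1L + loc$stem3_off,
            stem5 = loc$stem5, stem3 = loc$stem3,
            separation = loc$sep, class = loc$class,
            stringsAsFactors = FALSE)
          break
        }
        if (tries == 50L) stop("could not place ncRNA locus")
      }
    }
    if (plant_tracts) {
      for (si in setdiff(seq_len(n_seg), ncrna_seg)) {
        n_tr <- stats::rpois(1L, cfg$slippage_rate *
                               nchar(segs[si]) / 1000)
        if (n_tr == 0L) next
        planted <- list()
        seg <- segs[si]
        ok_seg <- TRUE
        for (t in seq_len(n_tr)) {
          placed <- FALSE
          for (tries in 1:50) {
            k <- sample(1:6, 1L)
            m <- min_copies[k] + stats::rgeom(1L, cfg$slippage_geometric_p)
            unit <- paste(.rand_nt(k, cfg$at_fraction), collapse = "")
            if (!.is_primitive(unit)) next
            tr <- strrep(unit, m)
            off <- sample(seq.int(2L, nchar(seg)), 1L)
            left_ok <- substr(seg, off - 1L, off - 1L) !=
              substr(unit, k, k)
            right_ok <- substr(seg, off, off) != substr(unit, 1L, 1L)
            if (!left_ok || !right_ok) next
            seg <- paste0(substr(seg, 1L, off - 1L), tr,
                          substr(seg, off, nchar(seg)))
            planted[[length(planted) + 1L]] <-
              c(start = off, k = k, len = m * k)
            # planted coordinates later in the segment shift
            if (length(planted) > 1L) {
              for (pp in seq_len(length(planted) - 1L)) {
                if (planted[[pp]]["start"] >= off)
                  planted[[pp]]["start"] <-
                    planted[[pp]]["start"] + m * k
              }
            }
            placed <- TRUE
            break
          }
          if (!placed) { ok_seg <- FALSE; break }
        }
        if (!ok_seg) next  # keep segment tract-free rather than fail
        # validate the final segment scan matches exactly the planted set
        found <- .naive_scan_tracts(strsplit(seg, "")[[1L]])
        want <- do.call(rbind, planted)
        want <- want[order(want[, "start"], want[, "k"]), , drop = FALSE]
        if (nrow(found) == nrow(want) &&
            all(found[, "start"] == want[, "start"]) &&
            all(found[, "k"] == want[, "k"]) &&
            all(found[, "len"] == want[, "len"])) {
          segs[si] <- seg
          tract_truth[[length(tract_truth) + 1L]] <-
            data.frame(seg = si, start_local = want[, "start"],
                       unit_length = want[, "k"], len = want[, "len"])
        }
        # else: drop this segment's tracts (segment unchanged)
      }
    }
    # assemble
    pieces <- character(2L * n_genes + 1L)
    pieces[seq(1L, 2L * n_genes + 1L, 2L)] <- segs
    if (n_genes > 0L)
      pieces[seq(2L, 2L * n_genes, 2L)] <- genes$seq
    full <- paste(pieces, collapse = "")
    piece_len <- nchar(pieces)
    piece_start <- cumsum(c(1L, piece_len[-length(piece_len)]))
    gene_starts <- piece_start[seq(2L, 2L * n_genes, 2L)]
    seg_starts <- piece_start[seq(1L, 2L * n_genes + 1L, 2L)]
    # each planted ncRNA locus must validate against the assembled
    # scaffold too: sequence beyond its segment (the neighbouring gene)
    # falls inside the stem search windows when the locus sits near a
    # segment boundary
    if (cfg$scrub_background && length(ncrna_truth)) {
      nt <- do.call(rbind, ncrna_truth)
      ok_loci <- all(vapply(seq_len(nrow(nt)), function(j)
        .validate_ncrna_in_context(
          full,
          seg_starts[nt$seg[j]] + nt$anchor_local[j] - 1L,
          seg_starts[nt$seg[j]] + nt$stem5_local[j] - 1L,
          seg_starts[nt$seg[j]] + nt$stem3_local[j] - 1L),
        logical(1)))
      if (!ok_loci) next   # re-place loci with fresh randomness
    }
    # genome-level check: the only qualifying tracts are the planted ones
    if (cfg$scrub_background) {
      found <- .naive_scan_tracts(strsplit(full, "")[[1L]])
      want <- if (length(tract_truth)) {
        tt <- do.call(rbind, tract_truth)
        gstart <- seg_starts[tt$seg] + tt$start_local - 1L
        mm <- cbind(start = gstart, k = tt$unit_length, len = tt$len)
        mm[order(mm[, "start"], mm[, "k"]), , drop = FALSE]
      } else matrix(integer(), ncol = 3L)
      if (nrow(found) != nrow(want) ||
          (nrow(found) > 0L &&
           !(all(found[, 1L] == want[, 1L]) &&
             all(found[, 2L] == want[, 2L]) &&
             all(found[, 3L] == want[, 3L]))))
        next  # junction artefact: rebuild scaffold
    }
    gene_tab <- if (n_genes > 0L) data.frame(
      gene_id = genes$gene_id, scaffold_id = scaffold_id,
      start = gene_starts,
      end = gene_starts + nchar(genes$seq) - 1L,
      strand = genes$strand, stringsAsFactors = FALSE)
    else data.frame(gene_id = character(), scaffold_id = character(),
                    start = integer(), end = integer(),
                    strand = character(), stringsAsFactors = FALSE)
    tract_tab <- if (length(tract_truth)) {
      tt <- do.call(rbind, tract_truth)
      data.frame(scaffold_id = scaffold_id,
                 start = seg_starts[tt$seg] + tt$start_local - 1L,
                 unit_length = tt$unit_length,
                 length = tt$len, stringsAsFactors = FALSE)
    } else data.frame(scaffold_id = character(), start = integer(),
                      unit_length = integer(), length = integer(),
                      stringsAsFactors = FALSE)
    ncrna_tab <- if (length(ncrna_truth)) {
      nt <- do.call(rbind, ncrna_truth)
      data.frame(scaffold_id = scaffold_id,
                 anchor_start = seg_starts[nt$seg] + nt$anchor_local - 1L,
                 duse_start = seg_starts[nt$seg] + nt$duse_local - 1L,
                 stem5_start = seg_starts[nt$seg] + nt$stem5_local - 1L,
                 stem3_start = seg_starts[nt$seg] + nt$stem3_local - 1L,
                 stem5 = nt$stem5, stem3 = nt$stem3,
                 separation = nt$separation, class = nt$class,
                 stringsAsFactors = FALSE)
    } else data.frame(scaffold_id = character(), anchor_start = integer(),
                      duse_start = integer(), stem5_start = integer(),
                      stem3_start = integer(), stem5 = character(),
                      stem3 = character(), separation = integer(),
                      class = character(), stringsAsFactors = FALSE)
    return(list(seq = full, genes = gene_tab, tracts = tract_tab,
                ncrna = ncrna_tab))
  }
  stop("could not assemble a clean scaffold after 50 attempts")
}

.chunk <- function(x, n_chunks) {
  if (n_chunks >= length(x)) n_chunks <- max(1L, min(n_chunks, length(x)))
  split(x, sort(rep_len(seq_len(n_chunks), length(x))))
}
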