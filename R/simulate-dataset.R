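# Dataset-level generation: ties the low-level generators together,
# writes the files the pipeline consumes, and records the planted truth.

.simulate_expression <- function(gene_ids, social, cfg) {
  n <- length(gene_ids)
  base <- stats::rlnorm(n, meanlog = log(200), sdlog = 0.7)
  share <- ifelse(social, 0.5 + cfg$social_effect / 2,
                  0.5 - cfg$social_effect / 2)
  libs <- c("veg", paste0("h", c(4L, 8L, 12L, 16L, 20L, 24L)))
  size <- 1 / cfg$nb_dispersion
  rows <- list()
  for (lib in libs) {
    mu <- if (lib == "veg") 2 * base * (1 - share) else 2 * base * share
    counts <- stats::rnbinom(n, size = size, mu = mu)
    rows[[lib]] <- data.frame(gene_id = gene_ids, library = lib,
                              count = counts, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  lib_tot <- tapply(tab$count, tab$library, sum)
  tab$pct <- tab$count / pmax(as.numeric(lib_tot[tab$library]), 1) * 100
  rownames(tab) <- NULL
  tab
}

# plant homopolymer runs into one ortholog codon pair; returns updated
# codon vectors plus run records (per species, with final positions)
.plant_runs_pair <- function(codons_a, codons_b, cfg) {
  runs_a <- list(); runs_b <- list()
  shift_runs <- function(runs, pos, len) {
    lapply(runs, function(r) {
      if (r$start >= pos) r$start <- r$start + len
      r
    })
  }
  draw_len <- function() 10L + stats::rgeom(1L, 0.3)
  n_shared <- stats::rpois(1L, cfg$homopolymer_rate * cfg$homopolymer_share)
  n_a <- stats::rpois(1L, cfg$homopolymer_rate * (1 - cfg$homopolymer_share))
  n_b <- stats::rpois(1L, cfg$homopolymer_rate * (1 - cfg$homopolymer_share))
  for (i in seq_len(n_shared)) {
    aa <- sample(.HP_AA, 1L)
    len <- draw_len()
    aa_a <- unname(Biostrings::GENETIC_CODE[codons_a])
    aa_b <- unname(Biostrings::GENETIC_CODE[codons_b])
    n <- length(codons_a)
    ok_pos <- which(seq_len(n) >= 2L & aa_a[pmax(seq_len(n) - 1L, 1L)] != aa &
                      aa_a != aa & aa_b[pmax(seq_len(n) - 1L, 1L)] != aa &
                      aa_b != aa)
    ok_pos <- ok_pos[ok_pos >= 2L]
    ok_pos <- ok_pos[!vapply(ok_pos, .pos_inside_runs, logical(1),
                             runs = c(runs_a, runs_b))]
    if (!length(ok_pos)) next
    placed <- FALSE
    for (pos in .resample(ok_pos, min(20L, length(ok_pos)))) {
      for (try in 1:5) {
        run_a <- .gen_run_codons(aa, len)
        run_b <- .gen_run_codons(aa, len)
        cand_a <- append(codons_a, run_a, after = pos - 1L)
        cand_b <- append(codons_b, run_b, after = pos - 1L)
        if (!.gene_dirty_run_aware2(cand_a, runs_a, pos, len,
                                    cfg$scrub_background) &&
            !.gene_dirty_run_aware2(cand_b, runs_b, pos, len,
                                    cfg$scrub_background)) {
          runs_a <- shift_runs(runs_a, pos, len)
          runs_b <- shift_runs(runs_b, pos, len)
          codons_a <- cand_a; codons_b <- cand_b
          runs_a[[length(runs_a) + 1L]] <-
            list(amino_acid = aa, start = pos, length = len, shared = TRUE)
          runs_b[[length(runs_b) + 1L]] <-
            list(amino_acid = aa, start = pos, length = len, shared = TRUE)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
  }
  plant_single <- function(codons, runs) {
    aa <- sample(.HP_AA, 1L)
    len <- draw_len()
    aa_seq <- unname(Biostrings::GENETIC_CODE[codons])
    n <- length(codons)
    ok_pos <- which(seq.int(2L, n) >= 2L &
                      aa_seq[seq.int(1L, n - 1L)] != aa &
                      aa_seq[seq.int(2L, n)] != aa) + 1L
    ok_pos <- ok_pos[!vapply(ok_pos, .pos_inside_runs, logical(1),
                             runs = runs)]
    if (!length(ok_pos)) return(list(codons = codons, runs = runs))
    for (pos in .resample(ok_pos, min(20L, length(ok_pos)))) {
      for (try in 1:5) {
        run <- .gen_run_codons(aa, len)
        cand <- append(codons, run, after = pos - 1L)
        if (!.gene_dirty_run_aware2(cand, runs, pos, len,
                                    cfg$scrub_background)) {
          runs <- shift_runs(runs, pos, len)
          runs[[length(runs) + 1L]] <-
            list(amino_acid = aa, start = pos, length = len,
                 shared = FALSE)
          return(list(codons = cand, runs = runs))
        }
      }
    }
    list(codons = codons, runs = runs)
  }
  for (i in seq_len(n_a)) {
    res <- plant_single(codons_a, runs_a)
    codons_a <- res$codons; runs_a <- res$runs
  }
  for (i in seq_len(n_b)) {
    res <- plant_single(codons_b, runs_b)
    codons_b <- res$codons; runs_b <- res$runs
  }
  list(codons_a = codons_a, codons_b = codons_b,
       runs_a = runs_a, runs_b = runs_b)
}

# run-aware cleanliness against a list of already-planted runs plus the
# new candidate run
.gene_dirty_run_aware2 <- function(codons, runs, new_start, new_len,
                                   scrub) {
  if (!scrub) return(FALSE)
  s <- paste(codons, collapse = "")
  v <- strsplit(s, "")[[1L]]
  if (nrow(.naive_scan_tracts(v)) > 0L) return(TRUE)
  if (any(vapply(.ANCHOR8, function(a) grepl(a, s, fixed = TRUE),
                 logical(1)))) return(TRUE)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  r <- rle(aa)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  allowed <- rbind(
    do.call(rbind, lapply(runs, function(x) {
      st <- if (x$start >= new_start) x$start + new_len else x$start
      c(st, x$length)
    })),
    c(new_start, new_len))
  for (h in which(r$lengths >= 6L)) {
    hit <- any(allowed[, 1L] == starts[h] & allowed[, 2L] == r$lengths[h])
    if (!hit) return(TRUE)
  }
  FALSE
}

#' Generate a synthetic paired-genome dataset with recorded truth
#'
#' Emits everything the pipeline consumes -- two genome FASTAs, two GFF3
#' gene sets, protein and CDS FASTAs, a one-to-one ortholog table and a
#' stage-structured expression table -- together with a truth bundle
#' (TSV) recording every planted feature: ortholog pairing and gene
#' classes, rearrangement breakpoints and conserved segments, slippage
#' repeat tracts, homopolymer runs, and DUSE/stem ncRNA loci.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{paths} (named file paths) and
#'   \code{truth} (the truth tables, also written as TSV).
#' @export
generate_dataset <- function(config = sim_config(), dir) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  min_copies <- c(10, 7, 5, 4, rep(3, 16))
  n_uniq <- round(cfg$n_genes * cfg$gene_turnover)
  n_orth <- cfg$n_genes - n_uniq
  pair_a <- sprintf("a_g%03d", seq_len(n_orth))
  pair_b <- sprintf("b_g%03d", seq_len(n_orth))
  uniq_a <- if (n_uniq) sprintf("a_u%03d", seq_len(n_uniq)) else character()
  uniq_b <- if (n_uniq) sprintf("b_u%03d", seq_len(n_uniq)) else character()
  social_orth <- stats::runif(n_orth) < cfg$social_fraction
  # genes unique to a species skew social: rapid social-gene turnover
  social_uniq_a <- stats::runif(n_uniq) < 0.8
  dn_target <- ifelse(social_orth, cfg$dn_high, cfg$dn_low)

  cds_a <- setNames(vector("list", n_orth + n_uniq), c(pair_a, uniq_a))
  cds_b <- setNames(vector("list", n_orth + n_uniq), c(pair_b, uniq_b))
  hp_truth <- list()
  for (i in seq_len(n_orth)) {
    len <- sample(seq.int(cfg$gene_len_codons[1L], cfg$gene_len_codons[2L]),
                  1L)
    ca <- .gen_gene(len, cfg$at_fraction, cfg$scrub_background)
    # substitutions can themselves complete a qualifying repeat in the
    # diverged copy; redraw until the B gene is as clean as the A gene
    repeat {
      cb <- .diverge_codons(ca, dn_target[i], cfg$at_fraction)
      if (!.gene_dirty(cb, cfg$scrub_background)) break
    }
    pl <- .plant_runs_pair(ca, cb, cfg)
    cds_a[[pair_a[i]]] <- pl$codons_a
    cds_b[[pair_b[i]]] <- pl$codons_b
    for (r in pl$runs_a)
      hp_truth[[length(hp_truth) + 1L]] <- data.frame(
        species = "a", protein_id = pair_a[i], amino_acid = r$amino_acid,
        start = r$start, length = r$length, shared = r$shared,
        stringsAsFactors = FALSE)
    for (r in pl$runs_b)
      hp_truth[[length(hp_truth) + 1L]] <- data.frame(
        species = "b", protein_id = pair_b[i], amino_acid = r$amino_acid,
        start = r$start, length = r$length, shared = r$shared,
        stringsAsFactors = FALSE)
  }
  plant_uniq <- function(ids, species) {
    for (id in ids) {
      len <- sample(seq.int(cfg$gene_len_codons[1L],
                            cfg$gene_len_codons[2L]), 1L)
      codons <- .gen_gene(len, cfg$at_fraction, cfg$scrub_background)
      runs <- list()
      for (k in seq_len(stats::rpois(1L, cfg$homopolymer_rate))) {
        aa <- sample(.HP_AA, 1L)
        rl <- 10L + stats::rgeom(1L, 0.3)
        res <- .insert_run(codons, aa, rl, cfg$scrub_background, runs)
        if (!is.null(res)) {
          for (j in seq_along(runs))
            if (runs[[j]]$start >= res$start)
              runs[[j]]$start <- runs[[j]]$start + rl
          codons <- res$codons
          runs[[length(runs) + 1L]] <-
            list(amino_acid = aa, start = res$start, length = rl)
        }
      }
      if (species == "a") cds_a[[id]] <<- codons else cds_b[[id]] <<- codons
      for (r in runs)
        hp_truth[[length(hp_truth) + 1L]] <<- data.frame(
          species = species, protein_id = id, amino_acid = r$amino_acid,
          start = r$start, length = r$length, shared = FALSE,
          stringsAsFactors = FALSE)
    }
  }
  plant_uniq(uniq_a, "a")
  plant_uniq(uniq_b, "b")

  # gene orders
  plan <- .plan_rearrangement(n_orth, cfg$rearrangement_ops)
  order_a <- pair_a
  order_b <- pair_b[plan$order]
  insert_at <- function(base, extra) {
    out <- base
    for (e in extra) {
      pos <- sample(length(out) + 1L, 1L)
      out <- append(out, e, after = pos - 1L)
    }
    out
  }
  full_a <- insert_at(order_a, uniq_a)
  full_b <- insert_at(order_b, uniq_b)
  chunks_a <- .chunk(full_a, cfg$n_scaffolds_a)
  chunks_b <- .chunk(full_b, cfg$n_scaffolds_b)

  strand_a <- setNames(sample(c("+", "-"), length(full_a), TRUE), full_a)
  strand_b <- setNames(sample(c("+", "-"), length(full_b), TRUE), full_b)
  oriented <- function(codons, strand) {
    s <- paste(codons, collapse = "")
    if (strand == "-") .revcomp(s) else s
  }

  # distribute ncRNA loci across genome-A scaffolds
  classes <- sample(c("classI", "classII", "putative"), cfg$n_ncrna_loci,
                    replace = TRUE, prob = c(0.5, 0.2, 0.3))
  loci_scaffold <- sample(length(chunks_a), cfg$n_ncrna_loci,
                          replace = TRUE)

  build_genome <- function(chunks, cds_list, strands, species) {
    seqs <- character(length(chunks))
    names(seqs) <- if (species == "a")
      paste0("scaffold_", seq_along(chunks)) else
      paste0("chr_", seq_along(chunks))
    genes <- list(); tracts <- list(); ncrnas <- list()
    for (s in seq_along(chunks)) {
      ids <- chunks[[s]]
      gene_df <- data.frame(
        gene_id = ids,
        seq = vapply(ids, function(g)
          oriented(cds_list[[g]], strands[[g]]), character(1)),
        strand = unname(strands[ids]), stringsAsFactors = FALSE)
      ncc <- if (species == "a") classes[loci_scaffold == s] else character()
      asm <- .assemble_scaffold(names(seqs)[s], gene_df, cfg,
                                plant_tracts = (species == "a"),
                                ncrna_classes = ncc,
                                min_copies = min_copies)
      seqs[s] <- asm$seq
      genes[[s]] <- asm$genes
      tracts[[s]] <- asm$tracts
      ncrnas[[s]] <- asm$ncrna
    }
    list(seqs = seqs, genes = do.call(rbind, genes),
         tracts = do.call(rbind, tracts),
         ncrna = do.call(rbind, ncrnas))
  }
  ga <- build_genome(chunks_a, cds_a, strand_a, "a")
  gb <- build_genome(chunks_b, cds_b, strand_b, "b")

  models_a <- gene_models(ga$genes,
                          data.frame(gene_id = ga$genes$gene_id,
                                     start = ga$genes$start,
                                     end = ga$genes$end,
                                     stringsAsFactors = FALSE))
  models_b <- gene_models(gb$genes,
                          data.frame(gene_id = gb$genes$gene_id,
                                     start = gb$genes$start,
                                     end = gb$genes$end,
                                     stringsAsFactors = FALSE))
  orthologs <- data.frame(gene_a = pair_a, gene_b = pair_b,
                          relation = "one_to_one",
                          stringsAsFactors = FALSE)

  expr_genes <- c(pair_a, uniq_a)
  expr_social <- c(social_orth, social_uniq_a)
  expression <- .simulate_expression(expr_genes, expr_social, cfg)

  # conserved-adjacency truth from the realized layouts
  restricted <- function(genes_df, keep) {
    g <- genes_df[genes_df$gene_id %in% keep, ]
    g <- g[order(g$scaffold_id, g$start), ]
    g$pos <- stats::ave(seq_len(nrow(g)), g$scaffold_id, FUN = seq_along)
    g
  }
  ra <- restricted(ga$genes, pair_a)
  rb <- restricted(gb$genes, pair_b)
  pair_of <- setNames(seq_len(n_orth), pair_a)
  adj <- NULL
  if (n_orth >= 2L) {
    scaf_a <- setNames(ra$scaffold_id, ra$gene_id)
    pos_a <- setNames(ra$pos, ra$gene_id)
    scaf_b <- setNames(rb$scaffold_id, rb$gene_id)
    pos_b <- setNames(rb$pos, rb$gene_id)
    i <- seq_len(n_orth - 1L)
    a1 <- pair_a[i]; a2 <- pair_a[i + 1L]
    b1 <- pair_b[i]; b2 <- pair_b[i + 1L]
    preserved <- scaf_a[a1] == scaf_a[a2] &
      abs(pos_a[a1] - pos_a[a2]) == 1L &
      scaf_b[b1] == scaf_b[b2] &
      abs(pos_b[b1] - pos_b[b2]) == 1L
    adj <- data.frame(pair_i = i, pair_j = i + 1L,
                      preserved = unname(preserved))
  }

  truth <- list(
    genes = data.frame(
      gene_id = c(pair_a, uniq_a, pair_b, uniq_b),
      species = c(rep("a", n_orth + n_uniq), rep("b", n_orth + n_uniq)),
      partner = c(pair_b, rep(NA, n_uniq), pair_a, rep(NA, n_uniq)),
      class = c(ifelse(social_orth, "social", "vegetative"),
                ifelse(social_uniq_a, "social", "vegetative"),
                ifelse(social_orth, "social", "vegetative"),
                rep(NA, n_uniq)),
      dn_class = c(ifelse(social_orth, "high", "low"), rep(NA, n_uniq),
                   ifelse(social_orth, "high", "low"), rep(NA, n_uniq)),
      dn_target = c(dn_target, rep(NA, n_uniq), dn_target,
                    rep(NA, n_uniq)),
      stringsAsFactors = FALSE),
    repeats = ga$tracts,
    homopolymers = if (length(hp_truth)) do.call(rbind, hp_truth) else
      data.frame(species = character(), protein_id = character(),
                 amino_acid = character(), start = integer(),
                 length = integer(), shared = logical()),
    ncrna = ga$ncrna,
    rearrangement_cuts = plan$cuts,
    adjacency = adj,
    config = cfg)

  # write files
  p <- function(f) file.path(dir, f)
  genome_a <- Biostrings::DNAStringSet(ga$seqs)
  genome_b <- Biostrings::DNAStringSet(gb$seqs)
  Biostrings::writeXStringSet(genome_a, p("genome_a.fasta"))
  Biostrings::writeXStringSet(genome_b, p("genome_b.fasta"))
  write_gff3(models_a, p("genes_a.gff3"))
  write_gff3(models_b, p("genes_b.gff3"))
  cds_chr_a <- vapply(cds_a, paste, character(1), collapse = "")
  cds_chr_b <- vapply(cds_b, paste, character(1), collapse = "")
  prot_a <- vapply(cds_a, .protein_of, character(1))
  prot_b <- vapply(cds_b, .protein_of, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds_chr_a),
                              p("cds_a.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds_chr_b),
                              p("cds_b.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot_a),
                              p("proteins_a.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot_b),
                              p("proteins_b.fasta"))
  write_ortholog_table(orthologs, p("orthologs.tsv"))
  utils::write.table(expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t",
                                           quote = FALSE,
                                           row.names = FALSE)
  wt(truth$genes, "truth_genes.tsv")
  wt(truth$repeats, "truth_repeats.tsv")
  wt(truth$homopolymers, "truth_homopolymers.tsv")
  wt(truth$ncrna, "truth_ncrna.tsv")
  if (!is.null(adj)) wt(adj, "truth_adjacency.tsv")
  writeLines(c(
    "Synthetic paired-genome dataset with planted ground truth.",
    sprintf("seed: %d", cfg$seed),
    sprintf("genes per genome: %d (%d orthologous, %d unique)",
            cfg$n_genes, n_orth, n_uniq),
    sprintf("target A+T fraction: %.3f", cfg$at_fraction),
    sprintf("rearrangement breakpoints: %d", cfg$rearrangement_ops),
    sprintf("planted repeat tracts: %d", nrow(truth$repeats)),
    sprintf("planted homopolymer runs: %d", nrow(truth$homopolymers)),
    sprintf("planted ncRNA loci: %d", nrow(truth$ncrna))),
    p("truth_summary.txt"))
  paths <- c(genome_a = p("genome_a.fasta"), genome_b = p("genome_b.fasta"),
             gff_a = p("genes_a.gff3"), gff_b = p("genes_b.gff3"),
             cds_a = p("cds_a.fasta"), cds_b = p("cds_b.fasta"),
             proteins_a = p("proteins_a.fasta"),
             proteins_b = p("proteins_b.fasta"),
             orthologs = p("orthologs.tsv"),
             expression = p("expression.tsv"))
  invisible(list(paths = paths, truth = truth))
}

#' Verify a generated dataset against its truth record
#'
#' Independently re-parses the emitted files and checks every truth entry:
#' gene membership and pairing, CDS extraction and translation
#' consistency, repeat tract sequence and maximality, homopolymer run
#' placement, ncRNA locus structure (DUSE, stems, separation), expression
#' completeness, and broken/preserved ortholog adjacencies.
#'
#' @param paths Named file paths as returned by
#'   \code{\link{generate_dataset}}.
#' @param truth Truth record as returned by \code{\link{generate_dataset}}.
#' @return list: \code{pass} (logical) and \code{failures} (character;
#'   first discrepancies found).
#' @export
truth_check <- function(paths, truth) {
  fails <- character()
  add <- function(msg) fails <<- c(fails, msg)
  genome_a <- read_genome_fasta(paths[["genome_a"]])
  genome_b <- read_genome_fasta(paths[["genome_b"]])
  models_a <- read_gff3(paths[["gff_a"]], genome_a)
  models_b <- read_gff3(paths[["gff_b"]], genome_b)
  cds_a <- read_seq_fasta(paths[["cds_a"]], "DNA")
  cds_b <- read_seq_fasta(paths[["cds_b"]], "DNA")
  prot_a <- read_seq_fasta(paths[["proteins_a"]], "AA")
  prot_b <- read_seq_fasta(paths[["proteins_b"]], "AA")
  orth <- read_ortholog_table(paths[["orthologs"]])
  expr <- utils::read.delim(paths[["expression"]])

  tg <- truth$genes
  ids_a <- tg$gene_id[tg$species == "a"]
  ids_b <- tg$gene_id[tg$species == "b"]
  if (!setequal(ids_a, models_a$genes$gene_id))
    add("genome A gene ids disagree with truth")
  if (!setequal(ids_b, models_b$genes$gene_id))
    add("genome B gene ids disagree with truth")
  want_pairs <- tg[tg$species == "a" & !is.na(tg$partner),
                   c("gene_id", "partner")]
  if (!identical(sort(paste(orth$gene_a, orth$gene_b)),
                 sort(paste(want_pairs$gene_id, want_pairs$partner))))
    add("ortholog table disagrees with truth pairing")

  # CDS extraction and translation
  for (g in models_a$genes$gene_id) {
    s <- extract_cds(genome_a, models_a, g)
    if (s != as.character(cds_a[[g]])) {
      add(paste0("extracted CDS mismatch for ", g)); break
    }
    if (.translate_cds(s) != as.character(prot_a[[g]])) {
      add(paste0("translation mismatch for ", g)); break
    }
  }
  for (g in models_b$genes$gene_id) {
    s <- extract_cds(genome_b, models_b, g)
    if (s != as.character(cds_b[[g]])) {
      add(paste0("extracted CDS mismatch for ", g)); break
    }
  }

  # repeat tracts: sequence content and maximality
  chars_a <- lapply(as.character(genome_a), function(s)
    strsplit(s, "")[[1L]])
  tr <- truth$repeats
  for (i in seq_len(nrow(tr))) {
    v <- chars_a[[tr$scaffold_id[i]]]
    st <- tr$start[i]; k <- tr$unit_length[i]; len <- tr$length[i]
    seg <- v[seq.int(st, st + len - 1L)]
    if (!all(seg == rep_len(seg[seq_len(k)], len))) {
      add(paste0("repeat tract content mismatch at ", tr$scaffold_id[i],
                 ":", st)); break
    }
    if (st > 1L && v[st - 1L] == seg[k]) {
      add(paste0("repeat tract not left-maximal at ", st)); break
    }
    if (st + len <= length(v) && v[st + len] == seg[1L]) {
      add(paste0("repeat tract not right-maximal at ", st)); break
    }
  }

  # homopolymer runs
  th <- truth$homopolymers
  for (i in seq_len(nrow(th))) {
    prot <- if (th$species[i] == "a") prot_a else prot_b
    s <- as.character(prot[[th$protein_id[i]]])
    run <- substr(s, th$start[i], th$start[i] + th$length[i] - 1L)
    if (run != strrep(th$amino_acid[i], th$length[i])) {
      add(paste0("homopolymer content mismatch in ", th$protein_id[i]))
      break
    }
    before <- if (th$start[i] > 1L)
      substr(s, th$start[i] - 1L, th$start[i] - 1L) else ""
    after_pos <- th$start[i] + th$length[i]
    after <- if (after_pos <= nchar(s))
      substr(s, after_pos, after_pos) else ""
    if (before == th$amino_acid[i] || after == th$amino_acid[i]) {
      add(paste0("homopolymer not maximal in ", th$protein_id[i]))
      break
    }
  }

  # ncRNA loci
  tn <- truth$ncrna
  for (i in seq_len(nrow(tn))) {
    s <- as.character(genome_a[[tn$scaffold_id[i]]])
    duse <- substr(s, tn$duse_start[i], tn$duse_start[i] + 7L)
    if (!grepl(paste0("^", .duse_regex, "$"), duse)) {
      add(paste0("planted DUSE mismatch at ", tn$duse_start[i])); break
    }
    st5 <- substr(s, tn$stem5_start[i], tn$stem5_start[i] + 4L)
    st3 <- substr(s, tn$stem3_start[i], tn$stem3_start[i] + 4L)
    if (st5 != tn$stem5[i] || st3 != .revcomp(st5)) {
      add(paste0("planted stem mismatch at ", tn$stem5_start[i])); break
    }
    sep <- tn$stem3_start[i] - (tn$stem5_start[i] + 5L)
    if (sep != tn$separation[i] || sep < 40L || sep > 70L) {
      add(paste0("planted stem separation out of bounds at ",
                 tn$stem5_start[i])); break
    }
    bulge <- substr(s, tn$stem5_start[i] + 5L, tn$stem5_start[i] + 16L)
    if (bulge != "CCTTACAGCCAA") {
      add(paste0("planted bulge mismatch at ", tn$stem5_start[i])); break
    }
  }

  # expression completeness
  expr_ids <- unique(expr$gene_id)
  need_ids <- tg$gene_id[tg$species == "a"]
  if (!all(need_ids %in% expr_ids))
    add("expression rows missing for some genome A genes")
  cnt <- table(expr$gene_id)
  if (length(cnt) && any(cnt != 7L))
    add("expression table does not have 7 libraries per gene")

  # adjacency truth against realized orders
  if (!is.null(truth$adjacency)) {
    map <- ordered_ortholog_map(models_a, models_b, orth)
    pa <- setNames(seq_len(nrow(truth$adjacency) + 1L),
                   sort(orth$gene_a))
    pos_a <- setNames(map$pos_a, map$gene_a)
    scf_a <- setNames(map$scaffold_a, map$gene_a)
    pos_b <- setNames(map$pos_b, map$gene_a)
    scf_b <- setNames(map$chrom_b, map$gene_a)
    ta <- truth$adjacency
    ids <- sort(orth$gene_a)
    obs <- scf_a[ids[ta$pair_i]] == scf_a[ids[ta$pair_j]] &
      abs(pos_a[ids[ta$pair_i]] - pos_a[ids[ta$pair_j]]) == 1L &
      scf_b[ids[ta$pair_i]] == scf_b[ids[ta$pair_j]] &
      abs(pos_b[ids[ta$pair_i]] - pos_b[ids[ta$pair_j]]) == 1L
    if (!all(unname(obs) == ta$preserved))
      add("adjacency truth disagrees with realized gene orders")
  }

  list(pass = length(fails) == 0L, failures = fails)
}

#' Simulate ortholog CDS pairs plus expression without writing files
#'
#' The light-weight path used for repeated simulations (e.g. checking
#' that a planted positive dN-vs-social-index relationship is
#' recovered): ortholog codon pairs diverged to their class targets and
#' a matching expression table, without genome assembly or homopolymer
#' planting.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param config A \code{\link{sim_config}}.
#' @param seed Seed (defaults to the config seed).
#' @return list: \code{pairs} data.frame (\code{gene_id}, \code{social},
#'   \code{dn_target}, \code{cds_a}, \code{cds_b}) and \code{expression}
#'   (long-format table for \code{\link{expression_profiles}}).
#' @export
simulate_pairs <- function(n_pairs, config = sim_config(),
                           seed = config$seed) {
  cfg <- config
  set.seed(seed)
  social <- stats::runif(n_pairs) < cfg$social_fraction
  dn_target <- ifelse(social, cfg$dn_high, cfg$dn_low)
  ids <- sprintf("g%04d", seq_len(n_pairs))
  cds_a <- character(n_pairs); cds_b <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    len <- sample(seq.int(cfg$gene_len_codons[1L],
                          cfg$gene_len_codons[2L]), 1L)
    ca <- .gen_codons(len, cfg$at_fraction)
    cb <- .diverge_codons(ca, dn_target[i], cfg$at_fraction)
    cds_a[i] <- paste(ca, collapse = "")
    cds_b[i] <- paste(cb, collapse = "")
  }
  expr <- .simulate_expression(ids, social, cfg)
  list(pairs = data.frame(gene_id = ids, social = social,
                          dn_target = dn_target, cds_a = cds_a,
                          cds_b = cds_b, stringsAsFactors = FALSE),
       expression = expr)
}
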