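# Social/gamete expression indices, QC filtering, and the regressions and
# rank tests relating expression to molecular evolution.

#' Build expression profiles from a long count table
#'
#' Expects one row per gene x library with columns \code{gene_id},
#' \code{library} (\code{veg} or \code{h<time>} for the social time
#' points), \code{count}, and optionally \code{pct} (percentage
#' representation within the library, computed from counts when absent).
#'
#' @param tab Long-format data.frame (e.g. a read-in expression TSV).
#' @return data.frame: \code{gene_id}, \code{vegetative_pct}, one
#'   \code{pct_h*} column per social time point, \code{total_reads}.
#' @export
expression_profiles <- function(tab) {
  stopifnot(all(c("gene_id", "library", "count") %in% names(tab)))
  if (!"pct" %in% names(tab)) {
    lib_tot <- tapply(tab$count, tab$library, sum)
    tab$pct <- tab$count / pmax(as.numeric(lib_tot[tab$library]), 1) * 100
  }
  libs <- unique(tab$library)
  soc_libs <- sort(setdiff(libs, "veg"))
  genes <- unique(tab$gene_id)
  wide <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  get_pct <- function(lib) {
    sub <- tab[tab$library == lib, ]
    out <- setNames(sub$pct, sub$gene_id)[genes]
    ifelse(is.na(out), 0, out)
  }
  wide$vegetative_pct <- get_pct("veg")
  for (lib in soc_libs) wide[[paste0("pct_", lib)]] <- get_pct(lib)
  tot <- tapply(tab$count, tab$gene_id, sum)
  wide$total_reads <- as.numeric(tot[genes])
  wide
}

#' Quality-filter expression profiles
#'
#' A gene passes QC with sufficient reads (total across libraries) and,
#' when replicate counts are available, reproducible replicates
#' (correlation of the per-library counts between replicates).
#'
#' @param profiles data.frame from \code{\link{expression_profiles}}.
#' @param min_total Minimum summed reads (default 20).
#' @param min_reproducibility Minimum replicate correlation (default
#'   0.8).
#' @param replicate_counts Optional matrix pair: a list of two gene x
#'   library count matrices (same dimnames) from replicate library sets.
#' @return \code{profiles} with a logical \code{qc_pass} column.
#' @export
qc_filter <- function(profiles, min_total = 20,
                      min_reproducibility = 0.8,
                      replicate_counts = NULL) {
  pass <- profiles$total_reads >= min_total
  if (!is.null(replicate_counts)) {
    stopifnot(length(replicate_counts) == 2L)
    m1 <- replicate_counts[[1L]]; m2 <- replicate_counts[[2L]]
    stopifnot(identical(dimnames(m1), dimnames(m2)))
    rep_cor <- vapply(profiles$gene_id, function(g) {
      if (!g %in% rownames(m1)) return(NA_real_)
      a <- m1[g, ]; b <- m2[g, ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      stats::cor(a, b)
    }, numeric(1))
    pass <- pass & (is.na(rep_cor) | rep_cor >= min_reproducibility)
  }
  profiles$qc_pass <- pass
  profiles
}

#' Social expression index
#'
#' S / (S + V): the mean percentage representation across the social-stage
#' libraries over that mean plus the vegetative percentage
#' representation. 1 means purely social expression, 0 purely
#' vegetative. Genes with no signal in either term are excluded with a
#' flag (index NA).
#'
#' @param profiles data.frame from \code{\link{expression_profiles}}
#'   (after \code{\link{qc_filter}} only \code{qc_pass} genes are used
#'   when the column is present).
#' @return data.frame: \code{gene_id}, \code{index}, \code{defined}.
#' @export
social_index <- function(profiles) {
  if ("qc_pass" %in% names(profiles))
    profiles <- profiles[profiles$qc_pass, , drop = FALSE]
  soc_cols <- grep("^pct_", names(profiles), value = TRUE)
  if (!length(soc_cols)) stop("no social-stage percentage columns")
  S <- rowMeans(profiles[, soc_cols, drop = FALSE])
  V <- profiles$vegetative_pct
  defined <- (S + V) > 0
  data.frame(gene_id = profiles$gene_id,
             index = ifelse(defined, S / (S + V), NA_real_),
             defined = defined, stringsAsFactors = FALSE)
}

#' Gamete expression index
#'
#' Same functional form as the social index with gamete-library counts in
#' place of social-stage expression: gamete / (gamete + vegetative).
#'
#' @param gamete,vegetative Non-negative per-gene EST/read counts.
#' @return Numeric index in [0, 1]; NA (excluded) where both are zero.
#' @export
gamete_index <- function(gamete, vegetative) {
  stopifnot(length(gamete) == length(vegetative),
            all(gamete >= 0), all(vegetative >= 0))
  tot <- gamete + vegetative
  ifelse(tot > 0, gamete / tot, NA_real_)
}

#' Regress a per-gene statistic on an expression index
#'
#' Ordinary least squares of e.g. dN or conservation score on the social
#' (or gamete) index, with the two-sided slope test.
#'
#' @param values Per-gene statistic.
#' @param indices Per-gene index (same length).
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p}, \code{n}.
#' @export
regress_on_index <- function(values, indices) {
  stopifnot(length(values) == length(indices))
  keep <- !is.na(values) & !is.na(indices)
  values <- values[keep]; indices <- indices[keep]
  if (length(values) < 10L)
    stop("need at least 10 paired observations")
  if (stats::sd(indices) == 0)
    stop("indices have zero variance")
  fit <- stats::lm(values ~ indices)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2L, 4L],
       n = length(values))
}

#' Compare expression indices of genes with and without orthologs
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie
#' correction) of the index between genes that have a partner in the
#' other species and genes that do not.
#'
#' @param indices Per-gene index.
#' @param has_ortholog Logical per-gene flag.
#' @return list: group \code{n}, \code{medians}, \code{p}.
#' @export
ortholog_presence_vs_index <- function(indices, has_ortholog) {
  stopifnot(length(indices) == length(has_ortholog))
  keep <- !is.na(indices)
  indices <- indices[keep]; has_ortholog <- has_ortholog[keep]
  g1 <- indices[has_ortholog]; g0 <- indices[!has_ortholog]
  if (!length(g1) || !length(g0)) stop("both groups must be non-empty")
  wt <- stats::wilcox.test(g1, g0, exact = FALSE, correct = TRUE)
  list(n = c(with_ortholog = length(g1), without_ortholog = length(g0)),
       medians = c(with_ortholog = stats::median(g1),
                   without_ortholog = stats::median(g0)),
       p = wt$p.value)
}
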