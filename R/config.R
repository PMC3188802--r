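#' Pipeline run configuration
#'
#' A flat key-value configuration covering every stage, with the package
#' defaults. Unknown keys are rejected so typos cannot silently fall back
#' to defaults. The seed is carried into every stochastic stage and
#' recorded in outputs.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A named list of class \code{run_config}.
#'
#' @section Defaults:
#' \describe{
#'   \item{ssr_min_copies}{Minimum whole copies per unit length 1..20:
#'     10, 7, 5, 4, then 3 for lengths 5-20.}
#'   \item{ssr_summed_bp}{Report genome fraction as summed tract bp
#'     instead of union bp (default \code{FALSE}).}
#'   \item{aa_alpha}{Significance level for homopolymer chance thresholds
#'     (0.01).}
#'   \item{align_substitution, align_gap_open, align_gap_extend}{Global
#'     protein alignment scoring (BLOSUM62, 11, 1).}
#'   \item{homology_min_overlap}{Minimum shared aligned columns for a
#'     repeat-homology call (1).}
#'   \item{synteny_w_max, synteny_n_perm, synteny_k_sd}{Window-selection
#'     scan limit (20), permutation count (100), growth-significance rule
#'     in null SDs (2).}
#'   \item{synteny_strict_order, synteny_whole_genome_shuffle}{Optional
#'     strict-order linkage and whole-genome scramble modes (both
#'     \code{FALSE}).}
#'   \item{duse_pattern}{IUPAC DUSE motif, \code{WCCCAWAA}.}
#'   \item{ncrna_k}{Anchor k-mer length (8).}
#'   \item{duse_window}{DUSE start must lie this many bp upstream of the
#'     anchor: \code{c(40, 90)}, encompassing the canonical ~63 bp.}
#'   \item{stem_len, stem_sep, stem5_offset}{Stem length (5), stem
#'     separation bounds \code{c(40, 70)} bp, and how far upstream of the
#'     anchor the 5' stem may begin (15 bp).}
#'   \item{bulge_pattern}{The NSBR bulge, \code{CCTTACAGCCAA}.}
#'   \item{qc_min_total, qc_min_reproducibility}{Expression QC: minimum
#'     summed reads (20) and replicate correlation (0.8).}
#'   \item{seed}{Integer seed (1).}
#' }
#' @export
run_config <- function(...) {
  defaults <- list(
    ssr_min_copies = c(10, 7, 5, 4, rep(3, 16)),
    ssr_summed_bp = FALSE,
    aa_alpha = 0.01,
    align_substitution = "BLOSUM62",
    align_gap_open = 11,
    align_gap_extend = 1,
    homology_min_overlap = 1,
    synteny_w_max = 20L,
    synteny_n_perm = 100L,
    synteny_k_sd = 2,
    synteny_strict_order = FALSE,
    synteny_whole_genome_shuffle = FALSE,
    duse_pattern = "WCCCAWAA",
    ncrna_k = 8L,
    duse_window = c(40L, 90L),
    stem_len = 5L,
    stem_sep = c(40L, 70L),
    stem5_offset = 15L,
    bulge_pattern = "CCTTACAGCCAA",
    qc_min_total = 20,
    qc_min_reproducibility = 0.8,
    seed = 1L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(length(cfg$ssr_min_copies) == 20L, all(cfg$ssr_min_copies >= 1))
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from a flat YAML file
#' @param path YAML path with keys from \code{\link{run_config}}.
#' @return A \code{run_config}.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configuration requires the 'yaml' package")
  stopifnot(file.exists(path))
  run_config(yaml::read_yaml(path))
}

#' Write a provenance block for a run
#'
#' Records parameters, seed and input checksums next to the outputs, so
#' stochastic stages can be re-run exactly.
#'
#' @param cfg A \code{run_config} (or \code{sim_config}).
#' @param inputs Named character vector of input file paths (may be empty).
#' @param path Output path for the provenance file.
#' @return \code{path}, invisibly.
#' @export
write_provenance <- function(cfg, inputs, path) {
  lines <- c(sprintf("package: dictycomp %s",
                     as.character(utils::packageVersion("dictycomp"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             "parameters:",
             vapply(names(cfg), function(k)
               sprintf("  %s: %s", k, paste(cfg[[k]], collapse = ",")),
               character(1)))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, "inputs:",
               sprintf("  %s: %s", basename(inputs), unname(sums)))
  }
  writeLines(lines, path)
  invisible(path)
}
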