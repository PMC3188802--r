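# Independent oracle implementations used to cross-check the package's
# detectors. These deliberately use different algorithms from the
# implementation: per-position greedy extension for repeats, recursive
# path enumeration for substitution counting, exhaustive column-by-column
# enumeration for alignment, and a BFS on an explicit link matrix for
# synteny clustering.

# -- brute-force SSR scanner -------------------------------------------------

oracle_ssr_scan <- function(seq, min_copies = c(10, 7, 5, 4, rep(3, 16))) {
  v <- strsplit(toupper(seq), "")[[1L]]
  n <- length(v)
  rot_min <- function(u) {
    k <- length(u)
    min(vapply(0:(k - 1L), function(r)
      paste(c(u[seq_len(k) > r], u[seq_len(r)]), collapse = ""),
      character(1)))
  }
  primitive <- function(u) {
    k <- length(u)
    if (k == 1L) return(TRUE)
    for (d in seq_len(k - 1L)) {
      if (k %% d == 0L && all(u == rep(u[seq_len(d)], length.out = k)))
        return(FALSE)
    }
    TRUE
  }
  res <- list()
  for (k in 1:20) {
    i <- 1L
    while (i + min_copies[k] * k - 1L <= n) {
      # left-maximality: no period-k continuation into position i-1
      if (i > 1L && v[i - 1L] != "N" && v[i - 1L] == v[i - 1L + k]) {
        i <- i + 1L; next
      }
      unit <- v[seq.int(i, i + k - 1L)]
      if (any(unit == "N")) { i <- i + 1L; next }
      j <- i + k
      while (j <= n && v[j] != "N" && v[j] == v[j - k]) j <- j + 1L
      total <- j - i
      if (total %/% k >= min_copies[k] && primitive(unit)) {
        res[[length(res) + 1L]] <- data.frame(
          start = i, end = i + total - 1L, unit_length = k,
          unit = rot_min(unit), copies = total / k,
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      unit_length = integer(), unit = character(),
                      copies = numeric(), stringsAsFactors = FALSE)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# -- Nei-Gojobori path-enumeration oracle ------------------------------------

oracle_ng <- local({
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- function(codon) unname(gc_tab[codon])
  # recursive enumeration of substitution paths avoiding stops
  enum_paths <- function(from, to) {
    d <- which(strsplit(from, "")[[1L]] != strsplit(to, "")[[1L]])
    if (!length(d)) return(list(list(syn = 0, nonsyn = 0, ok = TRUE)))
    out <- list()
    for (pos in d) {
      v <- strsplit(from, "")[[1L]]
      v[pos] <- strsplit(to, "")[[1L]][pos]
      mid <- paste(v, collapse = "")
      step_syn <- as.numeric(aa(mid) != "*" && aa(mid) == aa(from))
      step_non <- as.numeric(aa(mid) == "*" || aa(mid) != aa(from))
      ok_step <- aa(mid) != "*"
      for (rest in enum_paths(mid, to)) {
        out[[length(out) + 1L]] <- list(
          syn = step_syn + rest$syn,
          nonsyn = step_non + rest$nonsyn,
          ok = ok_step && rest$ok)
      }
    }
    out
  }
  function(c1, c2) {
    paths <- enum_paths(c1, c2)
    ok <- vapply(paths, `[[`, logical(1), "ok")
    use <- if (any(ok)) paths[ok] else paths
    c(Sd = mean(vapply(use, `[[`, numeric(1), "syn")),
      Nd = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
  }
})

oracle_ng_sites <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  v <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), v[pos])) {
      w <- v; w[pos] <- b
      alt <- paste(w, collapse = "")
      if (gc_tab[alt] != "*" && gc_tab[alt] == gc_tab[codon])
        s <- s + 1 / 3
    }
  }
  s
}

# -- exhaustive global-alignment score oracle --------------------------------

oracle_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  va <- strsplit(a, "")[[1L]]; vb <- strsplit(b, "")[[1L]]
  # enumerate every alignment recursively, tracking the previous move
  # for affine gap costs: gap of length L costs gap_open + L * gap_extend
  rec <- function(i, j, prev) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      best <- max(best, mat[va[i], vb[j]] + rec(i + 1L, j + 1L, "m"))
    }
    if (i <= length(va)) {
      cost <- gap_extend + if (prev == "ga") 0 else gap_open
      best <- max(best, -cost + rec(i + 1L, j, "ga"))
    }
    if (j <= length(vb)) {
      cost <- gap_extend + if (prev == "gb") 0 else gap_open
      best <- max(best, -cost + rec(i, j + 1L, "gb"))
    }
    best
  }
  rec(1L, 1L, "m")
}

# -- connected-components oracle for synteny blocks --------------------------

oracle_blocks <- function(map, w) {
  n <- nrow(map)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      link[i, j] <- map$scaffold_a[i] == map$scaffold_a[j] &&
        map$chrom_b[i] == map$chrom_b[j] &&
        abs(map$pos_a[i] - map$pos_a[j]) <= w + 1L &&
        abs(map$pos_b[i] - map$pos_b[j]) <= w + 1L
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      x <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[x])) next
      comp[x] <- cid
      queue <- c(queue, which(link[x, ] & is.na(comp)))
    }
  }
  sizes <- table(comp)
  in_block <- sizes[as.character(comp)] >= 2L
  list(membership = comp, in_block = as.vector(in_block),
       participation = mean(in_block),
       n_blocks = sum(sizes >= 2L))
}
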