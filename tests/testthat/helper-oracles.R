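# Independent oracles used across the suite. These deliberately avoid the
# package's search code paths: the enumerator walks every legal structure,
# the seed oracle checks complementarity base by base, and the intron oracle
# marks positions in a logical mask.

# Exhaustive enumeration of all single-hairpin structures (chains of nested
# pairs, terminal loop >= min_loop), scored with structure_energy(). Returns
# the minimum energy over all structures including the empty one.
enumerate_min_energy <- function(seq, model = default_energy_model()) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  ml <- model$min_loop
  best <- 0
  pairable <- function(i, j) {
    paste0(s[i], s[j]) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  rec <- function(lo, hi, chain) {
    if (lo > hi - ml - 1) return(invisible())
    for (i in lo:(hi - ml - 1)) {
      for (j in (i + ml + 1):hi) {
        if (!pairable(i, j)) next
        ch2 <- rbind(chain, c(i, j))
        e <- structure_energy(seq, ch2, model)
        if (is.finite(e)) {
          if (e < best) best <<- e
          rec(i + 1, j - 1, ch2)
        }
      }
    }
  }
  rec(1, n, matrix(integer(0), 0, 2))
  best
}

# Brute-force seed-site scan: slide over every region position and test each
# class definition by direct base comparison.
brute_seed_sites <- function(mature, region, min_class = "7mer-m8") {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  m <- strsplit(mature, "")[[1]]
  r <- strsplit(region, "")[[1]]
  n <- length(r)
  rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  out <- NULL
  for (k in seq_len(n - 5)) {
    core <- TRUE
    for (p in 2:7) { # region position k+7-p pairs mature position p
      t <- k + 7 - p
      if (t > n || r[t] != comp[m[p]]) { core <- FALSE; break }
    }
    if (!core) next
    has_m8 <- k > 1 && r[k - 1] == comp[m[8]]
    has_a1 <- k + 6 <= n && r[k + 6] == "A"
    cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
           else if (has_a1) "7mer-A1" else "6mer"
    if (rank[cls] < rank[min_class]) next
    out <- rbind(out, data.frame(
      start = if (has_m8) k - 1 else k,
      end = if (has_a1) k + 6 else k + 5,
      site_class = cls))
  }
  out
}

# Set-complement oracle for intron derivation: mark exonic positions, then
# read off maximal unmarked runs strictly between exons.
brute_introns <- function(exons, locus_length) {
  mask <- rep(FALSE, locus_length)
  for (k in seq_len(nrow(exons))) mask[exons$start[k]:exons$end[k]] <- TRUE
  lo <- min(exons$start); hi <- max(exons$end)
  runs <- rle(mask[lo:hi])
  pos <- lo
  out <- NULL
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) {
      out <- rbind(out, data.frame(start = pos,
                                   end = pos + runs$lengths[k] - 1))
    }
    pos <- pos + runs$lengths[k]
  }
  out
}

# Non-overlapping random exon models for property tests.
random_exon_model <- function(n_exons, locus_length) {
  bounds <- sort(sample(seq_len(locus_length - 1), 2 * n_exons))
  starts <- bounds[seq(1, 2 * n_exons, by = 2)]
  ends <- bounds[seq(2, 2 * n_exons, by = 2)]
  # guarantee gaps between consecutive exons
  keep <- c(TRUE, starts[-1] > ends[-n_exons] + 1)
  tibble::tibble(start = starts, end = ends)[keep, ]
}

random_rna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = p),
        collapse = "")
}

premir1_seq <- function() plaur_precursors()$sequence[1]
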