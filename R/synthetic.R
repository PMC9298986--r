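#' Specification of a planted hairpin
#'
#' Describes a synthetic stem-loop to embed in a locus: a perfect stem of
#' `stem_length` base pairs (a chosen fraction converted to GU wobbles), a
#' terminal loop, and optionally planted microprocessor motifs. With
#' `motifs`, the generator plants a basal `UG` 13 nt upstream of the
#' intended 5p cleavage site, a `GUG` in the loop, a `GHG` bulge is emulated
#' by leaving the stem perfect (the motif letters are placed on the 3'
#' strand), and a `CNNC` 17 nt downstream of the intended 3p cut.
#'
#' @param stem_length Stem length in base pairs (>= 8).
#' @param loop_length Terminal loop length in nt (>= 3).
#' @param gu_fraction Fraction of stem pairs converted to GU wobbles.
#' @param motifs Subset of `c("basal_ug", "apical", "cnnc")` to plant.
#' @param intron_index Intron (transcript order) to plant into.
#' @param mature_length Intended mature length (controls motif placement).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(stem_length = 25L, loop_length = 5L,
                       gu_fraction = 0.1,
                       motifs = c("basal_ug", "apical"),
                       intron_index = 1L, mature_length = 22L) {
  stopifnot(stem_length >= 8, loop_length >= 3,
            gu_fraction >= 0, gu_fraction <= 1)
  structure(list(stem_length = as.integer(stem_length),
                 loop_length = as.integer(loop_length),
                 gu_fraction = gu_fraction,
                 motifs = motifs,
                 intron_index = as.integer(intron_index),
                 mature_length = as.integer(mature_length)),
            class = "plant_spec")
}

#' Generate a synthetic hairpin sequence with known structure
#'
#' Builds `5' arm + loop + reverse complement of the arm` with the requested
#' GU wobbles, and returns the true pair set alongside.
#'
#' @param spec A [plant_spec()].
#' @param seed Integer seed (same seed, same output).
#' @return A list: `sequence`, `pairs` (true stem pairs), `loop` (span), and
#'   planted motif positions.
#' @export
make_hairpin <- function(spec = plant_spec(), seed = 1L) {
  with_seed(seed, {
    S <- spec$stem_length; L <- spec$loop_length
    # GC-leaning arm so the planted stem is unambiguously the MFE structure
    arm <- seq_chars(random_rna(S, gc = 0.6))
    loop <- seq_chars(random_rna(L, gc = 0.3))
    apical_pos <- NA_integer_
    if ("apical" %in% spec$motifs && L >= 3) {
      at <- max(1L, (L - 3L) %/% 2L + 1L)
      loop[at:(at + 2L)] <- c("G", "U", "G")
      apical_pos <- S + at
    }
    arm3 <- seq_chars(rc_rna(paste(arm, collapse = "")))
    n_gu <- round(spec$gu_fraction * S)
    if (n_gu > 0) {
      # convert pairs to GU wobbles: G-C -> G-U (3' side), A-U -> G-U (5' side)
      idx <- sample(seq_len(S), n_gu)
      for (i in idx) {
        j <- S - i + 1L  # arm3 position pairing arm position i
        if (arm[i] == "G") arm3[j] <- "U"
        if (arm[i] == "A") arm[i] <- "G"
      }
    }
    seqv <- c(arm, loop, arm3)
    pairs <- cbind(seq_len(S), 2L * S + L - seq_len(S) + 1L)
    list(sequence = paste(seqv, collapse = ""),
         pairs = pairs,
         loop = c(S + 1L, S + L),
         apical_pos = apical_pos)
  })
}

#' Generate a synthetic gene locus with an optional planted hairpin
#'
#' Background composition is i.i.d. uniform with configurable GC content;
#' exons and introns alternate with the requested lengths. When a hairpin is
#' planted, a basal `UG` and a flanking `CNNC` are written into the intron
#' at the microprocessor's expected offsets (13 nt basal of the intended 5p
#' cut; first flanking `C` 17 nt downstream of the intended 3p cut) if the
#' corresponding motifs are requested. The returned truth record locates the
#' plant so downstream recovery can be scored without refolding.
#'
#' @param n_exons Number of exons.
#' @param intron_lengths Intron lengths (recycled to `n_exons - 1`).
#' @param plant A [plant_spec()] or `NULL`.
#' @param exon_length Exon length (nt).
#' @param gc Background GC content.
#' @param seed Integer seed; the generator is a pure function of
#'   `(spec, seed)`.
#' @return A list: `locus` (a [gene_locus()]) and `truth` (planted interval
#'   in intron coordinates and locus coordinates, the hairpin record from
#'   [make_hairpin()], and the intron count).
#' @export
make_locus <- function(n_exons = 3L, intron_lengths = 200L, plant = NULL,
                       exon_length = 100L, gc = 0.5, seed = 1L) {
  stopifnot(n_exons >= 1)
  n_introns <- n_exons - 1L
  intron_lengths <- rep_len(as.integer(intron_lengths), max(n_introns, 1L))
  if (n_introns == 0) intron_lengths <- integer(0)
  hairpin <- NULL
  with_seed(seed, {
    introns <- lapply(intron_lengths, function(l) {
      seq_chars(random_rna(l, gc = gc))
    })
    plant_at <- NA_integer_
    if (!is.null(plant)) {
      if (plant$intron_index > n_introns) {
        stop("make_locus: plant intron_index exceeds the intron count")
      }
      hairpin <- make_hairpin(plant, seed = sample.int(2^31 - 1L, 1L))
      hp_len <- nchar(hairpin$sequence)
      il <- intron_lengths[plant$intron_index]
      pad <- 25L  # room for the basal/flanking motifs around the plant
      if (il < hp_len + 2L * pad) {
        stop("make_locus: intron ", plant$intron_index,
             " too short for the planted hairpin")
      }
      plant_at <- sample(seq(pad + 1L, il - hp_len - pad + 1L), 1L)
      iv <- introns[[plant$intron_index]]
      iv[plant_at:(plant_at + hp_len - 1L)] <- seq_chars(hairpin$sequence)
      # intended cuts: 5p mature ends at the last paired 5' base
      five_p_cut <- plant_at - 1L + plant$stem_length - plant$mature_length
      three_p_cut <- plant_at - 1L + plant$stem_length + plant$loop_length +
        plant$mature_length + 2L
      if ("basal_ug" %in% plant$motifs) {
        iv[(five_p_cut - 12L):(five_p_cut - 11L)] <- c("U", "G")
      }
      if ("cnnc" %in% plant$motifs && three_p_cut + 20L <= il) {
        iv[three_p_cut + 17L] <- "C"
        iv[three_p_cut + 20L] <- "C"
      }
      introns[[plant$intron_index]] <- iv
    }
    exons <- replicate(n_exons, random_rna(exon_length, gc = gc),
                       simplify = TRUE)
    pieces <- character(0)
    starts <- integer(n_exons)
    pos <- 1L
    for (e in seq_len(n_exons)) {
      starts[e] <- pos
      pieces <- c(pieces, exons[e])
      pos <- pos + exon_length
      if (e <= n_introns) {
        pieces <- c(pieces, paste(introns[[e]], collapse = ""))
        pos <- pos + intron_lengths[e]
      }
    }
    locus <- gene_locus(
      id = sprintf("synthetic_locus_%d", seed),
      sequence = paste(pieces, collapse = ""),
      exons = tibble::tibble(start = starts, end = starts + exon_length - 1L),
      strand = "+")
    truth <- list(
      n_introns = n_introns,
      plant = if (is.null(plant)) NULL else list(
        intron_index = plant$intron_index,
        intron_start = plant_at,
        intron_end = plant_at + nchar(hairpin$sequence) - 1L,
        locus_start = starts[plant$intron_index] + exon_length + plant_at - 1L,
        hairpin = hairpin)
    )
    list(locus = locus, truth = truth)
  })
}

#' Generate a multiple alignment with planted per-block conservation
#'
#' Every column's consensus level is controlled: exactly `round(level * n)`
#' rows carry the reference base, the remainder draw uniformly from the
#' other three bases; gaps are sprinkled independently at `gap_rate`.
#' Realized block consensus is within about +/-0.05 of the planted level for
#' `n_rows >= 20`.
#'
#' @param base_seq Reference (consensus) sequence for the region.
#' @param n_rows Number of species rows.
#' @param blocks Tibble/data.frame with `start`, `end`, `level` (consensus
#'   fraction in `[0.25, 1]`) per block; uncovered columns default to
#'   `default_level`.
#' @param gap_rate Per-cell gap probability.
#' @param default_level Consensus level outside the blocks.
#' @param seed Integer seed.
#' @return A list: `rows` (named character vector of aligned rows) and
#'   `truth` (per-column planted level and the block table).
#' @export
make_alignment <- function(base_seq, n_rows = 20L, blocks = NULL,
                           gap_rate = 0, default_level = 0.5, seed = 1L) {
  base_seq <- as_rna(base_seq, allow_n = FALSE)
  n <- nchar(base_seq)
  s <- seq_chars(base_seq)
  level <- rep(default_level, n)
  if (!is.null(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      stopifnot(blocks$level[b] >= 0.25, blocks$level[b] <= 1)
      level[blocks$start[b]:blocks$end[b]] <- blocks$level[b]
    }
  }
  with_seed(seed, {
    mat <- matrix("", n_rows, n)
    for (j in seq_len(n)) {
      k <- round(level[j] * n_rows)
      who <- sample.int(n_rows, k)
      if (k > 0) mat[who, j] <- s[j]
      rest <- setdiff(seq_len(n_rows), who)
      if (length(rest) > 0) {
        mat[rest, j] <- sample(setdiff(RNA_BASES, s[j]), length(rest),
                               replace = TRUE)
      }
    }
    if (gap_rate > 0) {
      gaps <- matrix(stats::runif(n_rows * n) < gap_rate, n_rows, n)
      mat[gaps] <- "-"
    }
    rows <- apply(mat, 1, paste, collapse = "")
    names(rows) <- sprintf("species_%02d", seq_len(n_rows))
    list(rows = rows,
         truth = list(level = level, blocks = blocks, gap_rate = gap_rate))
  })
}

#' Generate a clone-read mixture
#'
#' Emulates TA-clone sequencing of a small-RNA qPCR product: a stated
#' fraction of reads are mature-length fragments (22-24 nt, the mature
#' sequence with untemplated 3' extension as needed), a mid class (25-31 nt)
#' and the remainder longer by-products (32-134 nt) drawn from the supplied
#' transcripts. Defaults mirror a 19-clone experiment with 20% mature-class
#' reads.
#'
#' @param transcripts Tibble with `id`, `sequence` of by-product source
#'   transcripts (non-empty).
#' @param mature Mature miRNA sequence.
#' @param n_reads Number of clones (default 19).
#' @param frac_mature Fraction of mature-class reads (default 0.20).
#' @param frac_mid Fraction of mid-length reads (default 0.40).
#' @param error_rate Per-base substitution rate.
#' @param seed Integer seed.
#' @return A list: `reads` (tibble `id`, `sequence`, `length`,
#'   `length_class`, `origin`) and `truth` (the origin labels and class
#'   counts).
#' @export
make_reads <- function(transcripts, mature, n_reads = 19L,
                       frac_mature = 0.20, frac_mid = 0.40,
                       error_rate = 0, seed = 1L) {
  if (is.null(transcripts) || nrow(transcripts) == 0) {
    stop("make_reads: transcripts must be non-empty")
  }
  stopifnot(frac_mature + frac_mid <= 1)
  mature <- as_rna(mature, allow_n = FALSE)
  n_mat <- round(frac_mature * n_reads)
  n_mid <- round(frac_mid * n_reads)
  n_long <- n_reads - n_mat - n_mid
  with_seed(seed, {
    draw_fragment <- function(len) {
      tx <- transcripts[sample.int(nrow(transcripts), 1L), ]
      len <- min(len, nchar(tx$sequence))
      at <- sample.int(nchar(tx$sequence) - len + 1L, 1L)
      list(seq = substr(tx$sequence, at, at + len - 1L), origin = tx$id)
    }
    reads <- purrr::map_dfr(seq_len(n_reads), function(i) {
      if (i <= n_mat) {
        len <- sample(22:24, 1L)
        s <- mature
        if (nchar(s) < len) {
          s <- paste0(s, random_rna(len - nchar(s)))  # untemplated 3' tail
        } else {
          s <- substr(s, 1L, len)
        }
        origin <- "mature"
      } else if (i <= n_mat + n_mid) {
        len <- sample(25:31, 1L)
        fr <- draw_fragment(len); s <- fr$seq; origin <- fr$origin
      } else {
        len <- sample(32:134, 1L)
        fr <- draw_fragment(len); s <- fr$seq; origin <- fr$origin
      }
      if (error_rate > 0) {
        sc <- seq_chars(s)
        hit <- which(stats::runif(length(sc)) < error_rate)
        for (h in hit) sc[h] <- sample(setdiff(RNA_BASES, sc[h]), 1L)
        s <- paste(sc, collapse = "")
      }
      tibble::tibble(id = sprintf("clone_%02d", i), sequence = s,
                     length = nchar(s),
                     length_class = dplyr::case_when(
                       nchar(s) <= 24 ~ "mature_like",
                       nchar(s) <= 31 ~ "mid",
                       TRUE ~ "long"),
                     origin = origin)
    })
    list(reads = reads,
         truth = list(origins = stats::setNames(reads$origin, reads$id),
                      n_mature = n_mat, n_mid = n_mid, n_long = n_long))
  })
}

#' Generate a Ct table with planted fold changes
#'
#' Ct values are drawn as `base Ct - log2 fold + N(0, sd)`; the reference
#' gene is planted flat (fold 1 in every group), so 2^-ddCt recovers the
#' planted folds exactly at `sd = 0`.
#'
#' @param genes Character vector of target genes.
#' @param groups Character vector of groups; the first is the baseline.
#' @param planted_log2_folds Matrix (genes x groups) of planted log2 fold
#'   changes relative to baseline (baseline column must be 0), or a single
#'   number applied to every non-baseline group.
#' @param reference_gene Name of the flat reference gene.
#' @param sd_cycles Replicate noise (standard deviation, cycles).
#' @param n_replicates Biological replicates per group.
#' @param base_ct Mean Ct of every gene at baseline.
#' @param seed Integer seed.
#' @return A list: `table` (tibble `sample_id`, `group`, `gene`, `ct`) and
#'   `truth` (the planted fold matrix on the linear scale).
#' @export
make_ct_table <- function(genes, groups, planted_log2_folds,
                          reference_gene = "Actb", sd_cycles = 0.15,
                          n_replicates = 4L, base_ct = 24, seed = 1L) {
  if (is.null(dim(planted_log2_folds))) {
    lf <- matrix(0, length(genes), length(groups),
                 dimnames = list(genes, groups))
    if (length(groups) > 1) lf[, -1] <- planted_log2_folds
    planted_log2_folds <- lf
  }
  stopifnot(all(planted_log2_folds[, 1] == 0))
  all_genes <- c(genes, reference_gene)
  with_seed(seed, {
    tab <- purrr::map_dfr(groups, function(g) {
      purrr::map_dfr(seq_len(n_replicates), function(r) {
        sid <- sprintf("%s_%d", g, r)
        purrr::map_dfr(all_genes, function(gene) {
          lf <- if (gene == reference_gene) 0 else planted_log2_folds[gene, g]
          tibble::tibble(sample_id = sid, group = g, gene = gene,
                         ct = base_ct - lf + stats::rnorm(1, 0, sd_cycles))
        })
      })
    })
    list(table = tab,
         truth = list(fold = 2^planted_log2_folds,
                      reference_gene = reference_gene,
                      baseline = groups[1]))
  })
}
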