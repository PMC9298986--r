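#' Configuration for the intronic hairpin scan
#'
#' @param window_lengths Window sizes slid over each intron (nt).
#' @param step Step between window starts (nt).
#' @param energy_threshold Stability filter in model units (candidates must
#'   fold at or below it).
#' @param min_motif_classes Minimum number of microprocessor motif classes a
#'   candidate must present.
#' @param restrict_to_introns Scan introns only (the discovery setting) or
#'   the whole locus.
#' @param flank Nucleotides of single-stranded flank kept on each side when a
#'   candidate is trimmed to its maximal paired span.
#' @param rank_weights Weights of the ranking score
#'   `w1 * (-mfe / length) + w2 * motif_classes`.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_lengths = seq(60L, 130L, by = 10L),
                        step = 5L,
                        energy_threshold = -15,
                        min_motif_classes = 1L,
                        restrict_to_introns = TRUE,
                        flank = 5L,
                        rank_weights = c(1, 0.5)) {
  stopifnot(all(window_lengths >= 15), step >= 1)
  structure(list(window_lengths = as.integer(window_lengths),
                 step = as.integer(step),
                 energy_threshold = energy_threshold,
                 min_motif_classes = as.integer(min_motif_classes),
                 restrict_to_introns = restrict_to_introns,
                 flank = as.integer(flank),
                 rank_weights = rank_weights),
            class = "scan_config")
}

#' Scan the introns of a gene locus for stable hairpin candidates
#'
#' Slides windows of several lengths over every intron (in transcript
#' orientation), folds each window, keeps windows whose minimum free energy
#' passes the stability filter, trims each to its maximal paired span plus a
#' short single-stranded flank, screens the trimmed hairpin for
#' microprocessor motifs, and resolves overlapping survivors. Candidates are
#' ranked by `rank_score = -mfe/length + 0.5 * motif_classes` (weights
#' configurable).
#'
#' Windows containing `N` are skipped: the folding model is defined over
#' `A/C/G/U` only.
#'
#' @param locus A `gene_locus`.
#' @param cfg A [scan_config()].
#' @param model Energy model used for folding.
#' @param drosha_cfg Motif-screening configuration.
#' @return A tibble of candidates sorted by `rank_score` (descending):
#'   locus/intron bookkeeping, transcript-orientation start/end within the
#'   intron, locus-coordinate start/end, sequence, dot-bracket, `mfe`,
#'   `motif_classes` and `rank_score`. Zero rows (with a warning) when the
#'   locus has no introns under `restrict_to_introns`.
#' @export
scan_introns <- function(locus, cfg = scan_config(),
                         model = default_energy_model(),
                         drosha_cfg = drosha_config()) {
  regions <- if (cfg$restrict_to_introns) {
    derive_introns(locus)
  } else {
    region_row("locus", locus$id, 1L, nchar(locus$sequence), locus$strand,
               locus_subseq(locus, 1L, nchar(locus$sequence)), index = 1L)
  }
  if (nrow(regions) == 0) {
    warning("scan_introns: locus has no introns; returning no candidates")
    return(empty_candidates())
  }
  cands <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    scan_one_region(regions[r, ], cfg, model, drosha_cfg)
  })
  if (nrow(cands) == 0) return(empty_candidates())
  cands <- resolve_overlaps(cands)
  cands <- add_locus_coords(cands, locus, regions)
  dplyr::arrange(cands, dplyr::desc(.data$rank_score), .data$intron,
                 .data$start)
}

empty_candidates <- function() {
  tibble::tibble(locus_id = character(), intron = integer(),
                 start = integer(), end = integer(), length = integer(),
                 sequence = character(), dotbracket = character(),
                 mfe = numeric(), motif_classes = integer(),
                 rank_score = numeric())
}

scan_one_region <- function(region, cfg, model, drosha_cfg) {
  seq <- region$sequence
  n <- nchar(seq)
  out <- list()
  for (wl in cfg$window_lengths) {
    if (wl > n) next
    for (st in seq(1L, n - wl + 1L, by = cfg$step)) {
      win <- substr(seq, st, st + wl - 1L)
      if (grepl("N", win, fixed = TRUE)) next
      hp <- fold_hairpin(win, model)
      if (!is_stable(hp, cfg$energy_threshold) || nrow(hp$pairs) == 0) next
      # trim to the maximal paired span plus flanks; the paired span and its
      # energy are unchanged by removing exterior unpaired bases
      lo <- max(1L, min(hp$pairs[, 1]) - cfg$flank)
      hi <- min(wl, max(hp$pairs[, 2]) + cfg$flank)
      trimmed <- fold_hairpin(substr(win, lo, hi), model)
      if (!is_stable(trimmed, cfg$energy_threshold) ||
          nrow(trimmed$pairs) == 0) next
      classes <- tryCatch(
        scan_motifs(trimmed, cfg = drosha_cfg)$classes_present,
        error = function(e) 0L)
      if (classes < cfg$min_motif_classes) next
      len <- nchar(trimmed$sequence)
      out[[length(out) + 1L]] <- tibble::tibble(
        locus_id = region$source_id, intron = region$index,
        start = st + lo - 1L, end = st + hi - 1L, length = len,
        sequence = trimmed$sequence, dotbracket = trimmed$dotbracket,
        mfe = trimmed$mfe, motif_classes = as.integer(classes),
        rank_score = cfg$rank_weights[1] * (-trimmed$mfe / len) +
          cfg$rank_weights[2] * classes
      )
    }
  }
  if (length(out) == 0) empty_candidates() else dplyr::bind_rows(out)
}

#' Resolve overlapping hairpin candidates
#'
#' Greedy de-duplication: candidates are visited best-first (lowest MFE, ties
#' by more motif classes, then leftmost start) and a candidate is retained
#' only if it overlaps every retained candidate of the same intron by at most
#' 25% of the shorter of the two.
#'
#' @param cands Candidate tibble from one locus.
#' @param max_overlap Maximal allowed fractional overlap of the shorter
#'   candidate (default 0.25).
#' @return The retained candidates, original order restored
#'   (intron, then start).
#' @export
resolve_overlaps <- function(cands, max_overlap = 0.25) {
  if (nrow(cands) <= 1) return(cands)
  ord <- order(cands$mfe, -cands$motif_classes, cands$start)
  keep <- logical(nrow(cands))
  for (k in ord) {
    kept <- which(keep & cands$intron == cands$intron[k])
    ok <- TRUE
    for (j in kept) {
      ov <- min(cands$end[k], cands$end[j]) - max(cands$start[k], cands$start[j]) + 1L
      shorter <- min(cands$length[k], cands$length[j])
      if (ov > max_overlap * shorter) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  dplyr::arrange(cands[keep, ], .data$intron, .data$start)
}

# Map transcript-orientation intron positions back to plus-strand locus
# coordinates (start/end swap on the minus strand).
add_locus_coords <- function(cands, locus, regions) {
  if (nrow(cands) == 0 || !"index" %in% names(regions)) return(cands)
  reg <- regions[match(cands$intron, regions$index), ]
  if (locus$strand == "+" || unique(reg$kind)[1] == "locus") {
    cands$locus_start <- reg$start + cands$start - 1L
    cands$locus_end <- reg$start + cands$end - 1L
  } else {
    cands$locus_start <- reg$end - cands$end + 1L
    cands$locus_end <- reg$end - cands$start + 1L
  }
  cands
}

#' Export candidates as BED6
#'
#' Writes candidates in BED6 (0-based half-open, per the BED standard; locus
#' coordinates are converted from the internal 1-based inclusive convention).
#'
#' @param cands Candidate tibble from [scan_introns()] (needs locus
#'   coordinates).
#' @param path Output file.
#' @param strand Strand character for the BED records.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(cands, path, strand = "+") {
  stopifnot(all(c("locus_start", "locus_end") %in% names(cands)))
  score <- if (nrow(cands) > 0) {
    as.integer(pmin(1000, round(1000 * cands$rank_score /
                                  max(cands$rank_score))))
  } else integer(0)
  bed <- data.frame(
    chrom = cands$locus_id,
    start = cands$locus_start - 1L,  # BED is 0-based half-open
    end = cands$locus_end,
    name = sprintf("%s_intron%d_%d", cands$locus_id, cands$intron, cands$start),
    score = score,
    strand = strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
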