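#' Configuration of the microprocessor (Drosha/DGCR8) processing rules
#'
#' The four consensus motif classes that enhance Drosha processing are
#' screened with the following conventions:
#'
#' * **basal UG** — a `UG` dinucleotide lying basal (5' side) of the 5p
#'   cleavage site, its first base `basal_ug_offset` nucleotides upstream of
#'   the first mature base (default 13 +/- 3).
#' * **CNNC** — a `C..C` tetramer on the 3' flank whose first `C` sits
#'   16-18 nt downstream of the 3p cleavage site. Reported *unevaluable*
#'   (neither present nor absent, and not counted) when fewer than
#'   `cnnc_offset[2] + 3` nucleotides remain downstream of the 3p cut, since
#'   the full window cannot be checked.
#' * **GHG** — `G-H-G` (`H` one of `A/C/U`) on the 3' strand with the central
#'   nucleotide unpaired, its center within `ghg_search_span` nucleotides of
#'   the basal junction (the outermost base pair of the stem).
#' * **apical UGU/GUG** — either triplet within the terminal loop extended by
#'   one nucleotide on each side.
#'
#' @param basal_ug_offset Two-element range of offsets (nt upstream of the 5p
#'   cut) for the basal UG (default `c(10, 16)`, i.e. 13 +/- 3).
#' @param cnnc_offset Range of offsets downstream of the 3p cut for the first
#'   C of CNNC (default `c(16, 18)`).
#' @param ghg_search_span Maximum distance (nt) of the GHG center from the
#'   basal junction (default 10).
#' @param mature_length Default mature length used for unanchored cleavage
#'   placement (default 22 nt; mature products are 18-27 nt).
#' @param mature_bounds Allowed mature length range.
#' @param overhang The 2-nt 3' overhang left by the staggered Drosha cut
#'   (fixed at 2).
#' @return A `drosha_config` list.
#' @export
drosha_config <- function(basal_ug_offset = c(10L, 16L),
                          cnnc_offset = c(16L, 18L),
                          ghg_search_span = 10L,
                          mature_length = 22L,
                          mature_bounds = c(18L, 27L),
                          overhang = 2L) {
  stopifnot(length(basal_ug_offset) == 2, length(cnnc_offset) == 2,
            mature_bounds[1] >= 18 || mature_bounds[1] <= mature_bounds[2])
  if (overhang != 2L) stop("the Drosha 3' overhang is fixed at 2 nt")
  structure(list(basal_ug_offset = as.integer(basal_ug_offset),
                 cnnc_offset = as.integer(cnnc_offset),
                 ghg_search_span = as.integer(ghg_search_span),
                 mature_length = as.integer(mature_length),
                 mature_bounds = as.integer(mature_bounds),
                 overhang = 2L),
            class = "drosha_config")
}

#' Place Drosha cleavage sites on a folded hairpin
#'
#' With a known mature 5p sequence (`anchor_5p`), the 5p cut is placed
#' immediately before its first occurrence. Otherwise the 5p cut is chosen so
#' that a basal UG (when one exists) sits within the configured offset window
#' (closest to the 13-nt center), defaulting to `mature_length` nucleotides
#' below the apical loop. The 3p cut is derived from the pairing partner of
#' the first mature 5p base plus the 2-nt overhang.
#'
#' @param hp A `hairpin_structure` with a paired 5p arm.
#' @param cfg A [drosha_config()].
#' @param anchor_5p Optional known mature 5p sequence (must occur in the
#'   precursor).
#' @return A list of class `cleavage_sites`: `five_p_cut` (position before the
#'   first mature 5p base) and `three_p_cut` (position after the last 3p
#'   base, overhang included).
#' @export
place_cleavage <- function(hp, cfg = drosha_config(), anchor_5p = NULL) {
  seq <- hp$sequence
  ls <- loop_span(hp)
  if (is.null(ls)) stop("place_cleavage: structure has no paired stem")
  if (!is.null(anchor_5p)) {
    anchor_5p <- as_rna(anchor_5p, allow_n = FALSE)
    at <- regexpr(anchor_5p, seq, fixed = TRUE)[1]
    if (at < 0) stop("place_cleavage: anchor_5p is not a substring of the precursor")
    five_p_cut <- at - 1L
    L <- nchar(anchor_5p)
  } else {
    L <- cfg$mature_length
    default_cut <- max(0L, ls[1] - 1L - L)
    ug <- as.integer(gregexpr("UG", substr(seq, 1, ls[1] - 1), fixed = TRUE)[[1]])
    ug <- ug[ug > 0]
    five_p_cut <- default_cut
    if (length(ug) > 0) {
      # candidate cuts put some UG at offset basal_ug_offset[1]..[2]; prefer
      # the one closest to the default placement with the UG nearest 13 nt
      cand <- unlist(lapply(ug, function(p) {
        p + cfg$basal_ug_offset[1]:cfg$basal_ug_offset[2] - 1L
      }))
      cand <- unique(cand[cand >= 0 & cand + L <= ls[1] - 1L])
      if (length(cand) > 0) {
        five_p_cut <- cand[order(abs(cand - default_cut), cand)][1]
      }
    }
  }
  pt <- partner_table(hp)
  mat <- (five_p_cut + 1L):min(five_p_cut + L, nchar(seq))
  partners <- pt[mat]
  partners <- partners[partners > 0]
  if (length(partners) == 0) {
    stop("place_cleavage: the mature 5p region is entirely unpaired")
  }
  three_p_cut <- max(partners) + cfg$overhang
  structure(list(five_p_cut = as.integer(five_p_cut),
                 three_p_cut = as.integer(three_p_cut),
                 mature_length = as.integer(L)),
            class = "cleavage_sites")
}

#' Screen a folded hairpin for microprocessor consensus motifs
#'
#' Reports position and status for each of the four motif classes (see
#' [drosha_config()] for the conventions). `classes_present` counts motifs
#' found; an *unevaluable* CNNC (insufficient 3' flank) is neither present
#' nor counted as an evaluable class.
#'
#' @param hp A `hairpin_structure`.
#' @param cuts Optional [place_cleavage()] result; computed with default
#'   (unanchored) placement when missing.
#' @param cfg A [drosha_config()].
#' @return A one-row tibble: position and status per motif class,
#'   `classes_present`, `classes_evaluable` and `flank_available`.
#' @export
scan_motifs <- function(hp, cuts = NULL, cfg = drosha_config()) {
  if (is.null(cuts)) cuts <- place_cleavage(hp, cfg)
  seq <- hp$sequence
  s <- seq_chars(seq)
  n <- length(s)
  pt <- partner_table(hp)
  ls <- loop_span(hp)

  # basal UG: first base at offset basal_ug_offset upstream of the first
  # mature 5p base (offset = five_p_cut + 1 - position)
  ug_pos <- NA_integer_
  ug_starts <- as.integer(gregexpr("UG", seq, fixed = TRUE)[[1]])
  ug_starts <- ug_starts[ug_starts > 0]
  off <- cuts$five_p_cut + 1L - ug_starts
  hit <- which(off >= cfg$basal_ug_offset[1] & off <= cfg$basal_ug_offset[2])
  if (length(hit) > 0) {
    ug_pos <- ug_starts[hit[order(abs(off[hit] - 13L))][1]]
  }

  # CNNC on the 3' flank
  remaining <- n - cuts$three_p_cut
  cnnc_pos <- NA_integer_
  cnnc_status <- "absent"
  for (k in cfg$cnnc_offset[1]:cfg$cnnc_offset[2]) {
    p <- cuts$three_p_cut + k
    if (p + 3L <= n && s[p] == "C" && s[p + 3L] == "C") {
      cnnc_pos <- p; cnnc_status <- "present"; break
    }
  }
  if (is.na(cnnc_pos) && remaining < cfg$cnnc_offset[2] + 3L) {
    cnnc_status <- "unevaluable"
  }

  # GHG on the 3' strand near the basal junction
  ghg_pos <- NA_integer_
  if (nrow(hp$pairs) > 0) {
    b3 <- hp$pairs[1, 2]
    centers <- (b3 - cfg$ghg_search_span):(b3 + cfg$ghg_search_span)
    centers <- centers[centers >= 2 & centers <= n - 1]
    if (!is.null(ls)) centers <- centers[centers > ls[2]]
    centers <- centers[order(abs(centers - b3))]
    for (c0 in centers) {
      if (s[c0 - 1] == "G" && s[c0 + 1] == "G" &&
          s[c0] %in% c("A", "C", "U") && pt[c0] == 0) {
        ghg_pos <- c0 - 1L; break
      }
    }
  }

  # apical UGU/GUG within loop +/- 1
  apical_pos <- NA_integer_
  apical_motif <- NA_character_
  if (!is.null(ls)) {
    lo <- max(1L, ls[1] - 1L); hi <- min(n, ls[2] + 1L)
    win <- substr(seq, lo, hi)
    for (m in c("UGU", "GUG")) {
      at <- regexpr(m, win, fixed = TRUE)[1]
      if (at > 0 && (is.na(apical_pos) || lo + at - 1L < apical_pos)) {
        apical_pos <- lo + at - 1L
        apical_motif <- m
      }
    }
  }

  present <- c(basal_ug = !is.na(ug_pos),
               cnnc = cnnc_status == "present",
               ghg = !is.na(ghg_pos),
               apical = !is.na(apical_pos))
  evaluable <- c(TRUE, cnnc_status != "unevaluable", TRUE, TRUE)
  tibble::tibble(
    basal_ug = ug_pos,
    cnnc = cnnc_pos,
    cnnc_status = cnnc_status,
    ghg = ghg_pos,
    apical = apical_pos,
    apical_motif = apical_motif,
    classes_present = sum(present),
    classes_evaluable = sum(evaluable),
    flank_available = remaining > 0
  )
}

#' Extract the mature 5p/3p duplex from a cleaved hairpin
#'
#' The 5p mature is the `mature_length` nucleotides following the 5p cut; the
#' 3p mature is the 3'-arm segment pairing with it, extended by exactly 2 nt
#' at its 3' end (the staggered-cut overhang). If the extension would run
#' past the precursor the product is truncated and flagged, not an error.
#'
#' @param hp A `hairpin_structure`.
#' @param cuts A [place_cleavage()] result.
#' @param cfg A [drosha_config()].
#' @return A `mature_duplex`: lists `five_p` and `three_p` (sequence, start,
#'   end), `overhang_3p` (realized 3'-arm overhang), `truncated`, and
#'   `in_bounds` flags for the configured mature length range.
#' @export
extract_duplex <- function(hp, cuts, cfg = drosha_config()) {
  seq <- hp$sequence
  n <- nchar(seq)
  L <- cuts$mature_length %||% cfg$mature_length
  a <- cuts$five_p_cut + 1L
  b <- min(a + L - 1L, n)
  pt <- partner_table(hp)
  partners <- pt[a:b]
  partners <- partners[partners > 0]
  if (length(partners) == 0) stop("extract_duplex: 5p mature is unpaired")
  p_lo <- min(partners); p_hi <- max(partners)
  t_end <- p_hi + cfg$overhang
  truncated <- t_end > n
  t_end <- min(t_end, n)
  five_p <- list(sequence = substr(seq, a, b), start = a, end = b)
  three_p <- list(sequence = substr(seq, p_lo, t_end), start = p_lo, end = t_end)
  lens <- c(nchar(five_p$sequence), nchar(three_p$sequence))
  structure(
    list(five_p = five_p, three_p = three_p,
         overhang_3p = as.integer(t_end - p_hi),
         truncated = truncated,
         in_bounds = lens >= cfg$mature_bounds[1] & lens <= cfg$mature_bounds[2],
         source = hp),
    class = "mature_duplex"
  )
}

#' @export
print.mature_duplex <- function(x, ...) {
  cat("<mature_duplex>\n",
      "  5p: ", x$five_p$sequence, " [", x$five_p$start, "-", x$five_p$end, "]\n",
      "  3p: ", x$three_p$sequence, " [", x$three_p$start, "-", x$three_p$end,
      "]  3' overhang: ", x$overhang_3p, " nt",
      if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

#' Tidy a mature duplex into a per-arm tibble
#'
#' @param x A `mature_duplex`.
#' @param ... Unused.
#' @return A two-row tibble (arms 5p and 3p).
#' @export
tidy.mature_duplex <- function(x, ...) {
  tibble::tibble(
    arm = c("5p", "3p"),
    sequence = c(x$five_p$sequence, x$three_p$sequence),
    start = c(x$five_p$start, x$three_p$start),
    end = c(x$five_p$end, x$three_p$end),
    length = nchar(sequence),
    in_bounds = x$in_bounds
  )
}

#' Summarize motif support for Drosha processing
#'
#' The fraction of evaluable motif classes that are present: a crude score in
#' `[0, 1]` mirroring the two-criteria (stability + motifs) prioritization of
#' hairpin candidates. Returns 0 when no class is evaluable.
#'
#' @param rep A [scan_motifs()] report.
#' @return A number in `[0, 1]`.
#' @export
processing_score <- function(rep) {
  if (rep$classes_evaluable == 0) return(0)
  rep$classes_present / rep$classes_evaluable
}

`%||%` <- function(a, b) if (is.null(a)) b else a
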