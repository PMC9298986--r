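#' Seed-match configuration for target-site scanning
#'
#' Canonical site classes, ordered strongest to weakest:
#' `8mer` (perfect match to mature positions 2-8 plus an `A` across from
#' position 1), `7mer-m8` (match to 2-8), `7mer-A1` (match to 2-7 plus the
#' `A`), `6mer` (match to 2-7).
#'
#' @param min_class Weakest class reported (default `"7mer-m8"`).
#' @param region_kinds Region kinds scanned (default all four).
#' @param supp_span Mature positions whose 3'-supplementary pairing is scored
#'   by [duplex_score()] (default 13-16).
#' @param class_base Base score per class, ascending with class strength;
#'   must be monotone in class order.
#' @return A `seed_match_config` list.
#' @export
seed_match_config <- function(min_class = "7mer-m8",
                              region_kinds = c("three_prime_utr", "cds",
                                               "promoter", "intron"),
                              supp_span = c(13L, 16L),
                              class_base = c(`6mer` = 0.3, `7mer-A1` = 0.4,
                                             `7mer-m8` = 0.5, `8mer` = 0.6)) {
  classes <- c("6mer", "7mer-A1", "7mer-m8", "8mer")
  stopifnot(min_class %in% classes,
            all(names(class_base) %in% classes),
            !is.unsorted(class_base[classes]))
  structure(list(min_class = min_class, region_kinds = region_kinds,
                 supp_span = as.integer(supp_span),
                 class_base = class_base, classes = classes),
            class = "seed_match_config")
}

site_class_rank <- function(cls) {
  match(cls, c("6mer", "7mer-A1", "7mer-m8", "8mer"))
}

#' Scan regions for miRNA seed-matched target sites
#'
#' Finds every site whose region subsequence is reverse-complementary to the
#' mature seed per the canonical class definitions (see
#' [seed_match_config()]), classifies it with the strongest applicable class
#' and scores the site duplex. Sites are reported on the region's sense
#' strand, 1-based inclusive.
#'
#' @param mature Mature miRNA sequence (18-27 nt).
#' @param regions A region tibble (columns `kind`, `source_id`, `sequence`;
#'   e.g. from [derive_introns()] / [extract_promoter()] or built manually).
#' @param cfg A [seed_match_config()].
#' @param mature_id Identifier recorded per site.
#' @return A tibble of target sites sorted by gene and position: `gene_id`,
#'   `region_kind`, `start`, `end`, `site_class`, `duplex_score`,
#'   `mature_id`. Regions shorter than the seed are skipped with a warning.
#' @export
scan_sites <- function(mature, regions, cfg = seed_match_config(),
                       mature_id = "mature") {
  mature <- as_rna(mature, allow_n = FALSE)
  if (nchar(mature) < 18 || nchar(mature) > 27) {
    stop("scan_sites: mature length must be 18-27 nt")
  }
  regions <- regions[regions$kind %in% cfg$region_kinds, , drop = FALSE]
  rc6 <- rc_rna(substr(mature, 2, 7))         # opposite positions 2-7
  m8c <- rna_complement(substr(mature, 8, 8)) # base opposite position 8
  min_rank <- site_class_rank(cfg$min_class)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(r) {
    reg <- as_rna(regions$sequence[r], allow_n = TRUE)
    if (nchar(reg) < 6) {
      warning("scan_sites: region ", regions$source_id[r],
              " shorter than the seed; skipped")
      return(NULL)
    }
    hits <- as.integer(gregexpr(rc6, reg, fixed = TRUE)[[1]])
    hits <- hits[hits > 0]
    purrr::map_dfr(hits, function(k) {
      has_m8 <- k > 1 && substr(reg, k - 1, k - 1) == m8c
      has_a1 <- k + 6 <= nchar(reg) && substr(reg, k + 6, k + 6) == "A"
      cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
             else if (has_a1) "7mer-A1" else "6mer"
      if (site_class_rank(cls) < min_rank) return(NULL)
      start <- if (has_m8) k - 1L else k
      end <- if (has_a1) k + 6L else k + 5L
      tibble::tibble(
        gene_id = regions$source_id[r], region_kind = regions$kind[r],
        start = start, end = end, site_class = cls,
        duplex_score = duplex_score_at(mature, reg, k, cls, cfg),
        mature_id = mature_id)
    })
  })
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, .data$gene_id, .data$start)
}

# Score a site found with its rc6 core at region position k.
duplex_score_at <- function(mature, reg, k, cls, cfg) {
  span <- cfg$supp_span[1]:cfg$supp_span[2]
  # target position opposite mature position p is k + 7 - p: the rc6 core at
  # k..k+5 pairs mature positions 7..2
  tpos <- k + 7L - span
  mbase <- substring(mature, span, span)
  tbase <- ifelse(tpos >= 1 & tpos <= nchar(reg),
                  substring(reg, tpos, tpos), "N")
  frac <- mean(tbase == rna_complement(mbase))
  base <- unname(cfg$class_base[cls])
  base + frac * (1 - base)
}

#' Score a mature/target-site duplex
#'
#' `score = class base + supplementary fraction x (1 - class base)`: the
#' class base value rises with seed-class strength, and the fraction of
#' complementary pairs in the 3'-supplementary window fills the remainder,
#' so a perfect full-length complement scores 1 and a 6mer with no
#' supplementary pairing scores the 6mer floor.
#'
#' @param mature Mature miRNA sequence.
#' @param site_context The region sequence containing the site.
#' @param site_start Position of the seed-core match (opposite mature
#'   positions 2-7) within `site_context`.
#' @param site_class The site's class.
#' @param cfg A [seed_match_config()].
#' @return A score in `[0, 1]`, monotone in class order at equal
#'   supplementary pairing.
#' @export
duplex_score <- function(mature, site_context, site_start, site_class,
                         cfg = seed_match_config()) {
  duplex_score_at(as_rna(mature, allow_n = FALSE),
                  as_rna(site_context, allow_n = TRUE),
                  site_start, site_class, cfg)
}

#' Corroborate predicted target genes with clone reads
#'
#' Each read is locally aligned (Smith-Waterman scoring) against every
#' transcript; a gene is corroborated when some read aligns at or above
#' `min_identity` over at least `min_length` aligned columns *and* the gene
#' is among the predictions - the intersection logic used to shortlist
#' targets for qPCR verification. Alignment uses match +2, mismatch -1, gap
#' open -2, gap extend -1 by default.
#'
#' @param reads Tibble with `id` and `sequence` (clone reads).
#' @param transcripts Tibble with `id` and `sequence` (candidate target
#'   transcripts); must be non-empty.
#' @param predicted Character vector of predicted target gene ids.
#' @param min_identity Minimal fraction of matching columns (default 0.8).
#' @param min_length Minimal alignment length in columns (default 20).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @return A list of class `corroboration`: `corroborated` (character vector,
#'   always a subset of `predicted`) and `evidence` (per read x transcript
#'   best local alignment: score, identity, alignment length, subject
#'   coordinates, and whether it passes).
#' @export
corroborate_with_reads <- function(reads, transcripts, predicted,
                                   min_identity = 0.8, min_length = 20,
                                   match = 2, mismatch = -1,
                                   gap_open = 2, gap_extend = 1) {
  if (is.null(transcripts) || nrow(transcripts) == 0) {
    stop("corroborate_with_reads: empty transcript set")
  }
  if (nrow(reads) == 0) {
    return(structure(list(corroborated = character(0),
                          evidence = tibble::tibble()),
                     class = "corroboration"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  evidence <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    purrr::map_dfr(seq_len(nrow(transcripts)), function(j) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(as_dna(reads$sequence[i])),
        Biostrings::DNAString(as_dna(transcripts$sequence[j])),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend)
      alen <- Biostrings::nchar(aln)
      ident <- if (alen > 0) Biostrings::nmatch(aln) / alen else 0
      tibble::tibble(
        read_id = reads$id[i], transcript_id = transcripts$id[j],
        score = Biostrings::score(aln), aln_length = alen,
        identity = ident,
        subject_start = BiocGenerics::start(Biostrings::subject(aln)),
        subject_end = BiocGenerics::end(Biostrings::subject(aln)),
        passes = alen >= min_length && ident >= min_identity)
    })
  })
  hit_genes <- unique(evidence$transcript_id[evidence$passes])
  structure(
    list(corroborated = sort(intersect(hit_genes, predicted)),
         evidence = evidence),
    class = "corroboration"
  )
}

#' @export
print.corroboration <- function(x, ...) {
  cat("<corroboration> ", length(x$corroborated), " gene(s): ",
      paste(x$corroborated, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy corroboration evidence
#'
#' @param x A `corroboration`.
#' @param ... Unused.
#' @return The per-read/per-transcript evidence tibble.
#' @export
tidy.corroboration <- function(x, ...) x$evidence
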