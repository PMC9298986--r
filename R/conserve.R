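#' Per-column conservation profile of a multiple alignment
#'
#' For each alignment column, *occupancy* is the fraction of rows that are
#' not gapped and *consensus* is the fraction of non-gap rows carrying the
#' modal residue. The two tracks are deliberately independent: occupancy
#' measures presence across species, consensus measures agreement among the
#' species that are present. A fully gapped column has occupancy 0 and
#' consensus `NA`.
#'
#' @param aln Aligned rows: a character vector (equal lengths, `-` gaps), a
#'   named vector, or a tibble with a `sequence` column (e.g. from
#'   [read_sequences()] with `format = "aligned_fasta"`).
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `occupancy`, `consensus`, `modal`; the number of rows profiled is kept
#'   in the `n_rows` attribute.
#' @examples
#' profile_alignment(c("AUGC", "AUGG", "AU-C"))
#' @export
profile_alignment <- function(aln) {
  if (is.data.frame(aln)) aln <- aln$sequence
  stopifnot(is.character(aln), length(aln) >= 2)
  if (length(unique(nchar(aln))) != 1) {
    stop("profile_alignment: ragged alignment (rows of unequal length)")
  }
  mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  nr <- nrow(mat)
  cols <- purrr::map_dfr(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    occ <- length(nongap) / nr
    if (length(nongap) == 0) {
      tibble::tibble(column = j, occupancy = 0, consensus = NA_real_,
                     modal = NA_character_)
    } else {
      tab <- sort(table(nongap), decreasing = TRUE)
      tibble::tibble(column = j, occupancy = occ,
                     consensus = unname(tab[1]) / length(nongap),
                     modal = names(tab)[1])
    }
  })
  structure(cols, class = c("conservation_profile", class(cols)),
            n_rows = nr)
}

#' Call the guide strand from arm conservation
#'
#' The arm whose mean consensus exceeds the threshold - while the other arm's
#' does not - is called the guide (the evolutionarily conserved, functional
#' strand); otherwise the call is ambiguous. Mean occupancy is reported
#' alongside for both arms.
#'
#' @param profile A [profile_alignment()] result.
#' @param region_5p,region_3p Column ranges (two-element integer vectors,
#'   inclusive) of the 5p and 3p mature arms within the alignment. Must be
#'   disjoint and inside the profile.
#' @param threshold Consensus fraction above which an arm counts as conserved
#'   (default 0.5, strict `>`).
#' @return A one-row tibble of class `strand_call`: `guide` (`"five_p"`,
#'   `"three_p"` or `"ambiguous"`), per-arm mean consensus and occupancy, and
#'   the threshold.
#' @export
call_guide_strand <- function(profile, region_5p, region_3p, threshold = 0.5) {
  stopifnot(length(region_5p) == 2, length(region_3p) == 2)
  r5 <- region_5p[1]:region_5p[2]
  r3 <- region_3p[1]:region_3p[2]
  if (length(intersect(r5, r3)) > 0) {
    stop("call_guide_strand: 5p and 3p column ranges overlap")
  }
  if (min(r5, r3) < 1 || max(r5, r3) > max(profile$column)) {
    stop("call_guide_strand: region outside the profile")
  }
  m5 <- mean(profile$consensus[profile$column %in% r5], na.rm = TRUE)
  m3 <- mean(profile$consensus[profile$column %in% r3], na.rm = TRUE)
  o5 <- mean(profile$occupancy[profile$column %in% r5])
  o3 <- mean(profile$occupancy[profile$column %in% r3])
  guide <- if (m5 > threshold && m3 <= threshold) {
    "five_p"
  } else if (m3 > threshold && m5 <= threshold) {
    "three_p"
  } else {
    "ambiguous"
  }
  structure(
    tibble::tibble(guide = guide,
                   mean_consensus_5p = m5, mean_consensus_3p = m3,
                   mean_occupancy_5p = o5, mean_occupancy_3p = o3,
                   threshold = threshold),
    class = c("strand_call", "tbl_df", "tbl", "data.frame")
  )
}

#' Plot a conservation profile
#'
#' Consensus and occupancy as two aligned tracks, the way alignment viewers
#' draw them.
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("column", "occupancy", "consensus")],
    cols = c("occupancy", "consensus"),
    names_to = "track", values_to = "fraction")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$column, y = .data$fraction)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::facet_wrap(~track, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Write a conservation profile as TSV
#'
#' @param profile A `conservation_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(tibble::as_tibble(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
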