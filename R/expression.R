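#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per biological sample, technical (instrumental) replicates are collapsed
#' to their mean Ct; `dCt = Ct(target) - Ct(reference)`;
#' `ddCt = dCt - mean dCt(baseline group)`; the per-sample fold change is
#' `2^-ddCt`. Group fold changes average on the log scale
#' (`2^-mean(ddCt)`), so the baseline group's fold is exactly 1 by
#' construction; the SEM is propagated on the linear scale from the
#' per-sample folds, matching the usual mean +/- SEM presentation.
#'
#' Samples missing the reference gene are excluded with a warning; a missing
#' baseline group is an error.
#'
#' @param table Ct tibble with columns `sample_id`, `group`, `gene`, `ct`
#'   (cycles, > 0); an optional `replicate` column distinguishes technical
#'   replicates.
#' @param target_gene Gene to quantify.
#' @param reference_gene Reference (housekeeping) gene, e.g. a small
#'   nucleolar RNA for small-RNA assays or beta-actin for mRNA.
#' @param baseline_group Group whose mean defines fold = 1.
#' @param per_sample Also return per-sample folds (attribute `samples`).
#' @return A tibble of class `fold_change_tbl`: `gene`, `group`, `fold`,
#'   `sem`, `n` (biological replicates), with the baseline group first.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("c1", "c2", "t1", "t2"), each = 2),
#'   group = rep(c("control", "treated"), each = 4),
#'   gene = rep(c("Mef2d", "Actb"), 4),
#'   ct = c(30, 20, 30, 20, 28, 20, 28, 20))
#' ddct_fold_change(ct, "Mef2d", "Actb", "control")  # treated fold = 4
#' @export
ddct_fold_change <- function(table, target_gene, reference_gene,
                             baseline_group, per_sample = FALSE) {
  table <- tibble::as_tibble(table)
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(table))) {
    stop("ddct_fold_change: table needs columns ",
         paste(need, collapse = ", "))
  }
  if (any(table$ct <= 0)) stop("ddct_fold_change: Ct values must be > 0")
  if (!baseline_group %in% table$group) {
    stop("ddct_fold_change: baseline group '", baseline_group,
         "' not present")
  }
  # collapse technical replicates
  ct <- table %>%
    dplyr::filter(.data$gene %in% c(target_gene, reference_gene)) %>%
    dplyr::group_by(.data$sample_id, .data$group, .data$gene) %>%
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- tidyr::pivot_wider(ct, names_from = "gene", values_from = "ct")
  if (!target_gene %in% names(wide)) {
    stop("ddct_fold_change: target gene '", target_gene, "' not present")
  }
  missing_ref <- !reference_gene %in% names(wide) |
    is.na(wide[[reference_gene]])
  if (any(missing_ref)) {
    warning("ddct_fold_change: excluding ", sum(missing_ref),
            " sample(s) without the reference gene")
    wide <- wide[!missing_ref, , drop = FALSE]
  }
  wide <- wide[!is.na(wide[[target_gene]]), , drop = FALSE]
  wide$dct <- wide[[target_gene]] - wide[[reference_gene]]
  base_mean <- mean(wide$dct[wide$group == baseline_group])
  wide$ddct <- wide$dct - base_mean
  wide$sample_fold <- 2^(-wide$ddct)
  res <- wide %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      gene = target_gene,
      sem = stats::sd(.data$sample_fold) / sqrt(dplyr::n()),
      fold = 2^(-mean(.data$ddct)),
      n = dplyr::n(), .groups = "drop") %>%
    dplyr::select("gene", "group", "fold", "sem", "n") %>%
    dplyr::arrange(.data$group != baseline_group, .data$group)
  out <- structure(res, class = c("fold_change_tbl", class(res)))
  if (per_sample) {
    attr(out, "samples") <- wide[, c("sample_id", "group", "dct", "ddct",
                                     "sample_fold")]
  }
  out
}

#' Plot fold changes
#'
#' Group means with SEM error bars, baseline at 1.
#'
#' @param object A `fold_change_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_change_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$group <- factor(df$group, levels = unique(df$group))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fold)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold - .data$sem,
                   ymax = .data$fold + .data$sem), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "relative expression (2^-ddCt)",
                  title = unique(df$gene)) +
    ggplot2::theme_minimal()
}

#' Densitometry ratio normalization
#'
#' Plain ratio of a band intensity to its loading control (e.g. beta-actin),
#' the standard western-blot normalization.
#'
#' @param value Band intensities.
#' @param control Loading-control intensities.
#' @return `value / control`.
#' @export
densitometry_ratio <- function(value, control) value / control
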