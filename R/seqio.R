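#' Read sequences from a FASTA or aligned-FASTA file
#'
#' Sequences are uppercased and normalized to the internal RNA alphabet
#' (`T -> U`) unless `alphabet = "as_is"`. Gap characters (`-`) are preserved
#' only for `format = "aligned_fasta"`; in plain FASTA they are dropped.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"aligned_fasta"`.
#' @param alphabet `"rna"` (default, `T` converted to `U`) or `"as_is"`.
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' plaur <- read_sequences(
#'   system.file("extdata", "plaur_premirs.fasta", package = "intronmiR"))
#' nchar(plaur$sequence)
#' @export
read_sequences <- function(path, format = c("fasta", "aligned_fasta"),
                           alphabet = c("rna", "as_is")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(raw)))
  if (length(nonempty) == 0) stop("empty input: ", path, " contains no records")
  first <- nonempty[1]
  if (!startsWith(trimws(raw[first]), ">")) {
    stop("malformed FASTA record at line ", first, " of ", path,
         ": expected a '>' header")
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty input: ", path, " contains no records")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (format == "fasta") seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (alphabet == "rna") {
    seqs <- as_rna(seqs, allow_n = TRUE, allow_gaps = (format == "aligned_fasta"))
  }
  if (format == "aligned_fasta" && length(unique(nchar(seqs))) > 1) {
    stop("aligned_fasta: rows have unequal lengths")
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x A tibble/data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path Output file.
#' @param alphabet `"dna"` (default; `U` written back as `T`) or `"rna"`.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, alphabet = c("dna", "rna"), width = 60) {
  alphabet <- match.arg(alphabet)
  if (is.character(x)) x <- tibble::tibble(id = names(x), sequence = unname(x))
  seqs <- if (alphabet == "dna") as_dna(x$sequence) else x$sequence
  lines <- unlist(purrr::map2(x$id, seqs, function(id, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Gene locus -----------------------------------------------------------------

#' Construct a gene locus
#'
#' A locus is a plus-strand reference sequence with an exon model, a strand
#' and a transcription start site. All locus coordinates are 1-based
#' inclusive, on the plus strand of the locus sequence; genomic coordinates
#' are obtained by adding `assembly_offset - 1`. Exons must be sorted,
#' non-overlapping and within the sequence.
#'
#' @param id Locus identifier.
#' @param sequence Plus-strand nucleotide sequence (DNA or RNA letters; kept
#'   internally as RNA).
#' @param exons Data frame with `start` and `end` (locus coordinates,
#'   ascending).
#' @param strand `"+"` or `"-"`. On the minus strand the transcript reads
#'   from high to low locus coordinates.
#' @param tss Locus coordinate of the transcription start site (first
#'   transcribed base). Defaults to the strand-aware 5' end of the exon span.
#' @param assembly_offset Genomic coordinate of locus position 1.
#' @return An object of class `gene_locus`.
#' @export
gene_locus <- function(id, sequence, exons, strand = "+", tss = NULL,
                       assembly_offset = 1L) {
  stopifnot(strand %in% c("+", "-"))
  sequence <- as_rna(sequence, allow_n = TRUE)
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  exons <- dplyr::arrange(exons, .data$start)
  if (nrow(exons) < 1) stop("gene_locus: at least one exon is required")
  if (any(exons$start > exons$end)) stop("gene_locus: exon start > end")
  if (any(exons$start < 1) || any(exons$end > nchar(sequence))) {
    stop("gene_locus: exon outside locus bounds")
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("gene_locus: overlapping exons")
  }
  if (is.null(tss)) {
    tss <- if (strand == "+") min(exons$start) else max(exons$end)
  }
  structure(
    list(id = id, sequence = sequence, exons = exons, strand = strand,
         tss = as.integer(tss), assembly_offset = as.integer(assembly_offset)),
    class = "gene_locus"
  )
}

#' @export
print.gene_locus <- function(x, ...) {
  cat("<gene_locus> ", x$id, ": ", nchar(x$sequence), " nt, ",
      nrow(x$exons), " exons (", max(0L, nrow(x$exons) - 1L), " introns), strand ",
      x$strand, ", TSS at ", x$tss, "\n", sep = "")
  invisible(x)
}

#' Convert between locus-relative and genomic coordinates
#'
#' @param locus A `gene_locus`.
#' @param pos Integer vector of positions.
#' @return The converted positions. The two functions are inverse bijections
#'   on all valid locus positions.
#' @export
locus_to_genomic <- function(locus, pos) {
  as.integer(locus$assembly_offset + pos - 1L)
}

#' @rdname locus_to_genomic
#' @export
genomic_to_locus <- function(locus, pos) {
  as.integer(pos - locus$assembly_offset + 1L)
}

#' Read a gene locus from FASTA + GFF3
#'
#' The GFF3 exon features (coordinates relative to the FASTA sequence,
#' 1-based) define the transcript model.
#'
#' @param fasta_path FASTA file with the locus sequence (first record used
#'   unless `id` names another).
#' @param gff_path GFF3 file whose `exon` features define the model.
#' @param id Optional record id to select from the FASTA.
#' @param assembly_offset Genomic coordinate of locus position 1.
#' @return A `gene_locus`.
#' @export
read_gene_locus <- function(fasta_path, gff_path, id = NULL,
                            assembly_offset = 1L) {
  seqs <- read_sequences(fasta_path)
  rec <- if (is.null(id)) seqs[1, ] else seqs[seqs$id == id, ]
  if (nrow(rec) != 1) stop("sequence record not found in ", fasta_path)
  gff <- rtracklayer::import(gff_path)
  ex <- gff[gff$type == "exon"]
  if (length(ex) == 0) stop("no exon features in ", gff_path)
  strand <- as.character(BiocGenerics::strand(ex))[1]
  if (!strand %in% c("+", "-")) strand <- "+"
  gene_locus(
    id = rec$id, sequence = rec$sequence,
    exons = tibble::tibble(start = BiocGenerics::start(ex),
                           end = BiocGenerics::end(ex)),
    strand = strand, assembly_offset = assembly_offset
  )
}

# Regions --------------------------------------------------------------------

region_row <- function(kind, source_id, start, end, strand, sequence,
                       truncated = FALSE, index = NA_integer_) {
  tibble::tibble(kind = kind, source_id = source_id, index = index,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, length = as.integer(end - start + 1L),
                 truncated = truncated, sequence = sequence)
}

# Extract a locus subsequence in transcript orientation.
locus_subseq <- function(locus, start, end) {
  s <- substr(locus$sequence, start, end)
  if (locus$strand == "-") rc_rna(s) else s
}

#' Derive introns from a gene locus
#'
#' Introns are the maximal gaps between consecutive exons. Their count is
#' `n_exons - 1` for a contiguous single-transcript model. Coordinates are
#' plus-strand locus coordinates; `sequence` and `index` follow transcript
#' orientation, so on a minus-strand locus intron 1 is the highest-coordinate
#' gap and its sequence is reverse-complemented.
#'
#' @param locus A `gene_locus`.
#' @return A tibble of intron regions (possibly zero rows), in transcript
#'   order.
#' @export
derive_introns <- function(locus) {
  ex <- locus$exons
  if (nrow(ex) < 2) {
    return(region_row(character(0), character(0), integer(0), integer(0),
                      character(0), character(0), logical(0), integer(0)))
  }
  starts <- ex$end[-nrow(ex)] + 1L
  ends <- ex$start[-1] - 1L
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  idx <- seq_along(starts)
  if (locus$strand == "-") idx <- rev(idx)
  out <- purrr::map2_dfr(seq_along(starts), idx, function(k, i) {
    region_row("intron", locus$id, starts[k], ends[k], locus$strand,
               locus_subseq(locus, starts[k], ends[k]), index = i)
  })
  dplyr::arrange(out, .data$index)
}

#' Extract the promoter window upstream of the TSS
#'
#' Returns the `window` nucleotides immediately 5' of the transcription start
#' site in transcript orientation (reverse-complemented on the minus strand).
#' If the locus boundary is reached the region is truncated and flagged.
#'
#' @param locus A `gene_locus` with a defined TSS.
#' @param window Window size in nucleotides (default 600).
#' @return A one-row region tibble with a `truncated` flag.
#' @export
extract_promoter <- function(locus, window = 600) {
  if (is.null(locus$tss) || is.na(locus$tss)) {
    stop("extract_promoter: locus has no TSS defined")
  }
  stopifnot(window >= 1)
  n <- nchar(locus$sequence)
  if (locus$strand == "+") {
    start <- locus$tss - window; end <- locus$tss - 1L
    truncated <- start < 1
    start <- max(1L, start)
  } else {
    start <- locus$tss + 1L; end <- locus$tss + window
    truncated <- end > n
    end <- min(n, end)
  }
  if (end < start) stop("extract_promoter: no sequence upstream of the TSS")
  region_row("promoter", locus$id, start, end, locus$strand,
             locus_subseq(locus, start, end), truncated = truncated)
}

# Packaged fixtures ----------------------------------------------------------

#' Packaged precursor sequences of the Plaur small-RNA study
#'
#' The three intronic precursor hairpins reported for the mouse Plaur
#' (urokinase receptor) gene, with their printed genomic intervals. The
#' pre-miR1 end coordinate was printed truncated in the source table; the
#' interval is stored verbatim and flagged unreliable rather than guessed.
#'
#' @return A tibble: `id`, `sequence`, `length`, `genome_start`, `genome_end`,
#'   `interval_reliable`, `intron`.
#' @export
plaur_precursors <- function() {
  tbl <- read_sequences(
    system.file("extdata", "plaur_premirs.fasta", package = "intronmiR"))
  meta <- tibble::tibble(
    id = c("Plaur-pre-miR1", "Plaur-pre-miR2", "Plaur-pre-miR3"),
    genome_start = c(24171226L, 24173938L, 24169492L),
    genome_end = c(2417132L, 24174023L, 24169600L),
    interval_reliable = c(FALSE, TRUE, TRUE),
    intron = c(3L, 3L, 6L)
  )
  dplyr::left_join(
    dplyr::mutate(tbl, length = nchar(.data$sequence)), meta, by = "id")
}

#' Packaged mature small-RNA sequences
#'
#' @return A tibble with the reported mature 5p and 3p sequences.
#' @export
plaur_mature <- function() {
  tbl <- read_sequences(
    system.file("extdata", "plaur_mature.fasta", package = "intronmiR"))
  dplyr::mutate(tbl, arm = c("5p", "3p"), length = nchar(.data$sequence))
}

#' Synthetic Plaur-like gene locus
#'
#' Builds a minus-strand locus with the packaged exon model (seven exons, six
#' introns, ~16 kb gene span, ~1 kb mature mRNA) and a deterministic random
#' background sequence into which the three packaged precursors are planted
#' at their printed genomic positions (pre-miR1 and pre-miR2 in intron 3,
#' pre-miR3 in intron 6). The exon coordinates and background sequence are
#' synthetic: the source study does not deposit them. Only the exon/intron
#' counts, the gene-scale dimensions and the precursor placements are
#' faithful.
#'
#' @return A `gene_locus`.
#' @export
plaur_locus <- function() {
  gff <- system.file("extdata", "plaur_gene_model_synthetic.gff3",
                     package = "intronmiR")
  imported <- rtracklayer::import(gff)
  ex <- imported[imported$type == "exon"]
  offset <- 24160001L
  n <- 16600L
  seq <- with_seed(20793L, random_rna(n, gc = 0.5))
  pre <- plaur_precursors()
  # plant each precursor on the plus strand as the reverse complement of its
  # transcript-orientation sequence (the gene is on the minus strand)
  plant_start <- genomic_to_locus(list(assembly_offset = offset),
                                  c(24171226L, 24173938L, 24169492L))
  s <- seq_chars(seq)
  for (k in 1:3) {
    ins <- seq_chars(rc_rna(pre$sequence[k]))
    s[plant_start[k]:(plant_start[k] + length(ins) - 1L)] <- ins
  }
  gene_locus(
    id = "PlaurLocus", sequence = paste(s, collapse = ""),
    exons = tibble::tibble(start = BiocGenerics::start(ex),
                           end = BiocGenerics::end(ex)),
    strand = "-", tss = 16000L, assembly_offset = offset
  )
}
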