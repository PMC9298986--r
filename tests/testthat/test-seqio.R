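test_that("packaged precursor fixtures have the reported lengths and intervals", {
  pre <- plaur_precursors()
  expect_equal(pre$length, c(103L, 86L, 109L))
  # for the two records with reliable printed intervals, span == length
  ok <- pre$interval_reliable
  expect_equal(pre$genome_end[ok] - pre$genome_start[ok] + 1L,
               pre$length[ok])
  expect_false(pre$interval_reliable[1])  # truncated printed end coordinate
})

test_that("single-record FASTA parses to an identity tibble", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGU"), path)
  expect_equal(read_sequences(path),
               tibble::tibble(id = "x", sequence = "ACGU"))
})

test_that("write-then-read round-trips random records", {
  set.seed(5)
  tbl <- tibble::tibble(
    id = sprintf("rec%02d", 1:50),
    sequence = vapply(sample(30:90, 50, replace = TRUE), random_rna_str,
                      character(1)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_sequences(tbl, path, alphabet = "rna")
  back <- read_sequences(path)
  expect_equal(back, tbl)
  # DNA round trip: T on disk, U in memory
  write_sequences(tbl, path, alphabet = "dna")
  expect_equal(read_sequences(path), tbl)
})

test_that("malformed and empty FASTA files raise informative errors", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", ">x"), path)
  expect_error(read_sequences(path), "line 1")
  writeLines(character(0), path)
  expect_error(read_sequences(path), "empty")
  expect_error(read_sequences("/nonexistent/f.fa"), "not found")
})

test_that("aligned FASTA keeps gaps and rejects ragged rows", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AC-U", ">b", "ACGU"), path)
  aln <- read_sequences(path, format = "aligned_fasta")
  expect_equal(aln$sequence, c("AC-U", "ACGU"))
  # plain FASTA drops gaps
  expect_equal(read_sequences(path)$sequence[1], "ACU")
  writeLines(c(">a", "AC-U", ">b", "ACGUA"), path)
  expect_error(read_sequences(path, format = "aligned_fasta"), "unequal")
})

test_that("the packaged gene model yields seven exons and six introns", {
  loc <- plaur_locus()
  expect_equal(nrow(loc$exons), 7)
  intr <- derive_introns(loc)
  expect_equal(nrow(intr), 6)
  # all three precursors sit in their annotated introns, transcript orientation
  pre <- plaur_precursors()
  expect_true(grepl(pre$sequence[1], intr$sequence[intr$index == 3]))
  expect_true(grepl(pre$sequence[2], intr$sequence[intr$index == 3]))
  expect_true(grepl(pre$sequence[3], intr$sequence[intr$index == 6]))
})

test_that("a single-exon model has no introns", {
  loc <- gene_locus("g", strrep("ACGU", 30),
                    tibble::tibble(start = 10, end = 50))
  expect_equal(nrow(derive_introns(loc)), 0)
})

test_that("introns equal the set-complement oracle on random exon models", {
  set.seed(9)
  for (case in 1:100) {
    L <- sample(200:600, 1)
    ex <- random_exon_model(sample(2:6, 1), L)
    if (nrow(ex) < 2) next
    loc <- gene_locus("g", random_rna_str(L), ex)
    got <- derive_introns(loc)
    want <- brute_introns(loc$exons, L)
    expect_equal(got$start[order(got$start)], want$start)
    expect_equal(got$end[order(got$end)], want$end)
  }
})

test_that("exons, introns and intergenic space partition the locus", {
  set.seed(21)
  for (case in 1:20) {
    L <- 300
    ex <- random_exon_model(3, L)
    if (nrow(ex) < 2) next
    loc <- gene_locus("g", random_rna_str(L), ex)
    intr <- derive_introns(loc)
    cover <- integer(L)
    for (k in seq_len(nrow(loc$exons))) {
      cover[loc$exons$start[k]:loc$exons$end[k]] <-
        cover[loc$exons$start[k]:loc$exons$end[k]] + 1L
    }
    for (k in seq_len(nrow(intr))) {
      cover[intr$start[k]:intr$end[k]] <- cover[intr$start[k]:intr$end[k]] + 1L
    }
    gene_span <- min(loc$exons$start):max(loc$exons$end)
    expect_true(all(cover[gene_span] == 1L))   # no overlap, no gap inside
    expect_true(all(cover[-gene_span] == 0L))  # nothing outside
  }
})

test_that("overlapping exons are rejected", {
  expect_error(
    gene_locus("g", strrep("ACGU", 30),
               tibble::tibble(start = c(1, 15), end = c(20, 40))),
    "overlap")
})

test_that("minus-strand introns come back reverse-complemented in transcript order", {
  # plus-strand layout: exon 1-10, intron 11-20, exon 21-30
  seqs <- paste0(strrep("A", 10), "CCCCCAAGGG", strrep("A", 10))
  loc <- gene_locus("g", seqs, tibble::tibble(start = c(1, 21), end = c(10, 30)),
                    strand = "-")
  intr <- derive_introns(loc)
  expect_equal(intr$sequence, rc_rna("CCCCCAAGGG"))
  expect_equal(intr$index, 1L)
})

test_that("promoter extraction follows strand and flags truncation", {
  loc <- plaur_locus()
  prom <- extract_promoter(loc)
  expect_equal(prom$length, 600L)
  expect_false(prom$truncated)

  # plus strand: window immediately 5' of the TSS
  plus <- gene_locus("g", strrep("ACGU", 50),
                     tibble::tibble(start = 101, end = 150), strand = "+",
                     tss = 101)
  p <- extract_promoter(plus, window = 10)
  expect_equal(p$sequence, substr(plus$sequence, 91, 100))

  # minus strand: reverse complement of the slice just 3' of the TSS in
  # plus coordinates (hand oracle)
  minus <- gene_locus("g", strrep("ACGU", 50),
                      tibble::tibble(start = 51, end = 100), strand = "-",
                      tss = 100)
  m <- extract_promoter(minus, window = 10)
  expect_equal(m$sequence, rc_rna(substr(minus$sequence, 101, 110)))

  # window = 1 just inside the boundary: no truncation flag
  tiny <- gene_locus("g", strrep("ACGU", 10),
                     tibble::tibble(start = 2, end = 30), tss = 2)
  t1 <- extract_promoter(tiny, window = 1)
  expect_equal(t1$length, 1L)
  expect_false(t1$truncated)

  # truncation at the locus edge
  tr <- extract_promoter(tiny, window = 5)
  expect_true(tr$truncated)
  expect_equal(tr$length, 1L)
})

test_that("locus/genomic coordinate conversion is a bijection", {
  loc <- gene_locus("g", strrep("ACGU", 25),
                    tibble::tibble(start = 1, end = 100),
                    assembly_offset = 24160001L)
  pos <- 1:100
  expect_equal(genomic_to_locus(loc, locus_to_genomic(loc, pos)), pos)
  expect_equal(locus_to_genomic(loc, 1), 24160001L)
})
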