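utr_region <- function(seq, id = "geneA", kind = "three_prime_utr") {
  tibble::tibble(kind = kind, source_id = id, sequence = seq)
}

test_that("a planted perfect 8mer site is found exactly once at the plant", {
  set.seed(19)
  mature <- "UGGUGAUUGGCUGCCAGGUUC"
  # reverse complement of positions 1-8 gives an 8mer site when the mature
  # starts with U (A across from position 1)
  site <- rc_rna(substr(mature, 1, 8))
  bg <- gsub("A", "C", random_rna_str(120))  # seedless background
  reg <- paste0(substr(bg, 1, 60), site, substr(bg, 61, 120))
  hits <- scan_sites(mature, utr_region(reg))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_class, "8mer")
  expect_equal(hits$start, 60 + 1)
  expect_equal(hits$end, 60 + 8)
})

test_that("poly-A regions contain no sites for a GC-containing seed", {
  hits <- scan_sites("UGGUGAUUGGCUGCCAGGUUC", utr_region(strrep("A", 200)))
  expect_equal(nrow(hits), 0)
})

test_that("scan_sites equals the brute-force sliding oracle", {
  set.seed(29)
  for (case in 1:100) {
    mature <- random_rna_str(sample(18:24, 1))
    region <- random_rna_str(sample(60:400, 1), gc = runif(1, 0.3, 0.7))
    for (min_class in c("6mer", "7mer-m8")) {
      got <- scan_sites(mature, utr_region(region),
                        seed_match_config(min_class = min_class))
      want <- brute_seed_sites(mature, region, min_class)
      if (is.null(want)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$site_class, want$site_class)
      }
    }
  }
})

test_that("site scanning is exhaustive on a 2 kb region", {
  set.seed(31)
  mature <- random_rna_str(22)
  region <- random_rna_str(2000, gc = 0.6)
  got <- scan_sites(mature, utr_region(region),
                    seed_match_config(min_class = "6mer"))
  want <- brute_seed_sites(mature, region, "6mer")
  expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want))
})

test_that("duplex scores span the documented extremes and formula", {
  cfg <- seed_match_config()
  mature <- "UGGUGAUUGGCUGCCAGGUUCA"
  # perfect full-length complement: score 1
  reg <- rc_rna(mature)
  hits <- scan_sites(mature, utr_region(reg),
                     seed_match_config(min_class = "6mer"))
  expect_gt(nrow(hits), 0)
  expect_equal(max(hits$duplex_score), 1.0)
  # 6mer with zero supplementary pairing scores the class floor
  core <- rc_rna(substr(mature, 2, 7))
  reg2 <- paste0(strrep("C", 30), core, strrep("C", 10))
  # positions opposite 13-16 are C; make sure they cannot pair (mature 13-16
  # must lack G); craft a mature with A/U there
  mat2 <- paste0("UGGUGAUUGGCU", "AUAU", "AGGUUC")
  core2 <- rc_rna(substr(mat2, 2, 7))
  reg3 <- paste0(strrep("C", 30), core2, strrep("C", 10))
  h3 <- scan_sites(mat2, utr_region(reg3), seed_match_config(min_class = "6mer"))
  h3 <- h3[h3$site_class == "6mer", ]
  expect_equal(h3$duplex_score, unname(cfg$class_base["6mer"]))
  # formula oracle on random sites
  set.seed(37)
  for (case in 1:50) {
    mature_r <- random_rna_str(22)
    region_r <- random_rna_str(300)
    hits_r <- scan_sites(mature_r, utr_region(region_r),
                         seed_match_config(min_class = "6mer"))
    for (k in seq_len(nrow(hits_r))) {
      site <- hits_r[k, ]
      k0 <- if (site$site_class %in% c("8mer", "7mer-m8")) {
        site$start + 1L
      } else {
        site$start
      }
      comp <- c(A = "U", C = "G", G = "C", U = "A")
      mt <- strsplit(mature_r, "")[[1]]
      rg <- strsplit(region_r, "")[[1]]
      frac <- mean(vapply(13:16, function(p) {
        t <- k0 + 7 - p
        t >= 1 && t <= length(rg) && rg[t] == comp[mt[p]]
      }, logical(1)))
      base <- unname(cfg$class_base[site$site_class])
      expect_equal(site$duplex_score, base + frac * (1 - base))
    }
  }
})

test_that("duplex scores are monotone in seed-class order", {
  cfg <- seed_match_config()
  expect_true(all(diff(cfg$class_base[c("6mer", "7mer-A1", "7mer-m8",
                                        "8mer")]) > 0))
})

test_that("an exact substring read corroborates its source gene", {
  set.seed(41)
  tx <- tibble::tibble(id = c("Mef2d", "Emx2"),
                       sequence = c(random_rna_str(500), random_rna_str(500)))
  read <- tibble::tibble(id = "r1", sequence = substr(tx$sequence[1], 101, 140))
  res <- corroborate_with_reads(read, tx, predicted = c("Mef2d", "Emx2"))
  expect_equal(res$corroborated, "Mef2d")
  ev <- tidy(res)
  best <- ev[ev$transcript_id == "Mef2d", ]
  expect_equal(best$subject_start, 101)
  expect_equal(best$subject_end, 140)
  expect_equal(best$identity, 1)
})

test_that("an empty read list corroborates nothing", {
  tx <- tibble::tibble(id = "g", sequence = random_rna_str(200))
  res <- corroborate_with_reads(tibble::tibble(id = character(),
                                               sequence = character()),
                                tx, predicted = "g")
  expect_equal(res$corroborated, character(0))
})

test_that("corroboration is always a subset of the predictions", {
  set.seed(43)
  tx <- tibble::tibble(id = paste0("g", 1:4),
                       sequence = replicate(4, random_rna_str(300)))
  reads <- tibble::tibble(id = paste0("r", 1:6),
                          sequence = c(substr(tx$sequence[1], 1, 40),
                                       substr(tx$sequence[2], 50, 90),
                                       substr(tx$sequence[3], 10, 60),
                                       replicate(3, random_rna_str(35))))
  res <- corroborate_with_reads(reads, tx, predicted = c("g1", "g3"))
  expect_true(all(res$corroborated %in% c("g1", "g3")))
  expect_equal(res$corroborated, c("g1", "g3"))
  expect_false("g2" %in% res$corroborated)  # aligned but not predicted
})

test_that("empty transcript sets are a validation error", {
  expect_error(
    corroborate_with_reads(tibble::tibble(id = "r", sequence = "ACGU"),
                           tibble::tibble(id = character(),
                                          sequence = character()),
                           predicted = "g"),
    "empty transcript")
})

test_that("alignment score decreases monotonically with planted mismatches", {
  set.seed(47)
  tx <- tibble::tibble(id = "g", sequence = random_rna_str(400))
  frag <- substr(tx$sequence, 201, 260)
  scores <- vapply(0:5, function(nmm) {
    s <- strsplit(frag, "")[[1]]
    if (nmm > 0) {
      at <- seq(5, 55, length.out = nmm)
      for (p in round(at)) s[p] <- setdiff(c("A", "C", "G", "U"), s[p])[1]
    }
    read <- tibble::tibble(id = "r", sequence = paste(s, collapse = ""))
    res <- corroborate_with_reads(read, tx, predicted = "g")
    res$evidence$score[1]
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
})
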