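premir1_hp <- function() fold_hairpin(premir1_seq())
mature_5p <- function() plaur_mature()$sequence[1]
mature_3p_printed <- function() plaur_mature()$sequence[2]

test_that("anchored cleavage places the 5p cut before the printed mature", {
  hp <- premir1_hp()
  cuts <- place_cleavage(hp, anchor_5p = mature_5p())
  at <- regexpr(mature_5p(), premir1_seq(), fixed = TRUE)[1]
  expect_equal(cuts$five_p_cut, at - 1L)
  expect_error(place_cleavage(hp, anchor_5p = "UUUUUGGGGGUUUUUGGGUUU"),
               "not a substring")
})

test_that("the precursor presents three motif classes with CNNC unevaluable", {
  hp <- premir1_hp()
  cuts <- place_cleavage(hp, anchor_5p = mature_5p())
  rep <- scan_motifs(hp, cuts)
  expect_equal(rep$classes_present, 3L)
  expect_false(is.na(rep$basal_ug))
  expect_false(is.na(rep$ghg))
  expect_equal(rep$apical_motif, "GUG")
  expect_equal(rep$cnnc_status, "unevaluable")
  # basal UG sits 13 +/- 3 nt basal of the 5p cut
  off <- cuts$five_p_cut + 1L - rep$basal_ug
  expect_true(off >= 10 && off <= 16)
  expect_equal(processing_score(rep), 1.0)
})

test_that("motif-free hairpins report no motifs", {
  # AU-only stem, poly-A loop: no G anywhere except none
  seq <- paste0(strrep("A", 15), "AAAA", strrep("U", 15))
  hp <- fold_hairpin(seq)
  rep <- scan_motifs(hp)
  expect_true(is.na(rep$basal_ug))
  expect_true(is.na(rep$ghg))
  expect_true(is.na(rep$apical))
  expect_equal(rep$classes_present, 0L)
})

test_that("processing_score is the present/evaluable ratio", {
  mk <- function(present, evaluable) {
    tibble::tibble(classes_present = present, classes_evaluable = evaluable)
  }
  expect_equal(processing_score(mk(0L, 4L)), 0)
  expect_equal(processing_score(mk(2L, 4L)), 0.5)
  expect_equal(processing_score(mk(3L, 3L)), 1)
  expect_equal(processing_score(mk(0L, 0L)), 0)
})

test_that("motif positions agree with a window-search oracle on random hairpins", {
  set.seed(17)
  cfg <- drosha_config()
  for (case in 1:100) {
    plant <- plant_spec(stem_length = sample(18:28, 1),
                        loop_length = sample(4:8, 1),
                        gu_fraction = 0.1, motifs = "apical")
    hp_rec <- make_hairpin(plant, seed = case)
    hp <- fold_hairpin(hp_rec$sequence)
    if (nrow(hp$pairs) == 0) next
    cuts <- tryCatch(place_cleavage(hp, cfg), error = function(e) NULL)
    if (is.null(cuts)) next
    rep <- scan_motifs(hp, cuts, cfg)
    s <- strsplit(hp$sequence, "")[[1]]
    # oracle: basal UG = any UG whose offset from the cut is in the window
    ug_hits <- which(vapply(seq_len(length(s) - 1), function(p) {
      s[p] == "U" && s[p + 1] == "G" &&
        (cuts$five_p_cut + 1 - p) >= cfg$basal_ug_offset[1] &&
        (cuts$five_p_cut + 1 - p) <= cfg$basal_ug_offset[2]
    }, logical(1)))
    expect_identical(!is.na(rep$basal_ug), length(ug_hits) > 0)
    if (!is.na(rep$basal_ug)) expect_true(rep$basal_ug %in% ug_hits)
    # oracle: apical = UGU/GUG triplet inside loop +/- 1
    lp <- hp$pairs[nrow(hp$pairs), ]
    lo <- max(1, lp[1]); hi <- min(length(s), lp[2])
    tri <- vapply(lo:(hi - 2), function(p) paste(s[p:(p + 2)], collapse = ""),
                  character(1))
    expect_identical(!is.na(rep$apical), any(tri %in% c("UGU", "GUG")))
  }
})

test_that("unanchored placement recovers a planted basal UG within the window", {
  set.seed(23)
  cfg <- drosha_config()
  hits <- 0; total <- 0
  for (case in 1:50) {
    # hairpin with planted basal UG 13 nt upstream of the intended cut
    lmk <- make_locus(n_exons = 2L, intron_lengths = 160L,
                      plant = plant_spec(stem_length = 30L, loop_length = 6L,
                                         gu_fraction = 0, motifs = "basal_ug",
                                         intron_index = 1L),
                      seed = case)
    intr <- derive_introns(lmk$locus)
    tr <- lmk$truth$plant
    # fold a window spanning the plant plus flanks
    lo <- max(1, tr$intron_start - 20)
    hi <- min(nchar(intr$sequence), tr$intron_end + 20)
    hp <- fold_hairpin(substr(intr$sequence, lo, hi))
    cuts <- tryCatch(place_cleavage(hp, cfg), error = function(e) NULL)
    if (is.null(cuts)) next
    total <- total + 1
    # truth: the intended cut in window coordinates
    truth_cut <- (tr$intron_start - 1 + 30 - 22) - lo + 1
    if (abs(cuts$five_p_cut - truth_cut) <= 3) hits <- hits + 1
  }
  expect_gte(total, 40)
  expect_gte(hits / total, 0.9)
})

test_that("duplex extraction leaves a 2-nt 3' overhang on the 3p arm", {
  hp <- premir1_hp()
  cuts <- place_cleavage(hp, anchor_5p = mature_5p())
  dup <- extract_duplex(hp, cuts)
  expect_equal(dup$overhang_3p, 2L)
  expect_false(dup$truncated)
  expect_equal(dup$five_p$sequence, mature_5p())
  # both matures are exact substrings of the precursor
  expect_true(grepl(dup$five_p$sequence, premir1_seq(), fixed = TRUE))
  expect_true(grepl(dup$three_p$sequence, premir1_seq(), fixed = TRUE))
  # arms do not overlap the loop
  ls <- c(hp$pairs[nrow(hp$pairs), 1] + 1, hp$pairs[nrow(hp$pairs), 2] - 1)
  expect_lt(dup$five_p$end, ls[1])
  expect_gt(dup$three_p$start, ls[2])
})

test_that("the printed mature 3p differs from its precursor arm at one position", {
  # the 3p arm segment aligned under the printed mature
  dup <- extract_duplex(premir1_hp(),
                        place_cleavage(premir1_hp(), anchor_5p = mature_5p()))
  printed <- mature_3p_printed()
  at <- regexpr(substr(printed, 4, 18), premir1_seq(), fixed = TRUE)[1]
  arm <- substr(premir1_seq(), at - 3, at - 4 + nchar(printed))
  expect_equal(nchar(arm), nchar(printed))
  hamming <- sum(strsplit(arm, "")[[1]] != strsplit(printed, "")[[1]])
  expect_equal(hamming, 1L)
  # and the computed 3p product covers that arm
  expect_true(grepl(arm, dup$three_p$sequence, fixed = TRUE))
})

test_that("palindromic stems cut symmetrically about the loop", {
  arm <- "GCGGCAUGCCAGGCAUCCGGAUGCAGGCUG"
  seq <- paste0(arm, "AAAA", rc_rna(arm))
  hp <- fold_hairpin(seq)
  cuts <- place_cleavage(hp, drosha_config(mature_length = 22L))
  n <- nchar(seq)
  # distance of the 5p cut from the left end equals distance of the 3p cut
  # from the right end (the 2-nt overhang shifts the 3p cut by 2)
  expect_equal(cuts$five_p_cut, n - cuts$three_p_cut + 2L)
  dup <- extract_duplex(hp, cuts)
  expect_equal(dup$overhang_3p, 2L)
  # 5p and 3p are reverse complements except the overhang
  core3 <- substr(dup$three_p$sequence, 1,
                  nchar(dup$three_p$sequence) - 2)
  expect_equal(rc_rna(core3), dup$five_p$sequence)
})

test_that("3' overhang extension holds over random planted hairpins", {
  set.seed(31)
  for (case in 1:100) {
    rec <- make_hairpin(plant_spec(stem_length = sample(22:30, 1),
                                   loop_length = sample(4:8, 1),
                                   gu_fraction = 0.1), seed = case + 1000)
    # embed with a 3' flank so extension cannot truncate
    seq <- paste0(rec$sequence, random_rna_str(6))
    hp <- fold_hairpin(seq)
    cuts <- tryCatch(place_cleavage(hp), error = function(e) NULL)
    if (is.null(cuts)) next
    dup <- extract_duplex(hp, cuts)
    if (!dup$truncated) expect_equal(dup$overhang_3p, 2L)
    expect_true(grepl(dup$five_p$sequence, seq, fixed = TRUE))
    expect_true(grepl(dup$three_p$sequence, seq, fixed = TRUE))
  }
})

test_that("anchoring on an extracted mature reproduces the same duplex", {
  hp <- premir1_hp()
  cuts1 <- place_cleavage(hp)  # unanchored
  dup1 <- extract_duplex(hp, cuts1)
  cuts2 <- place_cleavage(hp, anchor_5p = dup1$five_p$sequence)
  dup2 <- extract_duplex(hp, cuts2)
  expect_equal(dup1$five_p, dup2$five_p)
  expect_equal(dup1$three_p, dup2$three_p)
})

test_that("truncated 3p extension is flagged, not an error", {
  # hairpin flush with the 3' end: overhang runs off the precursor
  arm <- "GGGGGCCCCCGGGGG"
  seq <- paste0(arm, "AAAA", rc_rna(arm))
  hp <- fold_hairpin(seq)
  cuts <- place_cleavage(hp, drosha_config(mature_length = 15L))
  dup <- extract_duplex(hp, cuts)
  expect_true(dup$truncated)
  expect_lt(dup$overhang_3p, 2L)
})
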