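# A fixed reference used across builder tests: seeded, PAM-free background
# is irrelevant here, only coordinates matter.
builderRef <- local({
  set.seed(777)
  randomDNA(200)
})

test_that("buildPBS reverse-complements the sequence 5' of the ups nick", {
  seq <- paste0("AAAAAAAAAAAG", strrep("C", 30))
  expect_identical(buildPBS(seq, 12, 12), "CTTTTTTTTTTT")
  expect_identical(buildPBS(builderRef, 100, 12),
                   rcOracle(substr(builderRef, 89, 100)))
  expect_warning(buildPBS(builderRef, 100, 8), "below the recommended")
  expect_warning(buildPBS(builderRef, 100, 17), "above the tested range")
  expect_silent(buildPBS(builderRef, 100, 12))
  expect_error(buildPBS(builderRef, 10, 12), "beyond the locus")
  expect_error(buildPBS(builderRef, 100, 0), "positive")
})

test_that("buildES is the edit applied to the inter-nick window", {
  ups <- 100L; ext <- 137L
  # full inter-nick deletion -> empty ES
  expect_identical(buildES(builderRef, EditSpec(ups, ext, ""), ups, ext), "")
  # full inter-nick replacement -> the payload verbatim
  pay <- randomDNA(37)
  expect_identical(buildES(builderRef, EditSpec(ups, ext, pay), ups, ext),
                   pay)
  # interior replacement: ES equals the product restricted to the window
  e <- EditSpec(105, 108, "T")
  es <- buildES(builderRef, e, ups, ext)
  expect_identical(nchar(es), 35L)
  full <- productOracle(builderRef, editAtoms(e))
  expect_identical(paste0(substr(builderRef, 1, ups), es,
                          substr(builderRef, ext + 1, 200)), full)
  # edit extending past the ext nick widens the window
  e2 <- EditSpec(110, 150, randomDNA(20))
  expect_identical(esWindowEnd(e2, ext), 150L)
  expect_identical(nchar(buildES(builderRef, e2, ups, ext)), 30L)
  expect_error(buildES(builderRef, EditSpec(90, 110, ""), ups, ext),
               "upstream of the ups nick")
})

test_that("buildHS is the verbatim genomic slice after the ES window", {
  expect_identical(buildHS(builderRef, 137, 16), substr(builderRef, 138, 153))
  expect_warning(buildHS(builderRef, 137, 14), "below the recommended 16")
  expect_warning(buildHS(builderRef, 137, 10), "below the tested range")
  expect_silent(h22 <- buildHS(builderRef, 137, 22))
  expect_identical(nchar(h22), 22L)
  expect_error(buildHS(builderRef, 190, 16), "insufficient downstream")
})

test_that("mismatchFeasibility reports flanks and per-scheme maxima", {
  ups <- 100L; ext <- 137L
  # 20-nt deletion at the ups nick leaves a 17-nt retained 3' flank
  e <- EditSpec(100, 120, "")
  f <- mismatchFeasibility(e, ups, ext)
  expect_identical(f$side, "three_prime_flap")
  expect_identical(f$flank, 17L)
  expect_identical(f$maxK, 17L)
  expect_identical(mismatchFeasibility(e, ups, ext, "every3")$maxK, 6L)
  expect_identical(mismatchFeasibility(e, ups, ext, "every5")$maxK, 4L)
  # edit at the ext nick leaves a 5' flank instead
  e2 <- EditSpec(120, 137, randomDNA(5))
  f2 <- mismatchFeasibility(e2, ups, ext)
  expect_identical(f2$side, "five_prime_flap")
  expect_identical(f2$flank, 20L)
})

test_that("consecutive mismatches start nick-adjacent and use the fixed map", {
  ups <- 100L; ext <- 137L
  e <- EditSpec(100, 120, "")           # retained 3' flank = [120,137)
  es0 <- buildES(builderRef, e, ups, ext)
  mm <- introduceMismatches(es0, e, ups, ext, "consecutive", 11)
  expect_identical(nchar(mm$es), nchar(es0))
  a <- strsplit(es0, "")[[1L]]; b <- strsplit(mm$es, "")[[1L]]
  diff <- which(a != b) - 1L            # 0-based ES indices
  expect_identical(diff, 6:16)          # the 11 nick-adjacent positions
  expect_identical(mm$plan@esOffsets, 6:16)
  expect_identical(mm$plan@refPositions, 126:136)
  map <- c(A = "C", C = "A", G = "T", T = "G")
  expect_identical(b[diff + 1L], unname(map[a[diff + 1L]]))
  expect_identical(mm$plan@k, 11L)
  expect_identical(mm$plan@side, "three_prime_flap")
})

test_that("every3 / every5 schemes space mismatches from the nick-adjacent origin", {
  ups <- 100L; ext <- 137L
  e <- EditSpec(100, 120, "")
  es0 <- buildES(builderRef, e, ups, ext)
  m3 <- introduceMismatches(es0, e, ups, ext, "every3", 5)
  expect_identical(m3$plan@esOffsets, c(4L, 7L, 10L, 13L, 16L))
  expect_identical(m3$plan@refPositions, 120L + c(4L, 7L, 10L, 13L, 16L))
  m5 <- introduceMismatches(es0, e, ups, ext, "every5", 4)
  expect_identical(m5$plan@esOffsets, c(1L, 6L, 11L, 16L))
})

test_that("five-prime-flap mismatches count from the ups nick", {
  ups <- 100L; ext <- 137L
  e2 <- EditSpec(120, 137, randomDNA(5))
  es0 <- buildES(builderRef, e2, ups, ext)
  mm <- introduceMismatches(es0, e2, ups, ext, "consecutive", 4,
                            side = "five_prime_flap")
  expect_identical(mm$plan@esOffsets, 0:3)
  expect_identical(mm$plan@refPositions, 100:103)
})

test_that("infeasible mismatch requests fail with the feasible maximum", {
  ups <- 100L; ext <- 137L
  e <- EditSpec(100, 120, "")
  es0 <- buildES(builderRef, e, ups, ext)
  expect_error(introduceMismatches(es0, e, ups, ext, "consecutive", 18),
               "maximum feasible k is 17")
  # a deletion inside the flank breaks the consecutive-mapping run
  eDel <- EditSpec(c(100, 125), c(120, 128), c("", ""))
  esD <- buildES(builderRef, eDel, ups, ext)
  fD <- mismatchFeasibility(eDel, ups, ext)
  expect_identical(fD$flank, 9L)   # only [128,137) maps consecutively
  expect_error(introduceMismatches(esD, eDel, ups, ext, "consecutive", 10),
               "maximum feasible k is 9")
})

test_that("scheme none / k = 0 are identity with an empty plan", {
  ups <- 100L; ext <- 137L
  e <- EditSpec(100, 120, "")
  es0 <- buildES(builderRef, e, ups, ext)
  r <- introduceMismatches(es0, e, ups, ext, "none")
  expect_identical(r$es, es0)
  expect_identical(r$plan@k, 0L)
  r0 <- introduceMismatches(es0, e, ups, ext, "consecutive", 0)
  expect_identical(r0$es, es0)
})

test_that("mismatched ES stays alignable: Hamming distance equals k", {
  ups <- 100L; ext <- 137L
  e <- EditSpec(100, 120, "")
  es0 <- buildES(builderRef, e, ups, ext)
  for (k in 1:17) {
    mm <- introduceMismatches(es0, e, ups, ext, "consecutive", k)
    a <- strsplit(es0, "")[[1L]]; b <- strsplit(mm$es, "")[[1L]]
    expect_identical(sum(a != b), as.integer(k))
  }
})

test_that("assembleExtPegRNA composes the documented layout", {
  spacer <- randomDNA(20); es <- randomDNA(37); hs <- randomDNA(16)
  pbs <- randomDNA(12)
  peg <- assembleExtPegRNA(spacer, SGRNA_SCAFFOLD, es, hs, pbs)
  expect_identical(peg@full, paste0(spacer, SGRNA_SCAFFOLD, rcOracle(hs),
                                    rcOracle(es), pbs))
  expect_identical(nchar(peg@full),
                   20L + nchar(SGRNA_SCAFFOLD) + 37L + 16L + 12L)
  # RTT = revcomp(ES + HS) immediately 5' of the PBS
  rtt <- substr(peg@full, 21L + nchar(SGRNA_SCAFFOLD),
                nchar(peg@full) - 12L)
  expect_identical(rtt, rcOracle(paste0(es, hs)))
  # empty ES (full inter-nick deletion) is legal
  peg0 <- assembleExtPegRNA(spacer, SGRNA_SCAFFOLD, "", hs, pbs)
  expect_identical(peg0@full, paste0(spacer, SGRNA_SCAFFOLD, rcOracle(hs),
                                     pbs))
  expect_error(assembleExtPegRNA("", SGRNA_SCAFFOLD, es, hs, pbs),
               "empty spacer")
})

test_that("assemble/decode round-trips over random components", {
  set.seed(808)
  for (i in 1:1000) {
    spacer <- randomDNA(20)
    es <- randomDNA(sample(0:90, 1L))
    hs <- randomDNA(sample(12:22, 1L))
    pbs <- randomDNA(sample(9:16, 1L))
    peg <- assembleExtPegRNA(spacer, SGRNA_SCAFFOLD, es, hs, pbs)
    d <- decodeExtPegRNA(peg@full, SGRNA_SCAFFOLD, nchar(es), nchar(hs),
                         nchar(pbs))
    expect_identical(d, list(spacer = spacer, es = es, hs = hs, pbs = pbs))
  }
  expect_error(decodeExtPegRNA("ACGT", SGRNA_SCAFFOLD, 10, 16, 12),
               "length")
})

test_that("buildSgRNA encodes spacer + scaffold with optional U6 G", {
  expect_identical(buildSgRNA("ACGTACGTACGTACGTACGT"),
                   paste0("ACGTACGTACGTACGTACGT", SGRNA_SCAFFOLD))
  expect_identical(substr(buildSgRNA("ACGTACGTACGTACGTACGT", u6G = TRUE),
                          1, 2), "GA")
  expect_identical(substr(buildSgRNA("GCGTACGTACGTACGTACGT", u6G = TRUE),
                          1, 2), "GC")   # already starts with G
})

test_that("toRNA substitutes U for T", {
  expect_identical(toRNA("GATTACA"), "GAUUACA")
})
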