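test_that("alignGlobal handles trivial cases with the fixed scheme", {
  r <- alignGlobal("ACGT", "ACGT")
  expect_identical(r$score, 4)
  expect_identical(r$a, "ACGT")
  expect_identical(r$b, "ACGT")
  r2 <- alignGlobal("ACGT", "AGT")
  expect_identical(r2$score, 1)       # 3 matches + 1 gap
  expect_identical(r2$a, "ACGT")
  expect_identical(nchar(r2$b), 4L)
  expect_identical(gsub("-", "", r2$b, fixed = TRUE), "AGT")
  expect_error(alignGlobal("", "ACGT"), "empty")
  # deterministic: identical calls give identical tracebacks
  expect_identical(alignGlobal("AAGG", "AG"), alignGlobal("AAGG", "AG"))
})

test_that("aligned strings reconstruct their inputs", {
  set.seed(111)
  for (i in 1:100) {
    a <- randomDNA(sample(1:30, 1L)); b <- randomDNA(sample(1:30, 1L))
    r <- alignGlobal(a, b)
    expect_identical(gsub("-", "", r$a, fixed = TRUE), a)
    expect_identical(gsub("-", "", r$b, fixed = TRUE), b)
    expect_identical(nchar(r$a), nchar(r$b))
    expect_identical(alignGlobal(a, a)$score, as.numeric(nchar(a)))
  }
})

test_that("alignGlobal equals the exhaustive enumeration oracle (short strings)", {
  set.seed(222)
  for (i in 1:60) {
    a <- randomDNA(sample(1:8, 1L)); b <- randomDNA(sample(1:8, 1L))
    expect_identical(alignGlobal(a, b)$score, nwEnumScore(a, b))
  }
})

test_that("alignGlobal scores match Biostrings global alignment", {
  set.seed(333)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (i in 1:40) {
    a <- randomDNA(sample(5:40, 1L)); b <- randomDNA(sample(5:40, 1L))
    bs <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2)
    expect_identical(alignGlobal(a, b)$score, Biostrings::score(bs))
  }
})

# Classification fixture: planted pair at 80/117 on a 200-bp locus,
# 10 -> 3 nt replacement (edit region [80, 117) on the reference).
quantRef <- locusSeq(makePairedLocus(5, 200, 80, 37))
quantEdit <- EditSpec(85, 95, "TTT")
quantUps <- 80L
quantEsEnd <- 117L
quantEdited <- applyEdit(quantRef, quantEdit)

test_that("classifyRead assigns the five outcome classes", {
  expect_identical(classifyRead(quantEdited, quantRef, quantEdited,
                                quantUps, quantEsEnd), "intended")
  expect_identical(classifyRead(quantRef, quantRef, quantEdited,
                                quantUps, quantEsEnd), "unedited")
  # 4-nt deletion at the ext nick on a reference read
  del <- paste0(substr(quantRef, 1, 117), substr(quantRef, 122, 200))
  expect_identical(classifyRead(del, quantRef, quantEdited,
                                quantUps, quantEsEnd), "indel")
  # a read covering only sequence downstream of the window
  expect_identical(classifyRead(substr(quantRef, 140, 200), quantRef,
                                quantEdited, quantUps, quantEsEnd),
                   "unassigned")
  expect_identical(classifyRead("", quantRef, quantEdited, quantUps,
                                quantEsEnd), "unassigned")
  # substitution inside the edit region matching neither allele
  ch <- strsplit(quantRef, "")[[1L]]
  ch[101] <- setdiff(c("A", "C", "G", "T"), ch[101])[1L]
  expect_identical(classifyRead(paste(ch, collapse = ""), quantRef,
                                quantEdited, quantUps, quantEsEnd),
                   "substituted")
})

test_that("engineered mismatches are part of the intended product", {
  mmEdit <- EditSpec(80, 100, "")      # leaves a 17-nt retained 3' flank
  es0 <- buildES(quantRef, mmEdit, 80, 117)
  mm <- introduceMismatches(es0, mmEdit, 80, 117, "consecutive", 11)
  edited <- predictProduct(quantRef, mmEdit, mm$plan)
  expect_identical(classifyRead(edited, quantRef, edited, 80L, 117L),
                   "intended")
  # the mismatch-free edit product is NOT the intended allele (nor unedited)
  plain <- applyEdit(quantRef, mmEdit)
  expect_false(classifyRead(plain, quantRef, edited, 80L, 117L) %in%
                 c("intended", "unedited"))
})

test_that("sequencing noise outside the edit region does not demote reads", {
  # flip a base well downstream of the window
  ch <- strsplit(quantEdited, "")[[1L]]
  ch[170] <- setdiff(c("A", "C", "G", "T"), ch[170])[1L]
  expect_identical(classifyRead(paste(ch, collapse = ""), quantRef,
                                quantEdited, quantUps, quantEsEnd),
                   "intended")
})

test_that("quantifyReads computes the documented statistics exactly", {
  del <- paste0(substr(quantRef, 1, 80), substr(quantRef, 84, 200))
  reads <- c(rep(quantEdited, 40), rep(del, 5), rep(quantRef, 55))
  q <- quantifyReads(reads, quantRef, quantEdited, quantUps, quantEsEnd)
  expect_identical(readCounts(q),
                   c(total = 100L, intended = 40L, indel = 5L,
                     unedited = 55L, substituted = 0L, unassigned = 0L))
  expect_identical(efficiency(q), 40)
  expect_identical(indelRate(q), 5)
  expect_identical(productPurity(q), 8)
  qInf <- quantifyReads(rep(quantEdited, 10), quantRef, quantEdited,
                        quantUps, quantEsEnd)
  expect_identical(productPurity(qInf), Inf)
  expect_error(quantifyReads(character(), quantRef, quantEdited,
                             quantUps, quantEsEnd), "empty read set")
})

test_that("foldChange rounds half-up and guards its domain", {
  expect_identical(foldChange(9.13, 0.23), 39.7)
  expect_identical(foldChange(3.22, 0.07, 0), 46)
  expect_identical(foldChange(6.1, 0.05), 122)
  expect_identical(foldChange(5, 5), 1)
  expect_identical(foldChange(0.25, 1), 0.3)   # half-up, not banker's
  expect_warning(fc <- foldChange(3, 0), "zero control")
  expect_true(is.na(fc))
  expect_error(foldChange(-1, 2), "non-negative")
})

test_that("readReads handles FASTQ and FASTA with quality filtering", {
  reads <- c(r1 = substr(quantRef, 1, 40), r2 = substr(quantRef, 41, 80))
  fq <- tempfile(fileext = ".fastq")
  writeReadsFastq(reads, fq)
  back <- readReads(fq)
  expect_identical(back, reads)
  fa <- tempfile(fileext = ".fasta")
  writeFasta(reads, fa)
  expect_identical(readReads(fa), reads)
  # hand-written FASTQ with one low-quality read
  fq2 <- tempfile(fileext = ".fq")
  writeLines(c("@good", "ACGTACGT", "+", strrep("I", 8),   # Q40
               "@bad", "ACGTACGT", "+", strrep("#", 8)), fq2)  # Q2
  kept <- readReads(fq2, minMeanQ = 20)
  expect_identical(names(kept), "good")
  expect_identical(length(readReads(fq2)), 2L)
})

test_that("quantifyDesign recovers planted fractions from a design", {
  locus <- makePairedLocus(42, 400, 150, 37)
  set.seed(4242)
  e <- EditSpec(150, 165, randomDNA(37))
  d <- suppressMessages(designEdits(locus, e))$designs[[1L]]
  reads <- simulateReads(locusSeq(locus), predictedAllele(d), 200,
                         0.30, 0.05, 0.65, d@ups$nick, d@esEnd, seed = 7)
  q <- quantifyDesign(reads, locus, d)
  expect_identical(readCounts(q)[["intended"]], 60L)
  expect_identical(readCounts(q)[["indel"]], 10L)
  expect_identical(readCounts(q)[["unedited"]], 130L)
  expect_identical(efficiency(q), 30)
  expect_identical(indelRate(q), 5)
  expect_identical(productPurity(q), 6)
})

test_that("writeQuantResult emits schema-stable JSON and TSV", {
  q <- quantifyReads(c(rep(quantEdited, 3), quantRef), quantRef,
                     quantEdited, quantUps, quantEsEnd)
  pj <- tempfile(fileext = ".json")
  writeQuantResult(q, pj, meta = list(seed = 1729L))
  j <- jsonlite::fromJSON(pj)
  expect_identical(j$total, 4L)
  expect_identical(j$intended, 3L)
  expect_equal(j$efficiency_pct, 75)
  expect_identical(j$purity, "Inf")
  expect_identical(j$meta$seed, 1729L)
  pt <- tempfile(fileext = ".tsv")
  writeQuantResult(q, pt)
  tab <- read.delim(pt)
  expect_identical(tab$unedited, 1L)
  expect_equal(tab$indel_rate_pct, 0)
})
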