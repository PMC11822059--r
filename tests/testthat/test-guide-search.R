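test_that("a single planted forward site is found with the right geometry", {
  seq <- "ACGTACGTACGTACGTACGTAGGTT"   # protospacer [0,20), PAM AGG at [20,23)
  s <- findGuideSites(seq)
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "+")
  expect_identical(s$start, 0L)
  expect_identical(s$end, 20L)
  expect_identical(s$nick, 17L)
  expect_identical(s$pam, "AGG")
  expect_identical(s$spacer, "ACGTACGTACGTACGTACGT")
})

test_that("reverse-strand sites report spacer/PAM in their own frame", {
  # CC at [5,7) => reverse PAM; protospacer working interval [8,28)
  seq <- paste0("AAATA", "CCT", "ATATATATATATATATATAT", "AAAAA")
  s <- findGuideSites(seq, "reverse")
  expect_identical(nrow(s), 1L)
  expect_identical(s$strand, "-")
  expect_identical(s$start, 8L)
  expect_identical(s$nick, 11L)
  expect_identical(s$pam, rcOracle(substr(seq, 6, 8)))   # AGG
  expect_identical(s$spacer, rcOracle(substr(seq, 9, 28)))
})

test_that("PAM-free and too-short inputs behave as documented", {
  expect_identical(nrow(findGuideSites(strrep("A", 50))), 0L)
  expect_warning(s <- findGuideSites("ACGTACGT"), "shorter than 23")
  expect_identical(nrow(s), 0L)
})

test_that("overlapping PAMs are all found (all-G locus)", {
  s <- findGuideSites(strrep("G", 40), "forward")
  expect_identical(s$start, 0:17)
  expect_identical(s$nick, 0:17 + 17L)
  expect_true(all(s$pam == "GGG"))
  expect_identical(nrow(findGuideSites(strrep("G", 40), "reverse")), 0L)
})

test_that("site enumeration matches the exhaustive oracle on random loci", {
  set.seed(404)
  for (i in 1:500) {
    seq <- randomDNA(300)
    s <- findGuideSites(seq)
    o <- siteOracle(seq)
    expect_identical(sort(s$start[s$strand == "+"]), o$fwdStarts)
    expect_identical(sort(s$start[s$strand == "-"]), o$revStarts)
    # per-site field consistency
    expect_identical(s$nick,
                     ifelse(s$strand == "+", s$start + 17L, s$start + 3L))
    expect_true(all(s$end - s$start == 20L))
    expect_true(all(substr(s$pam, 2L, 3L) == "GG"))
    fwd <- s$strand == "+"
    expect_identical(s$spacer[fwd],
                     substr(rep(seq, sum(fwd)), s$start[fwd] + 1L,
                            s$end[fwd]))
  }
})

test_that("site enumeration is strand-symmetric", {
  set.seed(505)
  for (i in 1:50) {
    seq <- randomDNA(150)
    L <- nchar(seq)
    s <- findGuideSites(seq)
    sRC <- findGuideSites(rcOracle(seq))
    # a forward site [a,b) on the revcomp is a reverse site [L-b, L-a)
    expect_setequal(L - sRC$end[sRC$strand == "+"],
                    s$start[s$strand == "-"])
    expect_setequal(L - sRC$end[sRC$strand == "-"],
                    s$start[s$strand == "+"])
  }
})

mkSites <- function(nicks, strand = "+") {
  data.frame(spacer = vapply(seq_along(nicks),
                             function(i) paste(rep(LETTERS[1L], 20),
                                               collapse = ""), ""),
             pam = "AGG", strand = strand, start = nicks - 17L,
             end = nicks + 3L, nick = as.integer(nicks),
             stringsAsFactors = FALSE)
}

test_that("pairGuides accepts in-window DCNs and applies the hard floor", {
  edit <- EditSpec(60, 70, "")
  p <- pairGuides(mkSites(c(60, 97)), edit)
  expect_identical(nrow(p), 1L)
  expect_identical(p$dcn, 37L)
  expect_identical(p$upsNick, 60L)
  expect_identical(p$extNick, 97L)
  # hard floor: DCN 24 rejected even when the window would admit it
  expect_identical(nrow(pairGuides(mkSites(c(60, 84)), edit,
                                   dcnWindow = c(20L, 40L),
                                   dcnHardMin = 25L)), 0L)
  # DCN 25 passes the floor but sits outside the default window
  expect_message(p25 <- pairGuides(mkSites(c(60, 85)), edit),
                 "nearest achievable DCNs: 25")
  expect_identical(nrow(p25), 0L)
  expect_identical(attr(p25, "nearestDCNs"), 25L)
  # relaxing the window admits a DCN of 50
  expect_identical(nrow(pairGuides(mkSites(c(60, 110)), edit)), 0L)
  expect_identical(pairGuides(mkSites(c(60, 110)), edit,
                              dcnWindow = c(32L, 71L))$dcn, 50L)
})

test_that("pairGuides rejects uneditable geometry and mixed strands", {
  expect_error(pairGuides(mkSites(c(60, 97)), EditSpec(10, 20, "")),
               "uneditable geometry")
  mixed <- rbind(mkSites(60), mkSites(97, "-"))
  expect_error(pairGuides(mixed, EditSpec(60, 70, "")), "one strand")
})

test_that("pairGuides allows edits extending past the ext nick", {
  p <- pairGuides(mkSites(c(60, 97)), EditSpec(60, 120, "ACGT"))
  expect_identical(p$dcn, 37L)
})

test_that("every emitted pair satisfies the geometry inequalities", {
  set.seed(606)
  for (i in 1:50) {
    nicks <- sort(sample(30:260, sample(3:7, 1L)))
    p <- suppressMessages(
      pairGuides(mkSites(nicks), EditSpec(min(nicks), min(nicks) + 5L, ""),
                 dcnWindow = c(25L, 96L)))
    if (!nrow(p)) next
    expect_true(all(p$dcn == p$extNick - p$upsNick))
    expect_true(all(p$dcn >= 25L & p$dcn <= 96L))
    expect_true(all(p$upsNick <= min(nicks)))
  }
})

test_that("findHelperSites enforces separation and sorts by midpoint", {
  sites <- mkSites(c(30, 50, 80))
  pair <- list(upsNick = 0L, extNick = 110L, strand = "+")
  h <- findHelperSites(sites, pair, minSeparation = 25L)
  # midpoint 55: nick 50 closest; 30 and 80 tie at 25 -> lower nick first
  expect_identical(h$nick, c(50L, 30L, 80L))
  # a 40-nt DCN leaves no room at 25-nt separation
  expect_identical(nrow(findHelperSites(sites, list(upsNick = 20L,
                                                    extNick = 60L,
                                                    strand = "+"))), 0L)
})

test_that("writeGuideBed writes importable BED with spacer and nick features", {
  locus <- makePairedLocus(7, 300, 100, 37)
  sites <- findGuideSites(locus, "forward")
  p <- tempfile(fileext = ".bed")
  writeGuideBed(sites, locus, p)
  gr <- rtracklayer::import(p)
  expect_identical(length(gr), 2L * nrow(sites))
  sp <- gr[grepl("^spacer", gr$name)]
  expect_identical(sort(GenomicRanges::start(sp)) - 1L, sort(sites$start))
  nk <- gr[grepl("^nick", gr$name)]
  expect_identical(sort(GenomicRanges::start(nk)) - 1L, sort(sites$nick))
  expect_true(all(GenomicRanges::width(nk) == 1L))
})
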