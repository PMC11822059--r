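# Independent oracles and fixture builders. These deliberately avoid the
# package's own implementations (different algorithms / data layouts) so
# agreement is evidence, not tautology.

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# reverse complement via per-character vector ops (not Biostrings)
rcOracle <- function(s) {
  if (!nzchar(s)) return("")
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Exhaustive NGG window scan on both strands, character-by-character.
siteOracle <- function(seq) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  fwd <- integer(); rev <- integer()
  for (s in 0:(L - 23L)) {
    if (s < 0) next
    if (ch[s + 22L] == "G" && ch[s + 23L] == "G") fwd <- c(fwd, s)
  }
  for (j in 0:(L - 23L)) {
    if (ch[j + 1L] == "C" && ch[j + 2L] == "C") rev <- c(rev, j + 3L)
  }
  list(fwdStarts = fwd, revStarts = rev)
}

# Exhaustive enumeration of all global alignments by recursion (no DP
# insight beyond move decomposition); feasible for lengths <= 8.
nwEnumScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# Independent product-allele surgery on character vectors, including the
# mismatch overlay, tracking product coordinates explicitly.
productOracle <- function(refSeq, atoms, mismatchRefPos = integer()) {
  ch <- strsplit(refSeq, "", fixed = TRUE)[[1L]]
  subMap <- c(A = "C", C = "A", G = "T", T = "G")
  pieces <- list()
  pos <- 0L
  atoms <- atoms[order(atoms$start, atoms$end), , drop = FALSE]
  for (i in seq_len(nrow(atoms))) {
    if (atoms$start[i] > pos)
      pieces[[length(pieces) + 1L]] <-
        data.frame(base = ch[(pos + 1L):atoms$start[i]],
                   ref = pos:(atoms$start[i] - 1L))
    if (nzchar(atoms$payload[i]))
      pieces[[length(pieces) + 1L]] <-
        data.frame(base = strsplit(atoms$payload[i], "", fixed = TRUE)[[1L]],
                   ref = NA_integer_)
    pos <- atoms$end[i]
  }
  if (pos < length(ch))
    pieces[[length(pieces) + 1L]] <-
      data.frame(base = ch[(pos + 1L):length(ch)],
                 ref = pos:(length(ch) - 1L))
  prod <- do.call(rbind, pieces)
  hit <- !is.na(prod$ref) & prod$ref %in% mismatchRefPos
  prod$base[hit] <- unname(subMap[prod$base[hit]])
  paste(prod$base, collapse = "")
}

# Directly-constructed PegDesign for scoring tests (bypasses the pipeline
# so individual fields can be set freely).
fakeDesign <- function(dcn = 37L, pbsLen = 12L, hsLen = 16L, esLen = 30L,
                       scheme = "consecutive", k = 0L, flank3 = 0L,
                       helper = FALSE, netInsertion = 0L,
                       upsNick = 100L) {
  extNick <- upsNick + dcn
  spacerU <- paste(rep("A", 20), collapse = "")
  spacerE <- paste(rep("C", 20), collapse = "")
  mkSite <- function(spacer, nick)
    data.frame(spacer = spacer, pam = "AGG", strand = "+",
               start = nick - 17L, end = nick + 3L, nick = nick,
               stringsAsFactors = FALSE)
  es <- paste(rep(c("A", "C", "G"), length.out = esLen), collapse = "")
  hs <- paste(rep(c("T", "A"), length.out = hsLen), collapse = "")
  pbs <- paste(rep(c("G", "C"), length.out = pbsLen), collapse = "")
  plan <- if (k > 0L)
    new("MismatchPlan", scheme = scheme, k = as.integer(k),
        side = "three_prime_flap", esOffsets = as.integer(seq_len(k) - 1L),
        refPositions = as.integer(extNick - seq_len(k)))
  else new("MismatchPlan")
  peg <- assembleExtPegRNA(spacerE, SGRNA_SCAFFOLD, es, hs, pbs, plan)
  # an edit consistent with the requested retained 3' flank / net insertion
  payloadLen <- max(1L, dcn - flank3 + netInsertion)
  edit <- EditSpec(upsNick, upsNick + dcn - flank3,
                   paste(rep("A", payloadLen), collapse = ""))
  new("PegDesign", locusName = "fake", strand = "+",
      ups = mkSite(spacerU, upsNick), ext = mkSite(spacerE, extNick),
      helper = if (helper) mkSite(paste(rep("G", 20), collapse = ""),
                                  upsNick + dcn %/% 2L)
               else data.frame(),
      pegRNA = peg, upsSgRNA = buildSgRNA(spacerU),
      helperSgRNA = if (helper) buildSgRNA(paste(rep("G", 20),
                                                 collapse = ""))
                    else character(),
      dcn = as.integer(dcn), editNickDistance3p = as.integer(flank3),
      editNickDistance5p = 0L, esEnd = as.integer(extNick), edit = edit,
      score = NA_real_, flags = character(), predictedAllele = "")
}

# Random edit generator for oracle-equivalence sweeps: one of deletion /
# replacement / insertion / both-sides compound, anchored at the ups nick
# region of a planted pair.
randomEdit <- function(upsNick, extNick, locusLen) {
  type <- sample(c("del", "repl", "ins", "compound"), 1L)
  maxDown <- locusLen - 30L - extNick  # leave HS + margin downstream
  if (type == "del") {
    size <- sample(1:88, 1L)
    start <- upsNick + sample(0:5, 1L)
    end <- min(start + size, extNick + max(0L, maxDown))
    EditSpec(start, end, "", label = "del")
  } else if (type == "repl") {
    size <- sample(1:88, 1L)
    start <- upsNick + sample(0:5, 1L)
    end <- min(start + size, extNick + max(0L, maxDown))
    EditSpec(start, end, randomDNA(sample(1:88, 1L)), label = "repl")
  } else if (type == "ins") {
    pos <- upsNick + sample(0:(extNick - upsNick), 1L)
    EditSpec(pos, pos, randomDNA(sample(1:100, 1L)), label = "ins")
  } else {
    # one atom upstream of the ext nick, one at/after it
    mid <- upsNick + (extNick - upsNick) %/% 2L
    a1End <- sample(seq(upsNick + 1L, mid), 1L)
    a2Start <- extNick + sample(0:3, 1L)
    a2End <- min(a2Start + sample(1:10, 1L), extNick + max(1L, maxDown))
    EditSpec(c(upsNick, a2Start), c(a1End, a2End),
             c(randomDNA(sample(1:20, 1L)), randomDNA(sample(1:10, 1L))),
             label = "compound")
  }
}
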