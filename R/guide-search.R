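## SpCas9 NGG guide-site enumeration and cis-nick pairing.
##
## A guide site is reported as a one-row record with the protospacer
## interval [start, end) on the working strand, the spacer and PAM in the
## site's own strand frame, and the nick index converted to working-strand
## coordinates. The H840A nickase cuts the PAM-containing strand between
## protospacer positions 17 and 18 (3 nt 5' of the PAM), so a forward site
## starting at s nicks at s + 17 and a reverse site whose protospacer
## occupies working interval [s, s+20) nicks at s + 3.

.emptySites <- function() {
  data.frame(spacer = character(), pam = character(), strand = character(),
             start = integer(), end = integer(), nick = integer(),
             stringsAsFactors = FALSE)
}

#' Enumerate SpCas9 NGG guide sites on a locus
#'
#' Exhaustively scans for 20-nt protospacers immediately followed by an NGG
#' PAM on the requested strand(s). Reverse-strand sites are reported in the
#' reverse-strand frame (spacer and PAM as read on that strand) with the
#' nick converted to a working-strand index.
#'
#' @param locus A [Locus-class] or DNA string.
#' @param strand `"forward"`, `"reverse"` or `"both"`.
#' @return data.frame with columns `spacer`, `pam`, `strand` (`"+"`/`"-"`),
#'   `start`, `end` (protospacer interval, 0-based half-open, working
#'   strand) and `nick` (working-strand index).
#' @export
findGuideSites <- function(locus, strand = c("both", "forward", "reverse")) {
  strand <- match.arg(strand)
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  L <- nchar(seq)
  if (L < 23L) {
    warning("locus shorter than 23 nt; no guide site possible")
    return(.emptySites())
  }
  res <- list()
  if (strand %in% c("both", "forward")) {
    # GG at 0-based positions g, g+1 => PAM [g-1, g+2), protospacer start g-21
    gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1L]]
    gg <- if (gg[1L] == -1L) integer() else as.integer(gg) - 1L
    s <- gg - 21L
    s <- s[s >= 0L & s + 23L <= L]
    if (length(s))
      res$fwd <- data.frame(
        spacer = vapply(s, function(i) .slice(seq, i, i + 20L), ""),
        pam = vapply(s, function(i) .slice(seq, i + 20L, i + 23L), ""),
        strand = "+", start = s, end = s + 20L, nick = s + 17L,
        stringsAsFactors = FALSE)
  }
  if (strand %in% c("both", "reverse")) {
    # CC at 0-based positions j, j+1 => reverse-strand PAM is
    # revcomp([j, j+3)); protospacer occupies working [j+3, j+23)
    cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1L]]
    cc <- if (cc[1L] == -1L) integer() else as.integer(cc) - 1L
    j <- cc[cc >= 0L & cc + 23L <= L]
    if (length(j))
      res$rev <- data.frame(
        spacer = vapply(j, function(i) revcomp(.slice(seq, i + 3L, i + 23L)),
                        ""),
        pam = vapply(j, function(i) revcomp(.slice(seq, i, i + 3L)), ""),
        strand = "-", start = j + 3L, end = j + 23L, nick = j + 6L,
        stringsAsFactors = FALSE)
  }
  if (!length(res)) return(.emptySites())
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair guide sites into ups-sgRNA / ext-pegRNA cis-nick candidates
#'
#' Builds all ordered same-strand pairs whose distance between cis nicks
#' (DCN = ext nick - ups nick) clears the hard floor and falls inside the
#' window, and for which no edit atom starts upstream of the ups nick
#' (edits may extend downstream of the ext nick: both-sides edits).
#'
#' The default window `[32, 40]` is the empirical optimum at endogenous
#' loci; editing is detectable over a much wider reporter-derived range, so
#' the window may be relaxed up to 96 nt. DCNs of 24 nt or shorter are
#' always rejected (steric hindrance between adjacent nickases).
#'
#' @param sites Guide-site data.frame from [findGuideSites()]; all rows must
#'   share one strand.
#' @param edit [EditSpec-class] in the same (working-strand) frame.
#' @param dcnWindow Integer `c(min, max)` soft window, default `c(32, 40)`.
#' @param dcnHardMin Hard minimum DCN, default 25.
#' @return data.frame of pairs (columns `upsSpacer`, `upsPam`, `upsStart`,
#'   `upsNick`, `extSpacer`, `extPam`, `extStart`, `extNick`, `strand`,
#'   `dcn`). When no pair falls in the window the result is empty with an
#'   attribute `"nearestDCNs"` listing the closest achievable DCNs.
#' @export
pairGuides <- function(sites, edit, dcnWindow = c(32L, 40L),
                       dcnHardMin = 25L) {
  stopifnot(is.data.frame(sites))
  if (nrow(sites) && length(unique(sites$strand)) > 1L)
    stop("sites must share one strand (cis nicks); filter by strand first")
  atoms <- editAtoms(edit)
  empty <- data.frame(upsSpacer = character(), upsPam = character(),
                      upsStart = integer(), upsNick = integer(),
                      extSpacer = character(), extPam = character(),
                      extStart = integer(), extNick = integer(),
                      strand = character(), dcn = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sites) < 2L) return(empty)
  editStart <- min(atoms$start)
  if (all(sites$nick > editStart))
    stop("uneditable geometry: an edit atom lies upstream of every ",
         "candidate ups nick")
  ok <- sites$nick <= editStart   # candidate ups sites
  ups <- which(ok)
  rows <- list(); allDcns <- integer()
  for (i in ups) for (j in seq_len(nrow(sites))) {
    d <- sites$nick[j] - sites$nick[i]
    if (d <= 0L) next
    if (d < dcnHardMin) next
    allDcns <- c(allDcns, d)
    if (d < dcnWindow[1L] || d > dcnWindow[2L]) next
    rows[[length(rows) + 1L]] <- data.frame(
      upsSpacer = sites$spacer[i], upsPam = sites$pam[i],
      upsStart = sites$start[i], upsNick = sites$nick[i],
      extSpacer = sites$spacer[j], extPam = sites$pam[j],
      extStart = sites$start[j], extNick = sites$nick[j],
      strand = sites$strand[i], dcn = d, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    if (length(allDcns)) {
      near <- sort(unique(allDcns))
      near <- near[order(pmin(abs(near - dcnWindow[1L]),
                              abs(near - dcnWindow[2L])))]
      attr(empty, "nearestDCNs") <- head(near, 5L)
      message("no guide pair with DCN in [", dcnWindow[1L], ",",
              dcnWindow[2L], "]; nearest achievable DCNs: ",
              paste(head(near, 5L), collapse = ", "))
    }
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(abs(out$dcn - mean(dcnWindow)), out$extNick), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find Helper-gRNA candidates between the two cis nicks
#'
#' For large edits a third same-strand nick in the middle region between the
#' ups-sgRNA and ext-pegRNA nicks improves efficiency. Candidates must keep
#' at least `minSeparation` nt from both flanking nicks (mirroring the DCN
#' floor) and are returned closest-to-the-midpoint first.
#'
#' @param sites Guide-site data.frame (same strand as the pair).
#' @param pair One pair: a one-row data.frame (or list) with `upsNick`,
#'   `extNick` and `strand`.
#' @param minSeparation Minimum distance to either flanking nick, nt.
#' @return Guide-site data.frame sorted by distance from the midpoint
#'   (empty when nothing fits).
#' @export
findHelperSites <- function(sites, pair, minSeparation = 25L) {
  upsNick <- as.integer(pair$upsNick); extNick <- as.integer(pair$extNick)
  keep <- sites$strand == pair$strand &
    sites$nick >= upsNick + minSeparation &
    sites$nick <= extNick - minSeparation
  out <- sites[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  mid <- (upsNick + extNick) / 2
  out <- out[order(abs(out$nick - mid), out$nick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export guide sites and nick points as BED
#'
#' Writes protospacer intervals (feature name `spacer`) and 1-bp nick
#' features (`nick`) in 0-based half-open BED coordinates.
#'
#' @param sites Guide-site data.frame.
#' @param locus [Locus-class] the sites were found on.
#' @param path Output BED path.
#' @export
writeGuideBed <- function(sites, locus, path) {
  off <- locus@originOffset
  gr <- GenomicRanges::GRanges(
    seqnames = locusName(locus),
    ranges = IRanges::IRanges(
      start = c(sites$start, sites$nick) + off + 1L,
      end = c(sites$end, sites$nick + 1L) + off),
    strand = c(sites$strand, sites$strand),
    name = c(paste0("spacer_", seq_len(nrow(sites))),
             paste0("nick_", seq_len(nrow(sites)))),
    score = 0L)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
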