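## Seeded synthetic loci with planted guide geometry and synthetic read
## sets with known outcome composition, so the whole pipeline is testable
## without any external data.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Random background free of GG and CC dinucleotides, so the only NGG PAMs
# on either strand are the planted ones.
.pamFreeBackground <- function(len) {
  bases <- c("A", "C", "G", "T")
  out <- character(len)
  prev <- ""
  for (i in seq_len(len)) {
    allowed <- setdiff(bases, prev[prev %in% c("G", "C")])
    out[i] <- sample(allowed, 1L)
    prev <- out[i]
  }
  out
}

#' Generate a synthetic locus with planted guide sites
#'
#' The background is seeded-random DNA free of GG/CC dinucleotides, so no
#' NGG PAM exists on either strand except where planted. A forward
#' planting at protospacer start `s` writes an AGG PAM at `[s+20, s+23)`
#' (nick at `s + 17`); a reverse planting writes a CCT triplet at
#' `[s-3, s)` (nick at `s + 3`). Bases adjacent to a planted PAM are
#' adjusted so planting never creates an unintended overlapping PAM.
#' Re-running with the same seed is byte-identical.
#'
#' @param seed Integer RNG seed.
#' @param length Locus length (>= rightmost planting + 23).
#' @param plantings data.frame with columns `strand` (`"+"`/`"-"`) and
#'   `start` (0-based protospacer start on the working strand).
#' @param name Locus name.
#' @return A [Locus-class].
#' @export
makeLocus <- function(seed, length, plantings, name = "synthetic_locus") {
  stopifnot(is.data.frame(plantings), nrow(plantings) >= 1L)
  length <- as.integer(length)
  for (i in seq_len(nrow(plantings))) {
    s <- plantings$start[i]
    lo <- if (plantings$strand[i] == "+") s else s - 3L
    hi <- if (plantings$strand[i] == "+") s + 23L else s + 20L
    if (lo < 0L || hi > length)
      stop("infeasible planting: site ", i, " outside the locus")
  }
  if (nrow(plantings) > 1L) {
    iv <- cbind(ifelse(plantings$strand == "+", plantings$start,
                       plantings$start - 3L),
                ifelse(plantings$strand == "+", plantings$start + 23L,
                       plantings$start + 20L))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      stop("infeasible planting: sites overlap")
  }
  chars <- .withSeed(seed, .pamFreeBackground(length))
  for (i in seq_len(nrow(plantings))) {
    s <- plantings$start[i]
    if (plantings$strand[i] == "+") {
      chars[s + 21L] <- "A"                      # PAM = AGG, nick at s+17
      chars[s + 22L] <- "G"; chars[s + 23L] <- "G"
      if (s + 24L <= length && chars[s + 24L] == "G") chars[s + 24L] <- "A"
    } else {
      chars[s - 2L] <- "C"; chars[s - 1L] <- "C" # working CCT = reverse AGG
      chars[s] <- "T"                            # nick at s+3
      if (s - 3L >= 1L && chars[s - 3L] == "C") chars[s - 3L] <- "A"
    }
  }
  Locus(name, paste(chars, collapse = ""))
}

#' Synthetic locus with a planted forward cis-nick pair
#'
#' Convenience wrapper around [makeLocus()]: plants forward protospacers so
#' the ups and ext nicks fall at `upsNick` and `upsNick + dcn`, optionally
#' with a helper site at `helperNick`.
#'
#' @param seed RNG seed.
#' @param length Locus length.
#' @param upsNick Desired ups-sgRNA nick index.
#' @param dcn Desired distance between cis nicks.
#' @param helperNick Optional helper nick index.
#' @param name Locus name.
#' @return A [Locus-class].
#' @export
makePairedLocus <- function(seed, length, upsNick, dcn, helperNick = NULL,
                            name = "synthetic_locus") {
  starts <- c(upsNick - 17L, upsNick + dcn - 17L,
              if (!is.null(helperNick)) helperNick - 17L)
  makeLocus(seed, length,
            data.frame(strand = "+", start = sort(as.integer(starts))),
            name = name)
}

.largestRemainder <- function(n, probs) {
  raw <- n * probs
  base <- floor(raw)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

.mutateBase <- function(base) {
  unname(.MISMATCH_MAP[base])
}

.applySeqErrors <- function(reads, errorRate) {
  if (errorRate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    ch <- strsplit(r, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(ch)) < errorRate)
    for (i in hit)
      ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate an amplicon read set with planted outcome fractions
#'
#' Generates full-length reads from the reference and edited alleles with
#' a known class composition: `intended` reads copy the edited allele,
#' `unedited` reads the reference, `indel` reads carry a uniform 1-10 nt
#' deletion or insertion at one of the nick positions (where prime-editing
#' byproducts arise), and the remainder (`1 - sum(fractions)`) carries a
#' substitution inside the edit region matching neither allele. In
#' `deterministic` mode class counts are fixed by largest-remainder
#' rounding of `n * f`, so planted fractions are recovered exactly by
#' [quantifyReads()]; `multinomial` mode draws counts from the seeded RNG.
#' Per-base substitution errors are applied at `errorRate` afterwards.
#'
#' @param refAllele,editedAllele The two alleles.
#' @param n Number of reads.
#' @param fIntended,fIndel,fUnedited Class fractions (sum <= 1).
#' @param upsNick,esEnd 0-based edited-region bounds on the reference.
#' @param nicks Reference positions where indels are planted (default the
#'   two region bounds, i.e. the nick sites).
#' @param errorRate Per-base substitution error rate (default 0).
#' @param mode `"deterministic"` (largest-remainder allocation) or
#'   `"multinomial"`.
#' @param seed RNG seed (default 1729).
#' @param indelSize Integer range of planted indel sizes.
#' @return Character vector of reads named `read<i>_<class>`.
#' @export
simulateReads <- function(refAllele, editedAllele, n, fIntended, fIndel,
                          fUnedited, upsNick, esEnd,
                          nicks = c(upsNick, esEnd), errorRate = 0,
                          mode = c("deterministic", "multinomial"),
                          seed = 1729L, indelSize = c(1L, 10L)) {
  mode <- match.arg(mode)
  probs <- c(intended = fIntended, indel = fIndel, unedited = fUnedited)
  if (any(probs < 0) || sum(probs) > 1 + 1e-12)
    stop("fractions must be in [0,1] and sum to at most 1")
  probs <- c(probs, substituted = max(0, 1 - sum(probs)))
  .withSeed(seed, {
    counts <- switch(mode,
      deterministic = .largestRemainder(n, probs),
      multinomial = as.integer(rmultinom(1L, n, probs)))
    names(counts) <- names(probs)
    bases <- c("A", "C", "G", "T")
    mkIndel <- function() {
      p <- sample(rep(as.integer(nicks), 2L), 1L)  # rep: robust to length 1
      size <- sample(indelSize[1L]:indelSize[2L], 1L)
      if (runif(1L) < 0.5 && p + size <= nchar(refAllele)) {
        paste0(.slice(refAllele, 0L, p),
               .slice(refAllele, p + size, nchar(refAllele)))
      } else {
        ins <- paste(sample(bases, size, replace = TRUE), collapse = "")
        paste0(.slice(refAllele, 0L, p), ins,
               .slice(refAllele, p, nchar(refAllele)))
      }
    }
    mkSub <- function() {
      p <- (as.integer(upsNick) + as.integer(esEnd)) %/% 2L
      p <- min(max(p, 0L), nchar(refAllele) - 1L)
      ch <- strsplit(refAllele, "", fixed = TRUE)[[1L]]
      ch[p + 1L] <- .mutateBase(ch[p + 1L])
      paste(ch, collapse = "")
    }
    reads <- c(rep(editedAllele, counts["intended"]),
               vapply(seq_len(counts["indel"]), function(i) mkIndel(), ""),
               rep(refAllele, counts["unedited"]),
               vapply(seq_len(counts["substituted"]), function(i) mkSub(),
                      ""))
    cls <- rep(names(counts), counts)
    reads <- .applySeqErrors(reads, errorRate)
    setNames(reads, sprintf("read%d_%s", seq_along(reads), cls))
  })
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads Named character vector (names become read ids).
#' @param path Output FASTQ path.
#' @param quality Constant Phred quality (default 30).
#' @return The path, invisibly.
#' @export
writeReadsFastq <- function(reads, path, quality = 30L) {
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- if (!is.null(names(reads))) names(reads)
              else sprintf("read%d", seq_along(reads))
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep(rawToChar(as.raw(33L + quality)), n), collapse = ""), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write one or more sequences as FASTA
#'
#' @param seqs Named character vector (or [Locus-class]).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "Locus")) seqs <- setNames(locusSeq(seqs), locusName(seqs))
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- if (!is.null(names(seqs))) names(seqs)
              else sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
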