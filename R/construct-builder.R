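## ext-pegRNA / sgRNA assembly and the flap-mismatch engine.
##
## ES and HS are handled in product-strand (synthesized DNA) orientation;
## the encoded construct carries revcomp(ES + HS) as the RTT, 5' of the
## PBS, so the RT reads the extension from the PBS junction outward.

#' Standard SpCas9 sgRNA scaffold (DNA alphabet)
#'
#' Shipped default; always overridable through the config.
#' @export
SGRNA_SCAFFOLD <- paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCA",
                         "ACTTGAAAAAGTGGCACCGAGTCGGTGC")

#' End of the ES window for an edit
#'
#' The edit sequence spans from the ups nick through the last edited base
#' or the ext nick, whichever is further: `max(ext nick, last atom end)`.
#'
#' @param edit [EditSpec-class].
#' @param extNick 0-based ext-pegRNA nick index.
#' @return Integer 0-based half-open end of the ES window.
#' @export
esWindowEnd <- function(edit, extNick) {
  max(as.integer(extNick), max(editAtoms(edit)$end))
}

#' Build the primer binding site
#'
#' The PBS is the reverse complement of the `pbsLen` working-strand bases
#' immediately 5' of the ups nick -- the genomic primer that stays attached
#' after the inter-nick fragment is excised. Lengths 9-16 nt support
#' efficient editing with 12 nt the recommended default; shorter than 9 nt
#' drastically reduces editing and triggers a warning.
#'
#' @param locus [Locus-class] or DNA string.
#' @param upsNick 0-based ups-sgRNA nick index.
#' @param pbsLen PBS length in nt (default 12).
#' @return PBS sequence as encoded in the construct.
#' @export
buildPBS <- function(locus, upsNick, pbsLen = 12L) {
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  upsNick <- as.integer(upsNick); pbsLen <- as.integer(pbsLen)
  if (pbsLen <= 0L) stop("pbsLen must be positive")
  if (upsNick < pbsLen || upsNick > nchar(seq))
    stop("PBS window extends beyond the locus")
  if (pbsLen < 9L)
    warning("PBS of ", pbsLen, " nt is below the recommended minimum of 9 nt")
  else if (pbsLen > 16L)
    warning("PBS of ", pbsLen, " nt is above the tested range (9-16 nt)")
  revcomp(.slice(seq, upsNick - pbsLen, upsNick))
}

#' Build the edit sequence (ES)
#'
#' The ES is the exact product sequence the synthesized strand must carry
#' from the ups nick through the last edited base (at least to the ext
#' nick): the edit applied to the window `[upsNick, esWindowEnd)`. A full
#' inter-nick deletion therefore yields an empty ES.
#'
#' @param locus [Locus-class] or DNA string.
#' @param edit [EditSpec-class]; every atom must start at or after the ups
#'   nick.
#' @param upsNick,extNick 0-based nick indices.
#' @return ES in product-strand orientation (may be `""`).
#' @export
buildES <- function(locus, edit, upsNick, extNick) {
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  upsNick <- as.integer(upsNick)
  a <- editAtoms(edit)
  if (any(a$start < upsNick))
    stop("geometry error: edit atom starts upstream of the ups nick")
  esEnd <- esWindowEnd(edit, extNick)
  if (esEnd > nchar(seq)) stop("ES window extends beyond the locus")
  subref <- .slice(seq, upsNick, esEnd)
  if (!nzchar(subref) && nrow(a) == 1L && a$start[1L] == a$end[1L])
    return(a$payload[1L])
  shifted <- EditSpec(a$start - upsNick, a$end - upsNick, a$payload,
                      label = editLabel(edit))
  applyEdit(subref, shifted)
}

#' Build the homologous sequence (HS)
#'
#' The HS is the genome-identical working-strand slice
#' `[esEnd, esEnd + hsLen)` that lets the synthesized flap anneal 3' of the
#' edit. Effective editing was observed for 12-22 nt with >= 16 nt the
#' recommended starting point, so shorter values trigger a warning.
#'
#' @param locus [Locus-class] or DNA string.
#' @param esEnd 0-based end of the ES window ([esWindowEnd()]).
#' @param hsLen HS length in nt (default 16).
#' @return HS sequence (product-strand orientation, genome-identical).
#' @export
buildHS <- function(locus, esEnd, hsLen = 16L) {
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  esEnd <- as.integer(esEnd); hsLen <- as.integer(hsLen)
  if (hsLen <= 0L) stop("hsLen must be positive")
  if (esEnd + hsLen > nchar(seq))
    stop("insufficient downstream sequence for an HS of ", hsLen, " nt")
  if (hsLen < 12L)
    warning("HS of ", hsLen, " nt is below the tested range (12-22 nt) and ",
            "the recommended 16 nt")
  else if (hsLen < 16L)
    warning("HS of ", hsLen, " nt is below the recommended 16 nt")
  .slice(seq, esEnd, esEnd + hsLen)
}

# Map each ES position (0-based) to its reference index, or NA for payload
# bases. Retained runs are genome-identical by construction.
.esRefMap <- function(edit, upsNick, extNick) {
  a <- editAtoms(edit)
  esEnd <- esWindowEnd(edit, extNick)
  m <- integer(0)
  pos <- as.integer(upsNick)
  for (i in seq_len(nrow(a))) {
    if (a$start[i] > pos) m <- c(m, pos:(a$start[i] - 1L))
    m <- c(m, rep(NA_integer_, nchar(a$payload[i])))
    pos <- a$end[i]
  }
  if (esEnd > pos) m <- c(m, pos:(esEnd - 1L))
  m
}

.MISMATCH_MAP <- c(A = "C", C = "A", G = "T", T = "G")

# Retained-flank lengths of an edit window: the runs of positions mapping
# consecutively onto the genome from the ups nick (5' flank) and up to the
# ES window end (3' flank).
.esFlanks <- function(edit, upsNick, extNick) {
  m <- .esRefMap(edit, upsNick, extNick)
  esEnd <- esWindowEnd(edit, extNick)
  p5 <- 0L
  while (p5 < length(m) && !is.na(m[p5 + 1L]) &&
         m[p5 + 1L] == upsNick + p5) p5 <- p5 + 1L
  p3 <- 0L
  while (p3 < length(m) && !is.na(m[length(m) - p3]) &&
         m[length(m) - p3] == esEnd - 1L - p3) p3 <- p3 + 1L
  if (p5 == length(m) && p3 == length(m)) p3 <- 0L
  c(five_prime = p5, three_prime = p3)
}

#' Maximum feasible mismatch count for an edit geometry
#'
#' @param edit [EditSpec-class].
#' @param upsNick,extNick 0-based nick indices.
#' @param scheme Mismatch scheme.
#' @param side `"auto"` or an explicit flap side.
#' @return `list(side, flank, maxK)`.
#' @export
mismatchFeasibility <- function(edit, upsNick, extNick,
                                scheme = c("consecutive", "every3",
                                           "every5"),
                                side = c("auto", "three_prime_flap",
                                         "five_prime_flap")) {
  scheme <- match.arg(scheme)
  side <- match.arg(side)
  fl <- .esFlanks(edit, as.integer(upsNick), as.integer(extNick))
  if (side == "auto")
    side <- if (fl["three_prime"] >= fl["five_prime"]) "three_prime_flap"
            else "five_prime_flap"
  flank <- unname(if (side == "three_prime_flap") fl["three_prime"]
                  else fl["five_prime"])
  spacing <- switch(scheme, consecutive = 1L, every3 = 3L, every5 = 5L)
  maxK <- if (flank <= 0L) 0L else (flank - 1L) %/% spacing + 1L
  list(side = side, flank = flank, maxK = maxK)
}

#' Engineer flap-disruption mismatches into an ES
#'
#' When the editing region sits away from a nick, the retained
#' (genome-identical) part of the ES can hybridize with the genomic flap
#' released at that nick and stall reverse transcription. Substituting
#' bases in that retained flank disrupts the hybrid. Mismatches start from
#' the nucleotide corresponding to the first (nick-adjacent) base of the
#' complementary flap and extend toward the editing region, either
#' consecutively or at intervals of every 3rd/5th position; 10-11
#' consecutive mismatches gave the highest efficiency in the source
#' experiments, hence the default `k = 11`.
#'
#' Substitutions use the fixed transversion map A->C, C->A, G->T, T->G
#' (deterministic and maximally destabilizing). They are real product
#' changes: the predicted allele carries them.
#'
#' @param es ES string (product-strand orientation).
#' @param edit [EditSpec-class] the ES was built from.
#' @param upsNick,extNick 0-based nick indices of the guide pair.
#' @param scheme `"none"`, `"consecutive"`, `"every3"` or `"every5"`.
#' @param k Number of mismatches (default 11).
#' @param side `"auto"` (longer retained flank), `"three_prime_flap"`
#'   (flank abutting the ext nick) or `"five_prime_flap"` (flank abutting
#'   the ups nick).
#' @return `list(es = modified ES, plan = `[MismatchPlan-class]`)`.
#' @export
introduceMismatches <- function(es, edit, upsNick, extNick,
                                scheme = c("consecutive", "none", "every3",
                                           "every5"),
                                k = 11L,
                                side = c("auto", "three_prime_flap",
                                         "five_prime_flap")) {
  scheme <- match.arg(scheme)
  side <- match.arg(side)
  k <- as.integer(k)
  emptyPlan <- new("MismatchPlan")
  if (scheme == "none" || k == 0L)
    return(list(es = es, plan = emptyPlan))
  m <- .esRefMap(edit, upsNick, extNick)
  if (length(m) != nchar(es))
    stop("ES does not match the edit/nick geometry it was built from")
  # Flanks are the runs of ES positions that map consecutively onto the
  # genome from the respective nick; a deletion's ref-index jump ends the
  # run even though both sides are genome-identical.
  feas <- mismatchFeasibility(edit, as.integer(upsNick),
                              as.integer(extNick), scheme, side)
  side <- feas$side
  flank <- feas$flank
  spacing <- switch(scheme, consecutive = 1L, every3 = 3L, every5 = 5L)
  need <- spacing * (k - 1L) + 1L
  if (flank < need)
    stop("mismatch scheme infeasible: retained ", side, " flank is ", flank,
         " nt, need ", need, "; maximum feasible k is ", feas$maxK)
  offsets <- spacing * (0:(k - 1L))          # from the nick-adjacent origin
  esIdx <- if (side == "three_prime_flap") nchar(es) - 1L - offsets
           else offsets                       # 0-based ES indices
  esIdx <- sort(esIdx)
  chars <- strsplit(es, "", fixed = TRUE)[[1L]]
  chars[esIdx + 1L] <- unname(.MISMATCH_MAP[chars[esIdx + 1L]])
  plan <- new("MismatchPlan", scheme = scheme, k = k, side = side,
              esOffsets = as.integer(esIdx),
              refPositions = as.integer(m[esIdx + 1L]))
  list(es = paste(chars, collapse = ""), plan = plan)
}

#' Assemble the full ext-pegRNA construct
#'
#' `full = spacer + scaffold + revcomp(hs) + revcomp(es) + pbs`
#' (equivalently `spacer + scaffold + revcomp(es + hs) + pbs`): the RTT is
#' encoded as the reverse complement of ES+HS, 5' of the PBS.
#'
#' @param spacer 20-nt spacer.
#' @param scaffold sgRNA scaffold.
#' @param es,hs,pbs Components from [buildES()], [buildHS()], [buildPBS()].
#' @param plan Optional [MismatchPlan-class] recorded on the construct.
#' @return An [ExtPegRNA-class].
#' @export
assembleExtPegRNA <- function(spacer, scaffold, es, hs, pbs,
                              plan = new("MismatchPlan")) {
  if (!nzchar(spacer)) stop("empty spacer")
  if (!nzchar(scaffold)) stop("empty scaffold")
  full <- paste0(spacer, scaffold, revcomp(hs), revcomp(es), pbs)
  new("ExtPegRNA", spacer = spacer, scaffold = scaffold, es = es, hs = hs,
      pbs = pbs, full = full, plan = plan)
}

#' Decode an ext-pegRNA construct back into components
#'
#' Inverse of [assembleExtPegRNA()] given the scaffold and the ES/HS/PBS
#' lengths.
#'
#' @param full Full construct sequence.
#' @param scaffold Scaffold used at assembly.
#' @param esLen,hsLen,pbsLen Component lengths.
#' @return `list(spacer, es, hs, pbs)`.
#' @export
decodeExtPegRNA <- function(full, scaffold, esLen, hsLen, pbsLen) {
  n <- nchar(full)
  expected <- 20L + nchar(scaffold) + esLen + hsLen + pbsLen
  if (n != expected)
    stop("construct length ", n, " != expected ", expected)
  spacer <- .slice(full, 0L, 20L)
  sc <- .slice(full, 20L, 20L + nchar(scaffold))
  if (!identical(sc, scaffold)) stop("scaffold mismatch while decoding")
  p <- 20L + nchar(scaffold)
  hs <- revcomp(.slice(full, p, p + hsLen))
  es <- revcomp(.slice(full, p + hsLen, p + hsLen + esLen))
  pbs <- .slice(full, p + hsLen + esLen, n)
  list(spacer = spacer, es = es, hs = hs, pbs = pbs)
}

#' Encode a plain sgRNA (ups-sgRNA or Helper gRNA)
#'
#' @param site One-row guide-site data.frame (or a spacer string).
#' @param scaffold sgRNA scaffold.
#' @param u6G Prepend a G when the spacer lacks one (U6 transcription
#'   start); default FALSE.
#' @return Encoded sgRNA sequence (DNA alphabet).
#' @export
buildSgRNA <- function(site, scaffold = SGRNA_SCAFFOLD, u6G = FALSE) {
  spacer <- if (is.data.frame(site)) site$spacer[1L] else site
  .checkAlphabet(spacer, "spacer")
  if (u6G && substr(spacer, 1L, 1L) != "G") spacer <- paste0("G", spacer)
  paste0(spacer, scaffold)
}

#' Convert a DNA-alphabet construct to RNA
#' @param x DNA string.
#' @return Same sequence with U for T.
#' @export
toRNA <- function(x) chartr("T", "U", x)
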