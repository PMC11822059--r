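## Heuristic design ranking. The underlying evidence is ordinal (sweep
## experiments at a handful of loci), so component scores are coarse tiers
## with equal default weights rather than a calibrated efficiency model.

.dcnComponent <- function(dcn, window = c(32L, 40L)) {
  if (dcn < 25L) return(NA_real_)           # hard reject
  if (dcn >= window[1L] && dcn <= window[2L]) return(1)
  if (dcn <= 71L) return(0.5)               # detectable, sub-optimal
  if (dcn <= 96L) return(0.25)              # reporter-only evidence
  0.1
}

.pbsComponent <- function(len) {
  if (len == 12L) return(1)
  if (len >= 9L && len <= 16L) return(0.75)
  if (len < 9L) return(0.25)
  0.5
}

.hsComponent <- function(len) {
  if (len >= 16L) return(1)
  if (len >= 12L) return(0.5)
  0.25
}

#' Score a design and attach warning flags
#'
#' Deterministic additive score over three components (DCN, PBS length, HS
#' length) with equal default weights, plus non-numeric flags:
#' \describe{
#'   \item{HARD_DCN}{DCN < 25 nt (score forced to 0; such pairs must be
#'     avoided).}
#'   \item{PBS_SHORT}{PBS below 9 nt.}
#'   \item{HS_SHORT}{HS below the tested floor of 12 nt.}
#'   \item{MISMATCH_RECOMMENDED}{a retained flank of >= 14 nt exists but no
#'     mismatches were engineered (editing activity collapses when the edit
#'     sits >= 14 nt from a nick).}
#'   \item{HELPER_RECOMMENDED}{ES of >= 70 nt without a Helper gRNA (a
#'     middle nick gave ~3-fold improvement for a 71-bp replacement).}
#'   \item{LARGE_INSERTION}{net insertion above 50 bp (rates drop sharply
#'     at 80-100 bp).}
#'   \item{TTTT_RUN}{a TTTT run in a variable guide segment -- spacer or
#'     ext-pegRNA extension (pol III terminator).}
#'   \item{RECUT_UPS / RECUT_EXT}{the predicted allele still contains the
#'     intact protospacer+PAM of the respective guide.}
#' }
#'
#' @param design A [PegDesign-class].
#' @param weights Named numeric weights for `dcn`, `pbs`, `hs` (normalized
#'   internally); default equal thirds.
#' @param dcnWindow Full-credit DCN window, default `c(32, 40)`.
#' @return `list(score = numeric in [0,1], flags = character)`.
#' @export
scoreDesign <- function(design, weights = c(dcn = 1, pbs = 1, hs = 1),
                        dcnWindow = c(32L, 40L)) {
  w <- weights[c("dcn", "pbs", "hs")] / sum(weights[c("dcn", "pbs", "hs")])
  flags <- character()
  peg <- design@pegRNA
  dcnC <- .dcnComponent(design@dcn, dcnWindow)
  if (is.na(dcnC)) {
    flags <- c(flags, "HARD_DCN")
    dcnC <- 0
    hard <- TRUE
  } else hard <- FALSE
  pbsLen <- nchar(peg@pbs); hsLen <- nchar(peg@hs)
  if (pbsLen < 9L) flags <- c(flags, "PBS_SHORT")
  if (hsLen < 12L) flags <- c(flags, "HS_SHORT")
  if (peg@plan@scheme == "none" &&
      (design@editNickDistance3p >= 14L || design@editNickDistance5p >= 14L))
    flags <- c(flags, "MISMATCH_RECOMMENDED")
  if (nchar(peg@es) >= 70L && nrow(design@helper) == 0L)
    flags <- c(flags, "HELPER_RECOMMENDED")
  a <- editAtoms(design@edit)
  if (sum(nchar(a$payload)) - sum(a$end - a$start) > 50L)
    flags <- c(flags, "LARGE_INSERTION")
  # pol III terminator scan: variable construct parts only (the standard
  # scaffold itself carries a tolerated TTTT)
  variable <- c(design@ups$spacer, design@ext$spacer,
                if (nrow(design@helper)) design@helper$spacer,
                paste0(revcomp(peg@hs), revcomp(peg@es), peg@pbs))
  if (any(grepl("TTTT", variable, fixed = TRUE)))
    flags <- c(flags, "TTTT_RUN")
  allele <- design@predictedAllele
  if (nzchar(allele)) {
    upsProto <- paste0(design@ups$spacer, design@ups$pam)
    extProto <- paste0(design@ext$spacer, design@ext$pam)
    if (grepl(upsProto, allele, fixed = TRUE))
      flags <- c(flags, "RECUT_UPS")
    if (grepl(extProto, allele, fixed = TRUE))
      flags <- c(flags, "RECUT_EXT")
  }
  score <- if (hard) 0
           else unname(w["dcn"] * dcnC + w["pbs"] * .pbsComponent(pbsLen) +
                       w["hs"] * .hsComponent(hsLen))
  list(score = score, flags = flags)
}

#' Rank designs
#'
#' Stable sort by score (descending), then distance of the DCN from 36 nt
#' (the midpoint of the optimal window), then ext nick position.
#'
#' @param designs List of [PegDesign-class] objects.
#' @return The list, reordered.
#' @export
rankDesigns <- function(designs) {
  if (!length(designs)) return(designs)
  score <- vapply(designs, function(d) d@score, numeric(1L))
  dd <- vapply(designs, function(d) abs(d@dcn - 36L), numeric(1L))
  en <- vapply(designs, function(d) d@ext$nick, integer(1L))
  designs[order(-score, dd, en)]
}

#' Tabulate designs for reporting
#'
#' @param designs List of [PegDesign-class] objects (ideally ranked).
#' @return data.frame with one row per design: rank, score, flags, DCN,
#'   component lengths, mismatch count and the construct sequences.
#' @export
designTable <- function(designs) {
  if (!length(designs))
    return(data.frame(rank = integer(), score = numeric(),
                      flags = character(), strand = character(),
                      upsNick = integer(), extNick = integer(),
                      helperNick = integer(), dcn = integer(),
                      pbsLen = integer(), esLen = integer(),
                      hsLen = integer(), mismatchK = integer(),
                      mismatchScheme = character(),
                      upsSgRNA = character(), extPegRNA = character(),
                      helperSgRNA = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    data.frame(rank = i, score = d@score,
               flags = paste(d@flags, collapse = ";"), strand = d@strand,
               upsNick = d@ups$nick, extNick = d@ext$nick,
               helperNick = if (nrow(d@helper)) d@helper$nick else NA_integer_,
               dcn = d@dcn, pbsLen = nchar(d@pegRNA@pbs),
               esLen = nchar(d@pegRNA@es), hsLen = nchar(d@pegRNA@hs),
               mismatchK = d@pegRNA@plan@k,
               mismatchScheme = d@pegRNA@plan@scheme,
               upsSgRNA = d@upsSgRNA, extPegRNA = d@pegRNA@full,
               helperSgRNA = if (length(d@helperSgRNA)) d@helperSgRNA
                             else "",
               stringsAsFactors = FALSE)
  }))
}
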