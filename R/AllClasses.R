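## Central S4 classes. All coordinates are 0-based, half-open, on the working
## strand (the strand carrying both protospacers); the +k/-k nick-relative
## labels used in edit names are a presentation layer only (see
## nickRelativeInterval).

#' Locus: a local reference DNA sequence
#'
#' A named reference sequence (working strand, 5'->3') that carries the
#' protospacers of all guides in a design. Only a local locus is modelled
#' (up to ~10 kb), not a genome-scale coordinate system.
#'
#' @slot name Character identifier.
#' @slot sequence DNA string over A/C/G/T (uppercase; ambiguity codes are
#'   rejected because guide design on ambiguous bases is meaningless).
#' @slot originOffset Integer added to coordinates when reporting them
#'   (default 0); internal arithmetic always uses 0-based local coordinates.
#' @exportClass Locus
setClass("Locus",
  representation(name = "character", sequence = "character",
                 originOffset = "integer"),
  prototype(name = "locus", sequence = "", originOffset = 0L))

setValidity("Locus", function(object) {
  if (length(object@sequence) != 1L || nchar(object@sequence) == 0L)
    return("sequence must be a single non-empty string")
  if (grepl("[^ACGT]", object@sequence))
    return("sequence must contain only A/C/G/T (uppercase, no ambiguity codes)")
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a single non-empty string")
  TRUE
})

#' EditSpec: an ordered set of atomic edits
#'
#' Each atom replaces the reference interval `[start, end)` with `payload`
#' (possibly empty). A deletion has a non-empty interval and empty payload;
#' an insertion has a zero-length interval and non-empty payload; a
#' replacement has both non-empty. Atoms are kept sorted and must not
#' overlap; adjacent zero-length and non-zero-length atoms may share a
#' boundary.
#'
#' @slot atoms data.frame with integer columns `start`, `end` and character
#'   column `payload`.
#' @slot label Free-text edit name (e.g. `"VEGFA_1 -37to-1 del 37 bp"`).
#' @exportClass EditSpec
setClass("EditSpec",
  representation(atoms = "data.frame", label = "character"),
  prototype(atoms = data.frame(start = integer(), end = integer(),
                               payload = character(),
                               stringsAsFactors = FALSE),
            label = ""))

setValidity("EditSpec", function(object) {
  a <- object@atoms
  if (!all(c("start", "end", "payload") %in% names(a)))
    return("atoms must have columns start, end, payload")
  if (nrow(a) < 1L) return("EditSpec needs at least one atom")
  if (any(a$end < a$start)) return("atom end < start")
  if (any(a$start < 0L)) return("negative atom coordinates")
  if (any(a$end == a$start & !nzchar(a$payload)))
    return("no-op atom (empty interval and empty payload)")
  if (any(grepl("[^ACGT]", a$payload)))
    return("payloads must be A/C/G/T only")
  if (nrow(a) > 1L) {
    o <- order(a$start, a$end)
    a <- a[o, , drop = FALSE]
    # overlap check on sorted atoms; zero-length atoms may touch boundaries
    if (any(a$start[-1L] < a$end[-nrow(a)]))
      return("atoms overlap")
  }
  TRUE
})

#' MismatchPlan: where and how mismatches were engineered into the ES
#'
#' Records the flap-disruption substitutions applied to the retained
#' (genome-identical) flank of an edit sequence.
#'
#' @slot scheme One of `"none"`, `"consecutive"`, `"every3"`, `"every5"`.
#' @slot k Number of substituted positions.
#' @slot side `"three_prime_flap"` or `"five_prime_flap"` (or `"none"`).
#' @slot esOffsets 0-based offsets of the substitutions within the ES.
#' @slot refPositions 0-based absolute working-strand indices mutated.
#' @exportClass MismatchPlan
setClass("MismatchPlan",
  representation(scheme = "character", k = "integer", side = "character",
                 esOffsets = "integer", refPositions = "integer"),
  prototype(scheme = "none", k = 0L, side = "none",
            esOffsets = integer(), refPositions = integer()))

setValidity("MismatchPlan", function(object) {
  if (!object@scheme %in% c("none", "consecutive", "every3", "every5"))
    return("unknown scheme")
  if (length(object@esOffsets) != object@k ||
      length(object@refPositions) != object@k)
    return("positions must have length k")
  TRUE
})

#' ExtPegRNA: the assembled extended pegRNA construct
#'
#' DNA-alphabet sequence of the encoded construct, 5'->3':
#' `spacer + scaffold + revcomp(HS) + revcomp(ES) + PBS`. ES and HS are
#' stored in product-strand (synthesized DNA) orientation; the encoded RNA
#' carries their reverse complements with the RTT 5' of the PBS, the
#' canonical pegRNA extension layout (the RT reads the extension from the
#' PBS junction).
#'
#' @slot spacer 20-nt spacer.
#' @slot scaffold sgRNA scaffold (config-supplied).
#' @slot es Edit sequence, product-strand orientation.
#' @slot hs Homologous sequence, product-strand orientation.
#' @slot pbs Primer binding site as encoded in the construct.
#' @slot full Full construct sequence.
#' @slot plan [MismatchPlan-class] applied to `es`.
#' @exportClass ExtPegRNA
setClass("ExtPegRNA",
  representation(spacer = "character", scaffold = "character",
                 es = "character", hs = "character", pbs = "character",
                 full = "character", plan = "MismatchPlan"),
  prototype(spacer = "", scaffold = "", es = "", hs = "", pbs = "",
            full = "", plan = new("MismatchPlan")))

setValidity("ExtPegRNA", function(object) {
  if (!nzchar(object@spacer)) return("empty spacer")
  if (!nzchar(object@scaffold)) return("empty scaffold")
  for (s in c(object@spacer, object@scaffold, object@es, object@hs,
              object@pbs))
    if (grepl("[^ACGT]", s)) return("non-ACGT character in component")
  expected <- paste0(object@spacer, object@scaffold, revcomp(object@hs),
                     revcomp(object@es), object@pbs)
  if (!identical(object@full, expected))
    return("full != spacer + scaffold + revcomp(hs) + revcomp(es) + pbs")
  TRUE
})

#' PegDesign: one candidate dual cis-nick design
#'
#' Bundles the ups-sgRNA and ext-pegRNA guide pair (plus optional Helper
#' gRNA), the assembled constructs, the DCN and edit-to-nick distances, the
#' heuristic score with warning flags, and the mechanistically predicted
#' product allele.
#'
#' @slot locusName Name of the designed locus.
#' @slot strand `"+"` if designed on the input orientation, `"-"` if on its
#'   reverse complement.
#' @slot ups,ext One-row data.frames describing the guide sites
#'   (columns `spacer`, `pam`, `strand`, `start`, `end`, `nick`).
#' @slot helper Zero- or one-row guide-site data.frame.
#' @slot pegRNA The assembled [ExtPegRNA-class].
#' @slot upsSgRNA,helperSgRNA Encoded sgRNA sequences (helper may be empty).
#' @slot dcn Distance between the cis nicks, nt (`ext nick - ups nick`).
#' @slot editNickDistance3p Retained genome-identical flank between the edit
#'   and the ext-pegRNA nick, nt (the distance the mismatch engine targets).
#' @slot editNickDistance5p Retained flank between the ups nick and the edit.
#' @slot esEnd 0-based end of the ES window on the design frame.
#' @slot edit The [EditSpec-class] (design-frame coordinates).
#' @slot score Heuristic design score in `[0, 1]`.
#' @slot flags Coded warning flags.
#' @slot predictedAllele Predicted product allele (design frame).
#' @slot editorLabel Free-text editor label (e.g. `"PE2"`-derived systems).
#' @exportClass PegDesign
setClass("PegDesign",
  representation(locusName = "character", strand = "character",
                 ups = "data.frame", ext = "data.frame",
                 helper = "data.frame", pegRNA = "ExtPegRNA",
                 upsSgRNA = "character", helperSgRNA = "character",
                 dcn = "integer", editNickDistance3p = "integer",
                 editNickDistance5p = "integer", esEnd = "integer",
                 edit = "EditSpec", score = "numeric", flags = "character",
                 predictedAllele = "character", editorLabel = "character"),
  prototype(strand = "+", helper = data.frame(), helperSgRNA = character(),
            flags = character(), editorLabel = "dual-cis-nick PE",
            score = NA_real_))

setValidity("PegDesign", function(object) {
  if (nrow(object@ups) != 1L || nrow(object@ext) != 1L)
    return("ups and ext must be one-row guide-site data.frames")
  if (object@dcn != object@ext$nick - object@ups$nick)
    return("dcn != ext nick - ups nick")
  if (object@dcn <= 0L) return("dcn must be positive (ups nick < ext nick)")
  TRUE
})

#' SimulationTrace: record of a mechanistic editing replay
#'
#' @slot excisedFragment Working-strand fragment between the two cis nicks.
#' @slot primer Genomic 3' end left by the upstream nick (PBS-complementary).
#' @slot synthesized New strand written by the RT (ES + HS).
#' @slot predictedAllele Final ligated product allele.
#' @slot steps Ordered text log of the replay.
#' @exportClass SimulationTrace
setClass("SimulationTrace",
  representation(excisedFragment = "character", primer = "character",
                 synthesized = "character", predictedAllele = "character",
                 steps = "character"))

#' QuantResult: amplicon read classification summary
#'
#' Counts partition the reads (`intended + indel + unedited + substituted +
#' unassigned = total`). Efficiency is the percentage of intended reads,
#' the indel rate the percentage of indel-containing reads, and product
#' purity the ratio intended:indel (`Inf` when no indel read was seen).
#'
#' @slot nTotal,nIntended,nIndel,nUnedited,nSubstituted,nUnassigned Counts.
#' @slot efficiency Percent intended reads.
#' @slot indelRate Percent indel-containing reads.
#' @slot purity Intended:indel ratio.
#' @exportClass QuantResult
setClass("QuantResult",
  representation(nTotal = "integer", nIntended = "integer",
                 nIndel = "integer", nUnedited = "integer",
                 nSubstituted = "integer", nUnassigned = "integer",
                 efficiency = "numeric", indelRate = "numeric",
                 purity = "numeric"))

setValidity("QuantResult", function(object) {
  if (object@nIntended + object@nIndel + object@nUnedited +
      object@nSubstituted + object@nUnassigned != object@nTotal)
    return("counts do not sum to nTotal")
  if (object@efficiency < 0 || object@efficiency > 100)
    return("efficiency outside [0,100]")
  if (object@indelRate < 0 || object@indelRate > 100)
    return("indel rate outside [0,100]")
  TRUE
})
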