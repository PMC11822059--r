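## Mechanistic replay of the dual cis-nick editing pathway. The simulator
## models the idealized intended pathway only: indel byproducts,
## flap-equilibrium kinetics and mismatch repair are quantified empirically
## by the amplicon module, not simulated.

# Product-coordinate index of a retained reference position: shift by the
# net length change of all atoms entirely upstream of it.
.productIndexOfRef <- function(edit, refPos) {
  a <- editAtoms(edit)
  vapply(refPos, function(r) {
    if (any(a$start < r & a$end > r))
      stop("reference position ", r, " falls inside an edit interval")
    before <- a$end <= r
    r + sum(nchar(a$payload[before]) - (a$end[before] - a$start[before]))
  }, integer(1L))
}

#' Overlay a mismatch plan onto a product allele
#'
#' Applies the plan's transversion substitutions at the product-coordinate
#' images of its reference positions.
#'
#' @param product Product allele from [applyEdit()].
#' @param edit The [EditSpec-class] that produced it.
#' @param plan A [MismatchPlan-class].
#' @return Product allele with mismatches applied.
#' @export
overlayMismatches <- function(product, edit, plan) {
  if (plan@k == 0L) return(product)
  idx <- .productIndexOfRef(edit, plan@refPositions)
  chars <- strsplit(product, "", fixed = TRUE)[[1L]]
  chars[idx + 1L] <- unname(.MISMATCH_MAP[chars[idx + 1L]])
  paste(chars, collapse = "")
}

#' Predict the product allele by direct string surgery
#'
#' The reference prediction every design is validated against:
#' [applyEdit()] plus the engineered mismatches of the plan.
#'
#' @param locus [Locus-class] or DNA string.
#' @param edit [EditSpec-class].
#' @param plan Optional [MismatchPlan-class].
#' @return Predicted allele (character).
#' @export
predictProduct <- function(locus, edit, plan = new("MismatchPlan")) {
  overlayMismatches(applyEdit(locus, edit), edit, plan)
}

#' Mechanistically replay the editing pathway for a design
#'
#' Steps: (1) nick the working strand at the ups and ext (and helper)
#' positions; (2) excise the inter-nick fragment, whose detachment the
#' second cis nick enhances; (3) verify that the genomic 3' end left at the
#' ups nick matches the construct's PBS; (4) extend the primer with the
#' reverse complement of the RTT (= ES + HS); (5) anneal the HS to the
#' genome 3' of the edit, verifying an exact match; (6) ligate. A PBS or
#' HS inconsistency is a hard construct/locus error naming the step.
#'
#' @param locus [Locus-class] or DNA string.
#' @param design A [PegDesign-class].
#' @return A [SimulationTrace-class]; `predictedAllele(trace)` equals
#'   [predictProduct()] for every internally consistent design.
#' @export
simulatePE <- function(locus, design) {
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  ups <- design@ups$nick; ext <- design@ext$nick
  peg <- design@pegRNA
  pbsLen <- nchar(peg@pbs); hsLen <- nchar(peg@hs)
  esEnd <- design@esEnd
  steps <- character()
  log <- function(...) steps <<- c(steps, paste0(...))
  log("1: nick working strand at ups=", ups, " and ext=", ext,
      " (DCN ", ext - ups, " nt)")
  if (nrow(design@helper))
    log("1b: helper nick at ", design@helper$nick,
        " (trace only; product unchanged)")
  excised <- .slice(seq, ups, ext)
  log("2: excise inter-nick fragment (", nchar(excised), " nt)")
  primer <- .slice(seq, ups - pbsLen, ups)
  if (!identical(primer, revcomp(peg@pbs)))
    stop("construct/locus inconsistency at step 3: genomic primer ", primer,
         " does not match revcomp(PBS) ", revcomp(peg@pbs))
  log("3: primer ", primer, " == revcomp(PBS)")
  synthesized <- paste0(peg@es, peg@hs)
  log("4: reverse transcription writes ", nchar(synthesized),
      " nt (ES ", nchar(peg@es), " + HS ", hsLen, ")")
  genomicHS <- .slice(seq, esEnd, esEnd + hsLen)
  if (!identical(genomicHS, peg@hs))
    stop("construct/locus inconsistency at step 5: HS does not anneal at [",
         esEnd, ",", esEnd + hsLen, ")")
  log("5: HS anneals at [", esEnd, ",", esEnd + hsLen, ")")
  allele <- paste0(.slice(seq, 0L, ups), peg@es,
                   .slice(seq, esEnd, nchar(seq)))
  log("6: ligate -> predicted allele of ", nchar(allele), " bp")
  new("SimulationTrace", excisedFragment = excised, primer = primer,
      synthesized = synthesized, predictedAllele = allele, steps = steps)
}

#' Validate a design by replaying it against the string-surgery prediction
#'
#' Runs [simulatePE()], compares the mechanistic allele with
#' [predictProduct()], and re-checks the construct invariants (HS is a
#' verbatim genomic substring; PBS is the reverse complement of the
#' genomic segment ending at the ups nick; construct composition).
#' Failures are report content, never errors.
#'
#' @param locus [Locus-class] or DNA string.
#' @param design A [PegDesign-class].
#' @return `list(pass = logical, checks = named logical, detail = character)`
#' @export
validateDesign <- function(locus, design) {
  seq <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  checks <- c(simulation = FALSE, oracle = FALSE, hsGenomic = FALSE,
              pbsGenomic = FALSE, composition = FALSE)
  detail <- character()
  trace <- tryCatch(simulatePE(seq, design), error = function(e) e)
  if (inherits(trace, "error")) {
    detail <- c(detail, conditionMessage(trace))
  } else {
    checks["simulation"] <- TRUE
    oracle <- predictProduct(seq, design@edit, design@pegRNA@plan)
    checks["oracle"] <- identical(trace@predictedAllele, oracle)
    if (!checks["oracle"])
      detail <- c(detail, paste0("mechanistic allele (",
                                 nchar(trace@predictedAllele),
                                 " bp) differs from string-surgery ",
                                 "prediction (", nchar(oracle), " bp)"))
  }
  peg <- design@pegRNA
  checks["hsGenomic"] <- identical(
    peg@hs, .slice(seq, design@esEnd, design@esEnd + nchar(peg@hs)))
  checks["pbsGenomic"] <- identical(
    revcomp(peg@pbs),
    .slice(seq, design@ups$nick - nchar(peg@pbs), design@ups$nick))
  checks["composition"] <- identical(
    peg@full, paste0(peg@spacer, peg@scaffold, revcomp(peg@hs),
                     revcomp(peg@es), peg@pbs))
  list(pass = all(checks), checks = checks, detail = detail)
}
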