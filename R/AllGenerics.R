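#' @name accessors
#' @title Accessors for cisprime classes
#' @description Slot accessors for the core S4 classes; use these instead
#'   of `@`.
#' @param x An object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("locusSeq", function(x) standardGeneric("locusSeq"))
#' @rdname accessors
#' @export
setMethod("locusSeq", "Locus", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @rdname accessors
#' @export
setMethod("locusName", "Locus", function(x) x@name)

#' @rdname accessors
#' @export
setGeneric("editAtoms", function(x) standardGeneric("editAtoms"))
#' @rdname accessors
#' @export
setMethod("editAtoms", "EditSpec", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("editLabel", function(x) standardGeneric("editLabel"))
#' @rdname accessors
#' @export
setMethod("editLabel", "EditSpec", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("constructSeq", function(x) standardGeneric("constructSeq"))
#' @rdname accessors
#' @export
setMethod("constructSeq", "ExtPegRNA", function(x) x@full)

#' @rdname accessors
#' @export
setGeneric("mismatchPlan", function(x) standardGeneric("mismatchPlan"))
#' @rdname accessors
#' @export
setMethod("mismatchPlan", "ExtPegRNA", function(x) x@plan)
#' @rdname accessors
#' @export
setMethod("mismatchPlan", "PegDesign", function(x) x@pegRNA@plan)

#' @rdname accessors
#' @export
setGeneric("designScore", function(x) standardGeneric("designScore"))
#' @rdname accessors
#' @export
setMethod("designScore", "PegDesign", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("designFlags", function(x) standardGeneric("designFlags"))
#' @rdname accessors
#' @export
setMethod("designFlags", "PegDesign", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("dcn", function(x) standardGeneric("dcn"))
#' @rdname accessors
#' @export
setMethod("dcn", "PegDesign", function(x) x@dcn)

#' @rdname accessors
#' @export
setGeneric("predictedAllele", function(x) standardGeneric("predictedAllele"))
#' @rdname accessors
#' @export
setMethod("predictedAllele", "PegDesign", function(x) x@predictedAllele)
#' @rdname accessors
#' @export
setMethod("predictedAllele", "SimulationTrace", function(x) x@predictedAllele)

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
#' @rdname accessors
#' @export
setMethod("efficiency", "QuantResult", function(x) x@efficiency)

#' @rdname accessors
#' @export
setGeneric("indelRate", function(x) standardGeneric("indelRate"))
#' @rdname accessors
#' @export
setMethod("indelRate", "QuantResult", function(x) x@indelRate)

#' @rdname accessors
#' @export
setGeneric("productPurity", function(x) standardGeneric("productPurity"))
#' @rdname accessors
#' @export
setMethod("productPurity", "QuantResult", function(x) x@purity)

#' @rdname accessors
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))
#' @rdname accessors
#' @export
setMethod("readCounts", "QuantResult", function(x)
  c(total = x@nTotal, intended = x@nIntended, indel = x@nIndel,
    unedited = x@nUnedited, substituted = x@nSubstituted,
    unassigned = x@nUnassigned))

setMethod("show", "Locus", function(object) {
  cat("Locus '", object@name, "': ", nchar(object@sequence), " bp",
      if (object@originOffset != 0L)
        paste0(" (origin offset ", object@originOffset, ")"), "\n", sep = "")
  s <- object@sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("  ", s, "\n", sep = "")
})

setMethod("show", "EditSpec", function(object) {
  cat("EditSpec '", object@label, "' with ", nrow(object@atoms),
      " atom(s):\n", sep = "")
  a <- object@atoms
  for (i in seq_len(nrow(a))) {
    kind <- if (a$end[i] == a$start[i]) "insert"
            else if (!nzchar(a$payload[i])) "delete" else "replace"
    cat(sprintf("  [%d,%d) %s %s\n", a$start[i], a$end[i], kind,
                if (nzchar(a$payload[i])) a$payload[i] else ""))
  }
})

setMethod("show", "ExtPegRNA", function(object) {
  cat("ExtPegRNA (", nchar(object@full), " nt): spacer 20 + scaffold ",
      nchar(object@scaffold), " + RTT ", nchar(object@es) + nchar(object@hs),
      " (ES ", nchar(object@es), " + HS ", nchar(object@hs), ") + PBS ",
      nchar(object@pbs), "\n", sep = "")
  if (object@plan@k > 0L)
    cat("  mismatches: ", object@plan@k, " (", object@plan@scheme, ", ",
        object@plan@side, ")\n", sep = "")
})

setMethod("show", "PegDesign", function(object) {
  cat("PegDesign on '", object@locusName, "' (strand ", object@strand,
      ")\n", sep = "")
  cat(sprintf("  ups nick %d, ext nick %d, DCN %d nt%s\n",
              object@ups$nick, object@ext$nick, object@dcn,
              if (nrow(object@helper))
                sprintf(", helper nick %d", object@helper$nick) else ""))
  cat(sprintf("  PBS %d nt, ES %d nt, HS %d nt, mismatches k=%d (%s)\n",
              nchar(object@pegRNA@pbs), nchar(object@pegRNA@es),
              nchar(object@pegRNA@hs), object@pegRNA@plan@k,
              object@pegRNA@plan@scheme))
  cat(sprintf("  score %.3f%s\n", object@score,
              if (length(object@flags))
                paste0("  [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "SimulationTrace", function(object) {
  cat("SimulationTrace (", length(object@steps), " steps) -> allele ",
      nchar(object@predictedAllele), " bp\n", sep = "")
  for (s in object@steps) cat("  ", s, "\n", sep = "")
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult over", object@nTotal, "reads\n")
  cat(sprintf("  intended %d (%.2f%%), indel %d (%.2f%%), unedited %d,
  substituted %d, unassigned %d\n",
              object@nIntended, object@efficiency, object@nIndel,
              object@indelRate, object@nUnedited, object@nSubstituted,
              object@nUnassigned))
  cat(sprintf("  product purity (intended:indel) %s\n",
              if (is.infinite(object@purity)) "Inf"
              else sprintf("%.2f", object@purity)))
})
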