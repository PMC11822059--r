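## Amplicon read classification and outcome statistics. Reads are aligned
## globally to both the reference and the predicted edited allele and
## classified inside a window around the edited region; precise-editing
## efficiency is the percentage of intended reads and the indel rate the
## percentage of indel-containing reads, so substitution-only reads count
## toward neither.

#' Global pairwise alignment (Needleman-Wunsch)
#'
#' Linear gap penalty with a fully specified, deterministic traceback:
#' ties prefer match/mismatch over a gap in `a` over a gap in `b`.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap Scoring scheme (defaults +1/-1/-2).
#' @return `list(score, a, b)` with the aligned strings (gaps as `-`).
#' @examples
#' alignGlobal("ACGT", "AGT")$score  # 1: three matches, one gap
#' @export
alignGlobal <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("alignGlobal: empty input")
  .nwAlign(a, b, match, mismatch, gap)
}

# Per-column digest of an alignment of `allele` (a) vs `read` (b):
#  readAt[p+1]  : read character aligned to 0-based allele position p
#                 ("-" for a deletion in the read)
#  insAt        : 0-based allele positions with read insertions attached
#                 (an insertion between allele p-1 and p is attached to p)
#  readSpan     : c(first, last+1) allele positions covered by read bases
.alignDigest <- function(aln) {
  ac <- strsplit(aln$a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(aln$b, "", fixed = TRUE)[[1L]]
  nAllele <- sum(ac != "-")
  readAt <- character(nAllele)
  insAt <- integer()
  first <- NA_integer_; last <- NA_integer_
  ap <- 0L
  for (k in seq_along(ac)) {
    if (ac[k] != "-") {
      readAt[ap + 1L] <- bc[k]
      if (bc[k] != "-") {
        if (is.na(first)) first <- ap
        last <- ap
      }
      ap <- ap + 1L
    } else {
      insAt <- c(insAt, ap)  # attached to the next allele base
      if (is.na(first)) first <- ap
      last <- max(last, ap - 1L, na.rm = TRUE)
    }
  }
  list(readAt = readAt, insAt = insAt,
       span = c(if (is.na(first)) 0L else first,
                if (is.na(last)) 0L else last + 1L))
}

.windowOn <- function(start, end, len) c(max(0L, start), min(len, end))

#' Classify one amplicon read
#'
#' Aligns the read to the reference and the predicted edited allele and
#' assigns one of:
#' \describe{
#'   \item{intended}{best allele is the edited one, no gap inside the
#'     quantification window, and the read matches the edited allele across
#'     the whole edited region (engineered mismatches included).}
#'   \item{indel}{the best alignment has at least one gap inside the
#'     window.}
#'   \item{unedited}{best allele is the reference, no window gap, and the
#'     read matches the reference across the edit region.}
#'   \item{substituted}{no window gap, but the edit region matches neither
#'     allele.}
#'   \item{unassigned}{the read does not span the window.}
#' }
#' Alignment-score ties go to the edited allele. The window is
#' `[upsNick - w, esEnd + w)` on the reference and the corresponding,
#' length-adjusted interval on the edited allele.
#'
#' @param read Read sequence.
#' @param refAllele,editedAllele The two alleles.
#' @param upsNick,esEnd 0-based edited-region bounds on the reference
#'   (ups nick through end of the ES window).
#' @param w Window flank, nt (default 10).
#' @return Label string.
#' @export
classifyRead <- function(read, refAllele, editedAllele, upsNick, esEnd,
                         w = 10L) {
  if (!nzchar(read)) return("unassigned")
  read <- toupper(read)
  delta <- nchar(editedAllele) - nchar(refAllele)
  if (esEnd + delta < upsNick)
    stop("allele/window inconsistency: edited region has negative length")
  alnRef <- alignGlobal(refAllele, read)
  alnEd <- alignGlobal(editedAllele, read)
  edited <- alnEd$score >= alnRef$score
  allele <- if (edited) editedAllele else refAllele
  aln <- if (edited) alnEd else alnRef
  regionEnd <- if (edited) esEnd + delta else esEnd
  win <- .windowOn(upsNick - w, regionEnd + w, nchar(allele))
  dig <- .alignDigest(aln)
  if (dig$span[1L] > win[1L] || dig$span[2L] < win[2L]) return("unassigned")
  winIdx <- if (win[2L] > win[1L]) (win[1L] + 1L):win[2L] else integer()
  hasDel <- any(dig$readAt[winIdx] == "-")
  hasIns <- any(dig$insAt > win[1L] & dig$insAt < win[2L])
  if (hasDel || hasIns) return("indel")
  region <- .windowOn(upsNick, regionEnd, nchar(allele))
  regIdx <- if (region[2L] > region[1L]) (region[1L] + 1L):region[2L]
            else integer()
  alleleChars <- strsplit(allele, "", fixed = TRUE)[[1L]]
  matchRegion <- all(dig$readAt[regIdx] == alleleChars[regIdx])
  if (edited && matchRegion) return("intended")
  if (!edited && matchRegion) return("unedited")
  "substituted"
}

#' Quantify editing outcomes over a read set
#'
#' Classifies every read with [classifyRead()] and computes the outcome
#' statistics: efficiency = 100 * intended / total, indel rate =
#' 100 * indel / total, product purity = intended / indel (`Inf` when no
#' indel read exists).
#'
#' @param reads Character vector, `DNAStringSet`, or path handled by
#'   [readReads()].
#' @param refAllele,editedAllele,upsNick,esEnd,w As in [classifyRead()].
#' @return A [QuantResult-class].
#' @export
quantifyReads <- function(reads, refAllele, editedAllele, upsNick, esEnd,
                          w = 10L) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- as.character(reads)
  if (!length(reads)) stop("empty read set")
  labels <- vapply(reads, classifyRead, "", refAllele, editedAllele,
                   upsNick, esEnd, w, USE.NAMES = FALSE)
  tab <- table(factor(labels, levels = c("intended", "indel", "unedited",
                                         "substituted", "unassigned")))
  n <- length(reads)
  new("QuantResult",
      nTotal = n, nIntended = as.integer(tab[["intended"]]),
      nIndel = as.integer(tab[["indel"]]),
      nUnedited = as.integer(tab[["unedited"]]),
      nSubstituted = as.integer(tab[["substituted"]]),
      nUnassigned = as.integer(tab[["unassigned"]]),
      efficiency = 100 * tab[["intended"]] / n,
      indelRate = 100 * tab[["indel"]] / n,
      purity = if (tab[["indel"]] == 0L) Inf
               else tab[["intended"]] / tab[["indel"]])
}

#' Quantify reads against a design
#'
#' Convenience wrapper deriving both alleles and the window from a
#' [PegDesign-class].
#'
#' @param reads As in [quantifyReads()].
#' @param locus [Locus-class] the design was made on (design frame).
#' @param design A [PegDesign-class].
#' @param w Window flank.
#' @return A [QuantResult-class].
#' @export
quantifyDesign <- function(reads, locus, design, w = 10L) {
  ref <- if (is(locus, "Locus")) locusSeq(locus) else locus
  quantifyReads(reads, ref, design@predictedAllele, design@ups$nick,
                design@esEnd, w)
}

#' Fold change between two printed percentages
#'
#' `treatment / control`, rounded half-up to `digits` decimal places (the
#' convention used when reporting efficiency improvements).
#'
#' @param treatment,control Percentages (control must be positive).
#' @param digits Decimal places (default 1).
#' @return Rounded ratio, or `NA` (with a warning) when control is zero.
#' @examples
#' foldChange(9.13, 0.23)      # 39.7
#' foldChange(3.22, 0.07, 0)   # 46
#' @export
foldChange <- function(treatment, control, digits = 1L) {
  if (control < 0 || treatment < 0) stop("percentages must be non-negative")
  if (control == 0) {
    warning("fold change undefined for zero control")
    return(NA_real_)
  }
  x <- treatment / control
  floor(x * 10^digits + 0.5) / 10^digits   # round half-up
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' Format is chosen by extension (`.fastq`/`.fq` vs anything else); quality
#' values are ignored. An optional minimum mean quality filter is applied
#' to FASTQ input.
#'
#' @param path Input file.
#' @param minMeanQ Optional minimum mean Phred quality; reads below are
#'   dropped.
#' @return Character vector of read sequences (named by read id).
#' @export
readReads <- function(path, minMeanQ = NULL) {
  isFastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  if (isFastq) {
    # Biostrings warns that FASTQ metadata columns are dropped; we never
    # use them, so silence that specific warning only.
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!is.null(minMeanQ)) {
      q <- methods::as(Biostrings::quality(x), "IntegerList")
      keep <- vapply(q, function(v) mean(v) >= minMeanQ, logical(1L))
      x <- x[keep]
    }
    setNames(as.character(x), names(x))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    setNames(as.character(x), names(x))
  }
}

#' Write a QuantResult as JSON or TSV
#'
#' @param result A [QuantResult-class].
#' @param path Output path; format chosen by extension (`.json` vs TSV).
#' @param meta Optional named list of run metadata recorded alongside the
#'   counts (JSON only).
#' @return The path, invisibly.
#' @export
writeQuantResult <- function(result, path, meta = NULL) {
  counts <- as.list(readCounts(result))
  stats <- list(efficiency_pct = efficiency(result),
                indel_rate_pct = indelRate(result),
                purity = if (is.infinite(productPurity(result))) "Inf"
                         else productPurity(result))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(c(counts, stats, if (!is.null(meta))
                           list(meta = meta)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(c(counts, stats), stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
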