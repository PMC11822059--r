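## End-to-end designer: guide search -> construct assembly -> mismatch
## engineering -> scoring -> mechanistic validation, plus report writers.

#' Mirror an edit onto the reverse complement of a locus
#'
#' @param edit [EditSpec-class] in working-strand coordinates.
#' @param locusLength Length of the locus.
#' @return The equivalent [EditSpec-class] on the reverse-complement frame.
#' @export
mirrorEdit <- function(edit, locusLength) {
  a <- editAtoms(edit)
  L <- as.integer(locusLength)
  pay <- vapply(a$payload, function(p) if (nzchar(p)) revcomp(p) else "",
                "", USE.NAMES = FALSE)
  EditSpec(L - a$end, L - a$start, pay,
           label = paste0(editLabel(edit), " (revcomp frame)"))
}

# Assemble, score and validate one candidate design; NULL when the pair
# cannot host the construct (PBS/HS out of bounds) or fails validation.
.buildOneDesign <- function(locus, edit, pair, sites, cfg, strandLabel) {
  seq <- locusSeq(locus)
  upsNick <- pair$upsNick; extNick <- pair$extNick
  if (upsNick < cfg$pbsLen) return(NULL)
  esEnd <- esWindowEnd(edit, extNick)
  if (esEnd + cfg$hsLen > nchar(seq)) return(NULL)
  pbs <- buildPBS(seq, upsNick, cfg$pbsLen)
  es0 <- buildES(seq, edit, upsNick, extNick)
  hs <- buildHS(seq, esEnd, cfg$hsLen)
  if (cfg$mismatchScheme == "none" || cfg$mismatchK == 0L) {
    es <- es0; plan <- new("MismatchPlan")
  } else {
    feas <- mismatchFeasibility(edit, upsNick, extNick, cfg$mismatchScheme,
                                cfg$mismatchSide)
    kUse <- min(cfg$mismatchK, feas$maxK)
    if (kUse == 0L) {
      es <- es0; plan <- new("MismatchPlan")
    } else {
      mm <- introduceMismatches(es0, edit, upsNick, extNick,
                                cfg$mismatchScheme, kUse, cfg$mismatchSide)
      es <- mm$es; plan <- mm$plan
    }
  }
  peg <- assembleExtPegRNA(pair$extSpacer, cfg$scaffold, es, hs, pbs, plan)
  upsSgRNA <- buildSgRNA(pair$upsSpacer, cfg$scaffold, cfg$u6G)
  helper <- .emptySites(); helperSgRNA <- character()
  if (cfg$helperPolicy != "off") {
    want <- cfg$helperPolicy == "on" ||
      (cfg$helperPolicy == "auto" && nchar(es) >= cfg$helperEsThreshold)
    if (want) {
      cand <- findHelperSites(sites, pair, cfg$helperMinSeparation)
      # the helper must not re-use either flanking protospacer
      cand <- cand[cand$nick != upsNick & cand$nick != extNick, ,
                   drop = FALSE]
      if (nrow(cand)) {
        helper <- cand[1L, , drop = FALSE]
        helperSgRNA <- buildSgRNA(helper$spacer, cfg$scaffold, cfg$u6G)
      } else if (cfg$helperPolicy == "on") {
        warning("helper requested but no candidate nick fits between ",
                upsNick, " and ", extNick, "; helper omitted")
      }
    }
  }
  fl <- .esFlanks(edit, upsNick, extNick)
  allele <- predictProduct(seq, edit, plan)
  ups <- data.frame(spacer = pair$upsSpacer, pam = pair$upsPam,
                    strand = pair$strand, start = pair$upsStart,
                    end = pair$upsStart + 20L, nick = upsNick,
                    stringsAsFactors = FALSE)
  ext <- data.frame(spacer = pair$extSpacer, pam = pair$extPam,
                    strand = pair$strand, start = pair$extStart,
                    end = pair$extStart + 20L, nick = extNick,
                    stringsAsFactors = FALSE)
  d <- new("PegDesign", locusName = locusName(locus), strand = strandLabel,
           ups = ups, ext = ext, helper = helper, pegRNA = peg,
           upsSgRNA = upsSgRNA, helperSgRNA = helperSgRNA,
           dcn = as.integer(pair$dcn),
           editNickDistance3p = unname(fl["three_prime"]),
           editNickDistance5p = unname(fl["five_prime"]),
           esEnd = as.integer(esEnd), edit = edit, score = NA_real_,
           flags = character(), predictedAllele = allele)
  sc <- scoreDesign(d, dcnWindow = cfg$dcnWindow)
  d@score <- sc$score
  d@flags <- sc$flags
  v <- validateDesign(seq, d)
  if (!v$pass) return(NULL)
  d
}

#' Design ups-sgRNA / ext-pegRNA constructs for an edit
#'
#' Runs the full pipeline: enumerate NGG guide sites on both orientations,
#' pick the orientation offering more valid cis-nick pairs (both guides
#' must share a strand, so the tool designs on whichever strand provides
#' PAMs), assemble PBS/ES/HS and the mismatch plan for each pair, attach a
#' Helper gRNA per policy, score, and keep only designs whose mechanistic
#' replay reproduces the intended product exactly.
#'
#' When the reverse orientation is selected, designs (coordinates, edit,
#' predicted allele) are expressed in the reverse-complement frame returned
#' as `$locus`; `$strand` records the choice.
#'
#' @param locus A [Locus-class].
#' @param edit An [EditSpec-class] in the input (working-strand) frame.
#' @param config Configuration list ([defaultConfig()]).
#' @return `list(designs = ranked list of `[PegDesign-class]`,
#'   locus = design-frame `[Locus-class]`, edit = design-frame edit,
#'   strand = "+" or "-")`.
#' @export
designEdits <- function(locus, edit, config = defaultConfig()) {
  stopifnot(is(locus, "Locus"), is(edit, "EditSpec"))
  .checkEditOnLocus(edit, locus)
  L <- length(locus)
  locusRC <- Locus(locusName(locus), revcomp(locusSeq(locus)),
                   locus@originOffset)
  editRC <- mirrorEdit(edit, L)
  frames <- list(
    `+` = list(locus = locus, edit = edit),
    `-` = list(locus = locusRC, edit = editRC))
  pairsOf <- lapply(frames, function(f) {
    sites <- findGuideSites(f$locus, "forward")
    p <- tryCatch(pairGuides(sites, f$edit, config$dcnWindow,
                             config$dcnHardMin),
                  error = function(e) .emptyPairs())
    list(sites = sites, pairs = p)
  })
  nPairs <- vapply(pairsOf, function(x) nrow(x$pairs), integer(1L))
  strand <- if (nPairs[["-"]] > nPairs[["+"]]) "-" else "+"
  message("designing on the ", if (strand == "+") "input" else
          "reverse-complement", " orientation (", nPairs[[strand]],
          " candidate pair(s); other orientation: ",
          nPairs[[setdiff(c("+", "-"), strand)]], ")")
  fr <- frames[[strand]]
  po <- pairsOf[[strand]]
  designs <- list()
  for (i in seq_len(min(nrow(po$pairs), config$maxDesigns))) {
    d <- .buildOneDesign(fr$locus, fr$edit, po$pairs[i, , drop = FALSE],
                         po$sites, config, strand)
    if (!is.null(d)) designs[[length(designs) + 1L]] <- d
  }
  list(designs = rankDesigns(designs), locus = fr$locus, edit = fr$edit,
       strand = strand)
}

.emptyPairs <- function() {
  data.frame(upsSpacer = character(), upsPam = character(),
             upsStart = integer(), upsNick = integer(),
             extSpacer = character(), extPam = character(),
             extStart = integer(), extNick = integer(),
             strand = character(), dcn = integer(),
             stringsAsFactors = FALSE)
}

#' Write the constructs of a design as FASTA
#'
#' Emits the ext-pegRNA, the ups-sgRNA and (when present) the Helper gRNA
#' as DNA-alphabet sequences for oligo ordering; `rna = TRUE` emits U for T.
#'
#' @param design A [PegDesign-class].
#' @param path Output FASTA path.
#' @param rna Emit RNA alphabet (default FALSE).
#' @return The path, invisibly.
#' @export
writeConstructFasta <- function(design, path, rna = FALSE) {
  seqs <- c(ext_pegRNA = design@pegRNA@full, ups_sgRNA = design@upsSgRNA)
  if (length(design@helperSgRNA))
    seqs <- c(seqs, helper_gRNA = design@helperSgRNA)
  if (rna) {
    x <- Biostrings::RNAStringSet(toRNA(unname(seqs)))
    names(x) <- names(seqs)
    Biostrings::writeXStringSet(x, path)
    return(invisible(path))
  }
  writeFasta(seqs, path)
}

.gbFeature <- function(key, loc, quals) {
  c(sprintf("     %-16s%s", key, loc),
    vapply(names(quals), function(q)
      sprintf("                     /%s=\"%s\"", q, quals[[q]]), ""))
}

#' Write an annotated GenBank record of the ext-pegRNA
#'
#' Features mark the spacer, scaffold, RTT (with ES and HS sub-features),
#' PBS and each engineered mismatch position on the encoded construct.
#'
#' @param design A [PegDesign-class].
#' @param path Output GenBank path.
#' @return The path, invisibly.
#' @export
writeConstructGenbank <- function(design, path) {
  peg <- design@pegRNA
  seq <- peg@full
  n <- nchar(seq)
  scLen <- nchar(peg@scaffold); esLen <- nchar(peg@es)
  hsLen <- nchar(peg@hs); pbsLen <- nchar(peg@pbs)
  # 1-based inclusive feature spans on the encoded construct
  spans <- list(
    spacer = c(1L, 20L),
    scaffold = c(21L, 20L + scLen),
    RTT = c(21L + scLen, 20L + scLen + hsLen + esLen),
    HS_revcomp = c(21L + scLen, 20L + scLen + hsLen),
    ES_revcomp = c(21L + scLen + hsLen, 20L + scLen + hsLen + esLen),
    PBS = c(21L + scLen + hsLen + esLen, n))
  lines <- c(
    sprintf("LOCUS       %-16s %5d bp    DNA     linear   SYN", "ext_pegRNA",
            n),
    sprintf("DEFINITION  extended pegRNA for locus %s (DCN %d nt).",
            design@locusName, design@dcn),
    "FEATURES             Location/Qualifiers")
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (sp[1L] > sp[2L]) next  # empty component (e.g. ES of a deletion)
    lines <- c(lines, .gbFeature("misc_feature",
                                 sprintf("%d..%d", sp[1L], sp[2L]),
                                 list(label = nm)))
  }
  plan <- peg@plan
  if (plan@k > 0L) {
    # ES offsets -> construct coordinates (ES is encoded reverse-complement)
    esStart <- spans$ES_revcomp[1L]
    pos <- esStart + (esLen - 1L - plan@esOffsets)
    for (i in seq_along(pos))
      lines <- c(lines, .gbFeature("variation", sprintf("%d", pos[i]),
                                   list(label = sprintf(
                                     "mismatch_%s_k%d", plan@scheme, i))))
  }
  lines <- c(lines, "ORIGIN")
  for (start in seq(1L, n, by = 60L)) {
    block <- substr(seq, start, min(n, start + 59L))
    groups <- substring(block, seq(1L, nchar(block), 10L),
                        pmin(nchar(block), seq(10L, nchar(block) + 9L, 10L)))
    lines <- c(lines, sprintf("%9d %s", start,
                              paste(tolower(groups), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Write a guide-pair table as TSV
#'
#' @param pairs Pair data.frame from [pairGuides()].
#' @param path Output path.
#' @export
writePairsTsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
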