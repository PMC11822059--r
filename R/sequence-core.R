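## Sequence and coordinate primitives. Coordinates are 0-based half-open
## throughout; conversion to R's 1-based substr() happens locally.

.checkAlphabet <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x))
    stop(what, " must be a single string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains non-ACGT characters", call. = FALSE)
  invisible(x)
}

.slice <- function(seq, start, end) {
  # 0-based half-open slice
  if (start > end) stop("slice start > end")
  if (start < 0L || end > nchar(seq)) stop("slice out of bounds")
  if (start == end) return("")
  substr(seq, start + 1L, end)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over A/C/G/T (empty string allowed).
#' @return The reverse complement. `revcomp(revcomp(x)) == x`.
#' @examples
#' revcomp("GATTACA")  # "TGTAATC"
#' @export
revcomp <- function(seq) {
  .checkAlphabet(seq)
  if (!nzchar(seq)) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Construct a Locus
#'
#' Normalizes the sequence to uppercase and validates the alphabet
#' (ambiguity codes including N are rejected).
#'
#' @param name Identifier.
#' @param sequence Working-strand DNA, 5'->3'.
#' @param originOffset Integer added when reporting coordinates (default 0).
#' @return A [Locus-class] object.
#' @export
Locus <- function(name, sequence, originOffset = 0L) {
  sequence <- toupper(as.character(sequence))
  new("Locus", name = as.character(name), sequence = sequence,
      originOffset = as.integer(originOffset))
}

#' Length of a locus in base pairs
#' @param x A [Locus-class].
#' @export
setMethod("length", "Locus", function(x) nchar(x@sequence))

#' Read a locus from a FASTA file
#'
#' Only the first record is used; a warning is emitted when the file holds
#' more than one.
#'
#' @param path FASTA file path.
#' @param originOffset Passed to [Locus()].
#' @return A [Locus-class].
#' @export
readLocus <- function(path, originOffset = 0L) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA record in ", path)
  if (length(ss) > 1L)
    warning("FASTA has ", length(ss), " records; using the first only")
  nm <- sub("\\s.*$", "", names(ss)[1L])
  Locus(nm, as.character(ss[[1L]]), originOffset)
}

#' Construct an EditSpec
#'
#' @param start,end Integer vectors of 0-based half-open atom intervals.
#' @param payload Character vector of replacement payloads ("" = deletion).
#' @param label Free-text edit name.
#' @return An [EditSpec-class]; atoms are sorted by start.
#' @examples
#' EditSpec(4, 8, "", label = "del 4 bp")
#' EditSpec(c(10, 30), c(10, 33), c("ACGT", ""), label = "ins + del")
#' @export
EditSpec <- function(start, end, payload, label = "") {
  a <- data.frame(start = as.integer(start), end = as.integer(end),
                  payload = toupper(as.character(payload)),
                  stringsAsFactors = FALSE)
  a <- a[order(a$start, a$end), , drop = FALSE]
  rownames(a) <- NULL
  new("EditSpec", atoms = a, label = as.character(label))
}

.checkEditOnLocus <- function(edit, locus) {
  L <- if (is(locus, "Locus")) length(locus) else nchar(locus)
  a <- editAtoms(edit)
  if (any(a$start < 0L) || any(a$end > L))
    stop("edit interval out of locus bounds")
  invisible(TRUE)
}

#' Apply an edit to a reference sequence
#'
#' Substitutes each atom's payload for its interval, left to right.
#' The product length equals
#' `nchar(ref) - sum(interval widths) + sum(payload lengths)`.
#'
#' @param locus A [Locus-class] or plain DNA string.
#' @param edit An [EditSpec-class].
#' @return Product sequence (character).
#' @examples
#' applyEdit("AAAACCCCGGGG", EditSpec(4, 8, ""))      # "AAAAGGGG"
#' applyEdit("AAAACCCCGGGG", EditSpec(4, 4, "TT"))    # "AAAATTCCCCGGGG"
#' @export
applyEdit <- function(locus, edit) {
  ref <- if (is(locus, "Locus")) locusSeq(locus) else .checkAlphabet(locus)
  .checkEditOnLocus(edit, ref)
  a <- editAtoms(edit)
  out <- character(2L * nrow(a) + 1L)
  pos <- 0L
  for (i in seq_len(nrow(a))) {
    out[2L * i - 1L] <- .slice(ref, pos, a$start[i])
    out[2L * i] <- a$payload[i]
    pos <- a$end[i]
  }
  out[2L * nrow(a) + 1L] <- .slice(ref, pos, nchar(ref))
  paste(out, collapse = "")
}

#' Convert nick-relative edit labels to absolute coordinates
#'
#' Edit names place positions relative to a nick with no position 0:
#' position `-k` is the base at absolute index `nick - k`, position `+k`
#' the base at `nick + k - 1`, so `-1 | +1` straddle the nick. A label pair
#' maps to the 0-based half-open interval covering both endpoints, e.g.
#' `-37to-1` with nick 100 gives `[63, 100)`.
#'
#' @param labelStart,labelEnd Signed nonzero integer labels, start <= end in
#'   label order.
#' @param nick 0-based nick index (between-bases position).
#' @return Integer `c(start, end)`, 0-based half-open.
#' @examples
#' nickRelativeInterval(-37, -1, 100)  # c(63, 100)
#' nickRelativeInterval(1, 1, 100)     # c(100, 101)
#' @export
nickRelativeInterval <- function(labelStart, labelEnd, nick) {
  labelStart <- as.integer(labelStart); labelEnd <- as.integer(labelEnd)
  nick <- as.integer(nick)
  if (labelStart == 0L || labelEnd == 0L)
    stop("nick-relative labels have no position 0")
  pos <- function(k) if (k < 0L) nick + k else nick + k - 1L
  s <- pos(labelStart); e <- pos(labelEnd)
  if (s > e) stop("label start after label end")
  c(s, e + 1L)
}

#' Inverse of nickRelativeInterval
#'
#' Labels an absolute 0-based half-open interval relative to a nick.
#'
#' @param interval Integer `c(start, end)`, non-empty.
#' @param nick 0-based nick index.
#' @return Integer `c(labelStart, labelEnd)`.
#' @export
nickRelativeLabel <- function(interval, nick) {
  s <- as.integer(interval[1L]); e <- as.integer(interval[2L]) - 1L
  nick <- as.integer(nick)
  if (e < s) stop("empty interval has no label")
  lab <- function(i) if (i < nick) i - nick else i - nick + 1L
  c(lab(s), lab(e))
}

#' Read an EditSpec from JSON
#'
#' Schema: `{"atoms":[{"start":int,"end":int,"payload":"ACGT..."}],
#' "label":"..."}`.
#'
#' @param path JSON file path (or literal JSON string).
#' @return An [EditSpec-class].
#' @export
readEditSpec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  a <- as.data.frame(x$atoms)
  if (is.null(a$payload)) a$payload <- ""
  a$payload[is.na(a$payload)] <- ""
  EditSpec(a$start, a$end, a$payload,
           label = if (!is.null(x$label)) x$label else "")
}

#' Parse a compact command-line edit string
#'
#' Dialect: `START-END:replace:SEQ | START-END:delete | POS:insert:SEQ`,
#' comma-separated for compound edits. Coordinates are absolute, 0-based,
#' half-open; an insertion at `POS` goes between bases `POS-1` and `POS`.
#'
#' @param x Edit string, e.g. `"63-100:replace:ACG...,105:insert:TT"`.
#' @param label Optional free-text label.
#' @return An [EditSpec-class].
#' @export
parseEditString <- function(x, label = x) {
  parts <- strsplit(trimws(x), ",", fixed = TRUE)[[1L]]
  starts <- integer(); ends <- integer(); pays <- character()
  for (p in parts) {
    f <- strsplit(trimws(p), ":", fixed = TRUE)[[1L]]
    coord <- f[1L]
    op <- if (length(f) >= 2L) f[2L] else stop("malformed edit atom: ", p)
    if (op == "insert") {
      if (length(f) != 3L) stop("insert needs a payload: ", p)
      pos <- as.integer(coord)
      if (is.na(pos)) stop("bad insert position: ", p)
      starts <- c(starts, pos); ends <- c(ends, pos)
      pays <- c(pays, toupper(f[3L]))
    } else {
      se <- strsplit(coord, "-", fixed = TRUE)[[1L]]
      if (length(se) != 2L) stop("bad interval: ", p)
      s <- as.integer(se[1L]); e <- as.integer(se[2L])
      if (is.na(s) || is.na(e)) stop("bad interval: ", p)
      if (op == "delete") {
        starts <- c(starts, s); ends <- c(ends, e); pays <- c(pays, "")
      } else if (op == "replace") {
        if (length(f) != 3L) stop("replace needs a payload: ", p)
        starts <- c(starts, s); ends <- c(ends, e)
        pays <- c(pays, toupper(f[3L]))
      } else stop("unknown edit op '", op, "' in: ", p)
    }
  }
  EditSpec(starts, ends, pays, label = label)
}

#' Write an EditSpec to JSON
#' @param edit An [EditSpec-class].
#' @param path Output path.
#' @export
writeEditSpec <- function(edit, path) {
  jsonlite::write_json(list(atoms = editAtoms(edit),
                            label = editLabel(edit)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
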