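---
title: "Designing dual cis-nick prime-editing constructs with cisprime"
author: "cisprime maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing dual cis-nick prime-editing constructs with cisprime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisprime)
```

## The editing model

Conventional prime editing writes an edit with a single pegRNA: the nicked
genomic strand primes reverse transcription of an RNA template carrying the
edit, and the newly synthesized 3' flap must out-compete the original 5'
flap. Efficiency collapses as edits grow or move away from the nick.

`cisprime` designs constructs for an *extended* configuration that places
**two nicks on the same strand** (cis nicks):

* an **ups-sgRNA** nicks upstream of the edit;
* an **ext-pegRNA** nicks downstream and carries the template.

The fragment between the two nicks is excised, removing the competing
genomic sequence wholesale. The ext-pegRNA extension is, 3' to 5' on the
encoded construct: reverse complement of **HS** (homologous sequence),
reverse complement of **ES** (edit sequence), then the **PBS** (primer
binding site). After nicking, the genomic 3' end upstream of the ups nick
anneals to the PBS, reverse transcription writes ES + HS, the HS anneals to
the genome just past the edit, and ligation yields the product allele.

Mechanistically this means:

* the **ES** is exactly the product sequence between the ups nick and the
  end of the edit window (`max(ext nick, last edited base)`) — an empty ES
  encodes a full inter-nick deletion;
* the **PBS** is the reverse complement of the sequence immediately 5' of
  the ups nick;
* the **HS** is a verbatim genomic slice starting at the ES window end.

`simulatePE()` replays these steps literally and `validateDesign()` demands
that the replayed allele equals the direct string-surgery prediction
(`applyEdit()` plus the mismatch overlay). Only designs passing this
mechanistic round-trip are emitted by `designEdits()`.

Two refinements complete the system:

* **Flap-disruption mismatches.** When the editing region sits ≥ 14 nt from
  a nick, the retained genome-identical part of the ES can re-hybridize
  with the flap released at that nick and stall synthesis. Substituting
  bases in that retained flank — starting at the nick-adjacent position and
  walking toward the edit — disrupts the hybrid. The substitutions are real
  product changes and appear in the predicted allele.
* **Helper gRNA.** For very long ES (≥ 70 nt), a third same-strand nick
  between the two cis nicks helps detach the inter-nick fragment. It never
  changes the predicted product, only the trace.

## Parameters, defaults, and why

| Parameter | Default | Range | Rationale |
|---|---|---|---|
| DCN (distance between cis nicks) | window [32, 40] | hard floor 25 | The empirical optimum at endogenous loci; editing is detectable out to ~96 nt (reporter data), so `relaxed` [25, 71] and `permissive` [25, 96] presets exist. DCN ≤ 24 is always rejected (steric clash between adjacent nickases). |
| PBS length | 12 | 9–16 | 9–16 nt support efficient editing; < 9 collapses (warned and flagged `PBS_SHORT`). |
| HS length | 16 | 12–22 | ≥ 16 nt is the recommended start; 12–15 works but scores lower; < 12 is flagged `HS_SHORT`. |
| Mismatch scheme / k | consecutive, k = 11 | 0–17 tested | 10–11 consecutive mismatches gave peak efficiency in the source sweep; `every3`/`every5` spacing is supported. k is auto-capped at the feasible maximum for the retained flank. |
| Mismatch map | A→C, C→A, G→T, T→G | fixed | Deterministic transversions, maximally destabilizing, reproducible. |
| Helper policy | auto (ES ≥ 70 nt) | on/off | Mirrors where helpers measurably helped (~3-fold at a 71-bp replacement). Helpers keep ≥ 25 nt from both flanking nicks. |
| Quantification window w | 10 | — | Flank added around the edited region when classifying reads. |
| Seed | 1729 | — | All randomness (locus and read generators, multinomial mode) flows from one seed. |

Scoring is deliberately coarse: the underlying evidence is ordinal sweeps
at a handful of loci, so `scoreDesign()` averages three tiered components
(DCN, PBS, HS) and attaches non-numeric flags (`MISMATCH_RECOMMENDED`,
`HELPER_RECOMMENDED`, `LARGE_INSERTION`, `TTTT_RUN`, `RECUT_*`) rather than
pretending to predict efficiencies.

## Coordinate conventions

* All coordinates are **0-based, half-open**, on the working strand (the
  strand carrying both protospacers).
* A nick is an index *between* bases. An SpCas9 site starting at `s` on the
  forward strand nicks at `s + 17` (3 nt 5' of the NGG PAM).
* Nick-relative edit labels have **no position 0**: `-k` is the base at
  index `nick - k`, `+k` the base at `nick + k - 1`, so `-1 | +1` straddle
  the nick. `nickRelativeInterval(-37, -1, 100)` is `[63, 100)`.
* The **DCN endpoint convention**: DCN = ext nick index − ups nick index,
  i.e. the number of excised bases. The window [32, 40] is interpreted on
  this quantity.
* Reverse-orientation loci are handled by mirroring: `designEdits()` tries
  both the input frame and its reverse complement and designs on whichever
  offers more valid same-strand pairs; results carry `strand = "-"` and are
  expressed in the mirrored frame (returned as `$locus`).

## Read classification

`classifyRead()` aligns each read globally (Needleman–Wunsch, +1/−1/−2
linear gaps, deterministic traceback: diagonal, then gap-in-allele, then
gap-in-read) to both alleles, picks the better one (ties go to the edited
allele), and classifies inside the window `[ups nick − w, region end + w)`:

* **intended** — edited allele, no window gap, read matches the edited
  allele across the whole edit region, *engineered mismatches included*;
* **indel** — any gap inside the window of the best alignment;
* **unedited** — symmetric to intended on the reference;
* **substituted** — gap-free but the edit region matches neither allele;
* **unassigned** — the read does not span the window.

Efficiency = 100 · intended/total, indel rate = 100 · indel/total, product
purity = intended : indel. Substitution-only reads count toward neither
rate, matching the reporting convention of the source experiments. Reads
truncated *inside* the window typically surface as `indel` rather than
`unassigned`, because a global aligner scatters their bases; only reads
lying wholly outside the window are `unassigned`. Parity with external
amplicon pipelines (e.g. CRISPResso2 windowing) is explicitly not a goal.

## Synthetic generators: scope and limits

`makeLocus()` draws a seeded random background **free of GG/CC
dinucleotides**, so the only NGG PAMs on either strand are the planted
ones — guide search on a synthetic locus is exactly solvable by
construction. `simulateReads()` plants class fractions with
**largest-remainder rounding** in deterministic mode (so golden tests are
exact) or multinomial draws otherwise; indel reads get a uniform 1–10 nt
insertion or deletion at a nick, where real byproducts arise; substituted
reads flip one base mid-region. Limits: constant Q30 qualities, uniform
substitution errors only, no sequencer-specific error profiles, full-length
reads only.

## Numerical choices

* `foldChange()` rounds **half-up** (`floor(x·10^d + 0.5)/10^d`), the
  convention used when reporting efficiency improvements; banker's rounding
  would print 0.25 → 0.2 instead of 0.3.
* Purity is reported as `Inf` when no indel read exists, never `NaN`.
* The aligner is implemented in C++ (Rcpp) because the tie-break order is
  part of the contract; an exhaustive enumeration oracle and
  `Biostrings::pairwiseAlignment` cross-checks pin it in the test suite.
* Problem sizes: loci up to ~10 kb, reads ≤ ~1 kb; alignment is O(n·m) per
  read, so quantification of 1000 × 200 bp reads takes seconds.

## Worked example

```{r example, eval = FALSE}
locus <- makePairedLocus(seed = 42, length = 400, upsNick = 150, dcn = 37)
set.seed(4242)
edit <- EditSpec(150, 165, paste(sample(c("A","C","G","T"), 37,
                                        replace = TRUE), collapse = ""),
                 label = "15->37 bp replacement")
res <- designEdits(locus, edit)
top <- res$designs[[1]]
top                      # show(): guides, DCN, score, flags
simulatePE(locus, top)   # step-by-step mechanistic trace

reads <- simulateReads(locusSeq(locus), predictedAllele(top), 1000,
                       0.30, 0.05, 0.65, 150, top@esEnd, seed = 7)
quantifyDesign(reads, locus, top)
```

The README shows the printed output of this exact session.
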