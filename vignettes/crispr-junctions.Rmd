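---
title: "Predicting and quantifying CRISPR-mediated rearrangement junctions"
author: "crisprJunctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and quantifying CRISPR-mediated rearrangement junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprJunctions)
```

## The model

Two simultaneous Cas9 double-strand breaks on one molecule can resolve as a
**deletion** (the intervening segment is lost and the outer ends re-ligate) or
an **inversion** (the segment is re-inserted in reverse-complement
orientation). Each event creates novel *fusion junctions*: one for a
deletion, two (5′ and 3′) for an inversion. Because the junction sequence is
predictable from the guide positions, deep sequencing of a junction amplicon
reads out how cells repaired the paired breaks — precisely, or with small
insertions and deletions.

The package rests on an explicit cut-site model. S. pyogenes Cas9 is
targeted by a 20-nt protospacer followed by a PAM (`NGG` canonical, `NAG`
weak but usable). The canonical cut is blunt, 3 nt upstream of the PAM on
both strands. The sgRNA-complementary (target) strand is, however, cut at a
fixed 3 nt while the protospacer-bearing strand can be cut 3–8 nt upstream
of the PAM, leaving a short 5′ overhang. A `cut_model(3, p)` with
`p ∈ [3, 8]` captures this; 3′-overhang geometries are rejected at
construction because the model space is deliberately restricted to what the
staggered-cleavage evidence supports.

Staggered cuts explain the reproducible 1–2 nt junction indels this kind of
experiment observes:

* **fill-in** — a polymerase copies the 5′ overhang before blunt ligation,
  duplicating it. The inserted bases are therefore *templated*: they equal
  the protospacer-strand sequence at offsets `(3, p]` upstream of the PAM.
  A cut at the 4th nt inserts exactly one base (`+G`, `+C`, …), at the 5th
  two bases, and so on; the insertion can never exceed 5 nt under the 3–8
  offset range.
* **resection** — the overhang is trimmed before ligation, deleting the same
  bases instead.
* **blunt ligation** — only defined when both ends are blunt; the
  `(3,3)+(3,3)` case is the *precise* (error-free) junction.

`enumerate_repair_products()` walks this finite mechanism space and
`explain_indel()` inverts it: every mechanism whose product carries the
observed left-normalized indel is reported. Small (1–2 nt) events at the
fusion additionally receive a generic `nhej` explanation, because imprecise
end joining and alternative cutting are empirically indistinguishable from
junction sequence alone; the package reports all consistent mechanisms and
never picks one.

### Whole-junction orientation matters

A subtlety worth stating explicitly: whether a staggered cut produces a
junction insertion depends on which fragment is retained. Fill-in inserts
bases into a *deletion* junction only when the guide's PAM faces the
retained flank (the overhang's template copy survives the deletion);
inversions retain both fragments, so a staggered cut always marks one of
the two inversion junctions. Tokens are reported in the coordinate frame of
the junction reference, so an overhang read on a − strand protospacer
appears reverse-complemented in the report — `fill_in_insertion()` gives the
mechanistic (PAM-strand) reading.

## Junction references and alignment conventions

The alignment reference for quantification is always the **canonical blunt
(3,3) junction** with a default flank of 100 nt on each side of the fusion
gap; staggered geometries enter only through the repair enumeration. All
coordinates are 0-based half-open with cut positions as gap coordinates;
1-based positions appear only in reports.

Reads are aligned glocally — read global, reference local — with affine gap
scoring (defaults: match +1, mismatch −2, gap open 5, gap extend 2, so a
1-nt gap costs more than two mismatches and substitution errors are not
absorbed into spurious indels). Reads below an identity floor of 80% are
unmapped. Reads that are exact substrings of the reference take a leftmost
fast path; all reported indels are left-normalized (shifted to the smallest
anchor preserving the alternate sequence), so homopolymer-ambiguous
placements aggregate into a single row.

Pileup conventions, chosen once and documented rather than inferred:

* a read **spans** the fusion when mapped and anchored by ≥ 10 nt on each
  side of the fusion gap; non-spanning reads count for nothing;
* indels are reported within ± 20 nt of the fusion (`window`);
* `VarFreq = var_reads / (ref_reads + var_reads)`, where `ref_reads` counts
  spanning reads covering the anchor without that indel. Published indel
  tables from pileup callers do not print the full per-allele depth, so no
  single denominator can be reverse-engineered from them; this two-allele
  definition is adopted and the raw counts are always emitted so any other
  denominator can be recomputed. Mismatch-only reads count as reference at
  indel anchors (indel-centric calling);
* `perfect_fraction` is the fraction of spanning reads with zero mismatches
  and zero indels inside the window;
* `indel representation` is a token's share of all indel-supporting reads;
* significance is a one-sided binomial tail (`pbinom`) against a
  configurable per-read error rate (default 0.01). This replaces the
  internal test of pileup variant callers; published p-values are not
  reproduction targets;
* report filtering defaults to `min_freq = 0.01`, `min_var_reads = 2` — the
  1% detection floor used when declaring a junction indel-free.

## The synthetic-data module

No raw sequencing data accompany the designs this package emulates, so the
generator is first-class, tested code rather than a fixture. Three
architectures are produced on random background sequence, deterministic in
`(kind, scale, seed)`:

* `igfp_like` — a circular plasmid: promoter, an inverted reporter cassette,
  two flanking NGG guide sites, and two *inverted* LoxP-like 34-nt sites
  carrying one shared protospacer with a weak NAG PAM (one guide, two cuts);
* `lsl_like` — a circular Lox-STOP-Lox plasmid: the STOP cassette sits
  between two *direct-repeat* LoxP-like sites, so the single NAG guide cuts
  twice and deletion removes the STOP;
* `two_cut_locus` — a linear molecule with two NGG guide sites roughly
  `scale/2` apart, the desk-scale stand-in for a multi-kilobase genomic
  region. The defaults (scale 3000, cut separation ≈ 1.4 kb) were chosen
  because no desk-scale property of junction analysis depends on the
  literal genomic distance; the separation is a parameter.

LoxP-like sites use the real site's structure (13-nt arm, asymmetric 8-nt
spacer, inverted-repeat arm, internal NAG PAM) but are **not** the true LoxP
sequence; the plasmids they emulate live in supplementary material not
reproduced here, and nothing in the analysis depends on the literal
sequence. Every fixture also carries an inversion-detection primer pair
(product only from the inverted molecule) and a deletion pair (product
shortens by exactly the excised length) so in-silico PCR mirrors the
gel-based detection logic.

Read simulation draws windows across the fusion point of a junction, first
applying a sampled outcome token (`none`, `+G`, `-A`, …) and then
independent per-base substitution errors. The error model is
substitution-only by design: it isolates repair-derived indels, which are
the signal of interest, from sequencing noise. Consequences for
interpretation: passing recovery tests show the pipeline is calibrated for
substitution noise at amplicon-like depths; they say nothing about
platform-specific indel error (e.g. homopolymer slippage), PCR chimeras or
amplification bias, which real amplicon data can contain and which the
generator deliberately does not emulate. Base qualities are constant and
unused. Paired-end data are treated as independent single-end mates.

## Numerical and design choices

* Circular molecules are scanned by doubling the sequence and deduplicating
  hits modulo the length; plasmid fixtures are circular, and for a circular
  deletion the caller chooses which arc is removed (`arc = "inner"/"outer"`)
  — the fixtures mark the reporter arc explicitly rather than guessing.
* In-silico PCR demands exact primer matches: it is detection logic, not
  thermodynamics; product-size arithmetic is the assay.
* Off-target enumeration is an exhaustive Hamming scan with a PAM filter.
  It is a generic stand-in — no published scoring scheme (CFD/MIT) is
  implemented, and the scan is not a reproduction of any specific
  prediction tool.
* Alignment ties are broken leftmost; the exact-substring fast path takes
  the smallest start.
* `explain_indel` orders mechanisms deterministically: fill-in/resection
  before generic NHEJ, smaller offsets first.
* All randomness flows through explicit integer seeds; identical
  configuration and seed reproduce every output byte-for-byte (the run log
  carries the only timestamp).

## Problem sizes used by the test suite

The suite validates construction arithmetic on 1,000 random instances,
alignment optimality against a brute-force affine-gap oracle on 500 random
read/reference pairs (reads ≤ 30 nt, references ≤ 60 nt), spectrum recovery
on 10,000 simulated reads (every token within 3 binomial standard errors of
its realized truth; total-variation distance < 0.03), the full mechanism
round-trip over offsets 3–8 and all repair modes, and an error-only null of
100,000 reads at substitution rate 0.001 in which no filtered indel call may
exceed 1% frequency. These sizes give the binomial bounds useful power
while keeping the whole suite to a few minutes.

## Limitations

* Translocations between molecules, duplications, and microhomology-driven
  junctions are out of scope; resection is modeled only as overhang
  trimming, so larger deletions fall to the generic NHEJ explanation.
* The mechanism report is a consistency analysis, not a probabilistic
  attribution; no weighting across mechanisms is offered because junction
  sequence alone cannot support one.
* Mapping is junction-local: reads from unrelated loci are simply unmapped,
  and genome-wide triage of amplicon contamination is not attempted.
* SNV calling, base-quality modeling and multi-allelic genotyping are
  deliberately absent; the pipeline is indel-centric at a known breakpoint.
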