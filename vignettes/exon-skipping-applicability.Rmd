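---
title: "Reading-frame arithmetic and exon-skipping applicability for dystrophin mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading-frame arithmetic and exon-skipping applicability for dystrophin mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdskip)
```

## The model

Duchenne muscular dystrophy (DMD) is caused by mutations in the dystrophin
gene that disrupt the open reading frame of its 79-exon, 11,058-nt coding
sequence; in-frame mutations instead typically produce the milder Becker
phenotype (the *reading-frame rule*). Antisense oligonucleotides (ASOs) can
force the spliceosome to skip chosen exons, and skipping the right exon(s)
next to a frame-disrupting mutation can restore the frame at the cost of an
internally truncated protein.

Whether a skip restores the frame is pure modular arithmetic. Let
$L_e$ be the coding length of exon $e$. The *phase* of the intron after exon
$e$ is $\sum_{i \le e} L_i \bmod 3$; an exon is *symmetric* when its flanking
introns share a phase, i.e. $L_e \equiv 0 \pmod 3$. A set $X$ of exons can be
removed from the transcript without shifting the frame downstream iff
$\sum_{e \in X} L_e \equiv 0 \pmod 3$. Everything this package computes is an
enumeration of such sets under therapeutic constraints:

* **Deletions** of exons $f..l$ are frameshift iff their total length is not
  a multiple of 3. Rescue targets are drawn from the immediately flanking
  exons $\{f-2, f-1, l+1, l+2\}$, at most two of them, such that the excluded
  region (deleted plus skipped) is a contiguous run whose total length is a
  multiple of 3. The admissible shapes are $\{f-1\}$, $\{l+1\}$,
  $\{f-2,f-1\}$, $\{l+1,l+2\}$ and the cross-flank pair $\{f-1,l+1\}$.
* **Small lesions** (point mutations, small indels, splice-site mutations).
  An intra-exonic lesion in a symmetric exon is removed by skipping that exon
  alone; in an asymmetric exon the lesion-bearing exon must be skipped with
  an adjacent exon such that the pair is frame-neutral. A splice-site lesion
  removes an exon from the transcript: if that exon is symmetric the induced
  loss is already in-frame and no ASO is needed; otherwise the induced
  single-exon deletion is rescued exactly like a deletion. The lesion's own
  length change is ignored — once its exon is excluded, only whole-exon
  lengths matter.
* **Duplications** use one-copy-skip arithmetic: skipping one copy of a
  subset $S$ of the duplicated exons (a single exon, or two adjacent ones)
  leaves an in-frame transcript iff the duplication's total length minus
  $S$'s is a multiple of 3. For a single-exon duplication the duplicated exon
  itself always qualifies (removing one copy restores the wild type). ASOs
  cannot distinguish the two copies; the hazard of excluding both is kept as
  an annotation note, not a disqualifier, and for single-exon duplications
  the *double-copy rescue* is also enumerated: an adjacent exon whose length
  complements the duplicated exon mod 3, so that losing both copies plus the
  neighbour stays in frame.
* **Multi-exon cocktails** (defaults: exons 3–9 and exons 45–55, both
  in-frame regions covering the two deletion hotspots) apply to a frameshift
  deletion iff the deletion lies entirely inside the range, to a small lesion
  iff the lesion-bearing (or splice-lost) exon lies inside the range, and
  never to duplications.

Exon 1 (start codon) and exon 79 (stop codon) are never skippable; all
targets live in exons 2–78.

## The exon table and its provenance

The bundled fixture (`inst/extdata/dmd_dp427m_exons.tsv`) is a curated
reconstruction of the Dp427m (RefSeq NM_004006) CDS exon structure in HGVS
c. coordinates, assembled from the clinical-genetics literature on dystrophin
exon skipping rather than downloaded at run time. Because transcription
errors in such a table would silently corrupt every downstream number,
`validate_fixture()` pins it to independently documented facts:

* 79 exons with contiguous c. coordinates and total CDS length 11,058 nt
  (3,685 residues plus stop);
* exon 52 spanning c.7543–c.7660 (118 nt, asymmetric) — the classic
  single-exon deletion rescued by skipping exon 51 or exon 53;
* exons 45–55 and 3–9 each in-frame as a block, consistent with the mild or
  asymptomatic phenotypes of patients carrying those whole-region deletions.

Beyond these programmatic anchors, the table was checked during curation
against a catalogue of strategy/mutation-class pairs reported for a large
patient registry (every reported strategy must be *reachable* by some
mutation of that class under the arithmetic above — 149 of 150 cells are;
the single exception concerns single-exon skips of the symmetric exon 3 for
deletions, which the mod-3 arithmetic provably forbids and which most likely
reflects registry records with sub-exonic breakpoints), and against known
frame facts such as the out-of-frame deletion of exons 3–7 seen in mild
patients and the naturally skipped in-frame exons 9, 71 and 71–74.
`load_transcript()` accepts any exon count so that the engine and its tests
can run on arbitrary synthetic transcripts; the dystrophin fixture is simply
the default model returned by `dmd_transcript()`.

## Mutation intake

Cohorts arrive as a TSV (`id, mclass, first_exon, last_exon, lesion_site,
phenotype, hgvs`) or as simplified HGVS c. strings. The parser handles the
exon-level subset used by locus-specific databases: boundary-aligned
`c.X_Ydel`/`dup` ranges become exon-range events; intra-exonic small variants
become `small_lesion(intra)`; positions with intronic offsets (`c.7660+1G>A`,
`c.7543-2A>G`) become donor/acceptor lesions anchored at exon boundaries. A
range that is not boundary-aligned and spans more than one exon is an error,
never a guess: partial-exon semantics are outside the model.

Any intronic offset, regardless of distance, marks a splice-site lesion;
splice-prediction windows are deliberately out of scope. Which exon a splice
lesion removes is genuinely ambiguous in the descriptive literature, so it is
a configuration switch: `own_exon` (default — the exon whose own donor or
acceptor is mutated is lost, standard splicing biology) or `paper_literal`
(a donor lesion removes the downstream neighbour, an acceptor lesion the
upstream one). Both conventions are property-tested.

## Cohort aggregation

`summarize_cohort()` reproduces the registry-style applicability tables: one
row per strategy (label conventions: `"51"`, `"6 & 7"`, `"45-55"`) with
distinct-mutation counts and percentages per class, and a per-class summary
of single / double-only / single-or-double / multi amenability. A mutation
counts at most once per strategy but may support many strategies. The
"double" column counts mutations with a double but no single option, so
single + double equals the union percentage. Splice lesions whose induced
loss is already in-frame need no ASO; they are reported with an empty target
set and excluded from per-strategy counts and the single/double columns.

Because registries are ambiguous about whether deletion percentages use all
DMD deletions or only the frameshift ones, both denominators are supported
(`denominator = "all"` (default) or `"frameshift"`); in-frame deletions
always carry zero strategies either way. Percentages are stored unrounded;
rounding is left to presentation. Ties in the strategy ranking are broken
lexicographically by label so reports are byte-reproducible.

## The synthetic cohort generator

No public mutation-level export of the registry exists, so the generator
emulates its *DMD-labelled* composition (non-DMD phenotype spectra are out of
scope): class mix 60 / 27 / 13.5 per cent (deletions / small lesions /
duplications), deletion hotspots with 70% of deletions inside exons 43–55
and 21% inside exons 2–22 and the remainder starting elsewhere, 52/232 of
duplications single-exon with exon 2 the modal start, and 25% of small
lesions at splice sites (split evenly donor/acceptor).

Choices the source composition does not determine were fixed once, on
field-plausibility grounds, and are configurable:

* **Deletion spans** are truncated-geometric with mean 4 exons — deletions in
  this gene are typically multi-exon, and a geometric span is the simplest
  monotone model. The hotspot region is drawn first (so hotspot shares match
  their configured weights exactly), then start and span within it.
* **Small-lesion exons** are drawn proportional to coding length, since point
  mutations accumulate roughly uniformly per nucleotide.
* **Exon-2 duplication enrichment** uses a sampling-weight multiplier of 15,
  enough to make exon-2 duplications clearly modal without dominating.
* **Phenotype labels** follow the reading-frame rule, so deletions and
  duplications are drawn conditioned on frameshift (the class mix describes
  the DMD-labelled cohort; an unconditioned draw would let in-frame events
  leak label mass and distort the mix). The `frame_rule_noise` knob generates
  rule-violating records — the rule is known to have exceptions — by
  sampling without the frameshift condition and/or flipping labels; the
  default is 0 so the in-frame/frameshift split of a generated cohort is
  exactly auditable.

Generation is deterministic for a fixed (seed, config, transcript) and
restores the caller's RNG state. What passing generator tests shows is that
the *pipeline* recovers configured composition parameters at realistic cohort
sizes; it does not show that real registry data have geometric spans,
length-proportional lesion placement, or these hotspot boundaries, and
per-strategy percentages computed on synthetic cohorts emulate but do not
reproduce registry values.

## Numerical and degenerate-input conventions

* All arithmetic is integer; there are no tolerances.
* Strategies are de-duplicated by (target set, category); a donor and an
  acceptor lesion with the same induced loss give identical strategy sets.
* Lesions in exon 1 or 79 (or splice lesions resolving outside 1–79) return
  an empty strategy table, not an error; enumerators called on in-frame
  deletions/duplications raise a contract error, while `annotate()` assigns
  `in_frame` with zero strategies.
* Every emitted deletion/small-lesion strategy is re-checked at output time:
  its excluded region must be frame-neutral (an internal soundness
  assertion).
* An empty cohort is an error in `summarize_cohort()` (denominators would be
  undefined); a zero-count class yields `NA` percentages.

## Verification strategy and problem sizes

The test suite checks the engine against independent brute-force enumerators
(direct subset enumeration and filtering, sharing no code with the engine) on
1000+ random transcripts of 5–15 exons with coding lengths 1–300, across all
three mutation classes and both splice conventions; property tests assert
frame-neutrality of every emitted strategy and order-independence of
annotation. Generator recovery is tested at n = 10,000 (±2 percentage points
on the class mix, ±3 on hotspot containment — a few binomial standard errors
at that size). The analysis scripts use n = 10,000 cohorts; all stages run in
seconds.

## Limitations

* Applicability is purely reading-frame arithmetic: it does not predict
  whether the truncated protein retains function, and the reading-frame rule
  itself has documented exceptions in both directions.
* Partial-exon deletions/duplications and complex rearrangements are not
  modelled; nucleotide-level HGVS support covers only the exon-resolution
  subset described above.
* The exon table is a curated reconstruction validated by anchors and
  reachability, not a mechanically derived annotation file; the anchors would
  catch any frame-relevant error, but users with access to a reference
  annotation can drop in their own table via `load_transcript()`.
* Cohort-level percentages depend on the mutation composition supplied;
  synthetic cohorts are emulations, not estimates of any real registry.
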