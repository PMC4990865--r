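---
title: "Identifying seminal fluid proteins from replicated tissue proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying seminal fluid proteins from replicated tissue proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfptools)
```

## The problem

Seminal fluid proteins (SFPs) are made chiefly in the male accessory gland
(MAG) and transferred to the female reproductive tract (FRT) during mating,
where they influence sperm storage, female receptivity and fecundity.
Direct biochemical proof of transfer is rarely available at proteome scale,
so SFP catalogues are inferred by integrating several imperfect lines of
evidence: label-free proteomic detection across tissues and replicates,
predicted secretion signals, sex-specific transcript expression, and
homology to SFPs already described in other insects. `sfptools` implements
that integration as a deterministic, fully specified decision cascade, so a
catalogue can be recomputed, audited and stress-tested.

## The procedure and its assumptions

**PSM filtering.** Scored peptide-spectrum matches from a search against the
concatenation of a real (target) and a decoy protein database are
thresholded at a target–decoy false discovery rate. We use the simple
estimator $\widehat{FDR}(c) = d(c) / \max(1, t(c))$, where $d(c)$ and $t(c)$
count decoy and target PSMs with score $\ge c$, and keep everything at or
above the smallest observed score with $\widehat{FDR}(c) \le \alpha$
(default $\alpha = 0.01$). This assumes decoys are exchangeable with false
targets — the standard target–decoy premise. Ties at the cutoff are kept.
If no cutoff qualifies the run keeps nothing rather than failing. The
threshold is applied globally per run by default; a per-sample mode is
available (`fdr_scope = "per_sample"`) since per-run versus per-sample
filtering is a genuine design choice in replicated designs.

**Protein inference.** A protein is present in a sample iff at least one
kept target PSM maps to it. There is no parsimony grouping: shared peptides
credit every protein they match. This overstates evidence for homologous
families, which is acceptable here because the downstream rules operate on
tissue-level presence rather than quantitation.

**Replicate rule.** A protein is *detected* in a tissue iff present in at
least `replicate_min = 2` of its `n_replicates = 3` replicates, evaluated
independently per tissue. Requiring reproducibility within a tissue is the
main guard against one-hit wonders in data-dependent acquisition.

**The cascade.** Candidates are proteins detected in both MAG and mated-FRT
(both are necessary for a transfer interpretation). Candidates are then
classed in a fixed order:

1. signal peptide (before or after CDS re-prediction) → SECRETED;
2. otherwise, absent from unmated-FRT **and** male-specific expression →
   SECRETED;
3. otherwise, homology to another insect's SFPs → UNCONFIRMED;
4. otherwise → CANDIDATE_UNCLASSIFIED.

The order matters and is deliberate: the signal-peptide rule is stated for
all detected proteins, the male-specific rule explicitly targets the
signal-peptide-negative remainder, and homology is the fallback for
candidates with no secretion evidence. With this order the secreted count
decomposes exactly as
`SECRETED = (candidates with SP) + (SP-negative, unmated-absent,
male-specific candidates)`, the identity the summary reports.
CANDIDATE_UNCLASSIFIED exists for totality; in well-behaved data it is
empty. Separately, signal-peptide proteins seen **only** in the MAG are
flagged MAG_ONLY_SECRETED — plausible SFPs whose products may be degraded
or modified in the female — and are never counted among SECRETED.

**Expression evidence.** Counts are normalized as
$RPKM = r \cdot 10^9 / (L \cdot N)$ with $r$ the read count, $L$ the gene
length in bp and $N$ the library's total mapped reads. A gene is
*expressed* iff RPKM strictly exceeds 0.3; *male-specific* iff expressed in
at least one male library and in no female library. The male-specificity
rule is presence/absence, not fold-change, because the flag feeds a boolean
cascade; where a study derives the flag differently it can be supplied
directly as a `male_specific` column, bypassing the rule.

**Homology marks.** Per protein and reference species: a conserved-domain
accession shared with that species' SFP set gives a Domain mark, else a
blastp hit with E-value strictly below 1e-5 gives a Blast mark; Domain
shadows Blast. Domain identity is matched on the accession, not the
superfamily. A separate megablast filter (E < 1e-20 and identity > 95 %,
both strict) supports scaffold localization.

## Tunable parameters

| parameter | default | unit / meaning |
|---|---|---|
| `fdr_alpha` | 0.01 | PSM-level target–decoy FDR |
| `replicate_min` | 2 | replicates per tissue required for detection |
| `n_replicates` | 3 | replicates per tissue in the design |
| `rpkm_expressed_threshold` | 0.3 | strict RPKM cutoff for "expressed" |
| `blastp_evalue_max` | 1e-5 | strict cutoff for a Blast mark |
| `megablast_evalue_max` | 1e-20 | strict, scaffold localization |
| `megablast_identity_min` | 95 | %, strict, scaffold localization |
| `male_libraries`, `female_libraries` | MALE / FEMALE | libraries compared for male-specificity |
| `share_basis` | MAG | library whose RPKM is accumulated for shares |

All comparisons at published thresholds are strict (`<`, `>`): RPKM exactly
0.3 is not expressed, a blastp hit at exactly 1e-5 earns no mark, megablast
identity exactly 95 is dropped. The boundary behaviour is pinned by tests.

## The synthetic-data generator

`generate_sfp_dataset()` emulates the study design end to end: six planted
protein classes (signal-peptide secreted with and without unmated-FRT
presence, male-specific secreted, unconfirmed homologs, MAG-only
signal-peptide proteins, background), a 3-tissue × 3-replicate detection
layout, normally distributed target and decoy PSM scores, log-normal
expression over MAG/MRT/male/female libraries, and homology realized half
through shared domains and half through blastp hits. Default class counts
(55 + 29 signal-peptide secreted, 10 male-specific, 124 unconfirmed, 14
MAG-only, 100 background) reproduce the composition of the motivating
study, so a zero-noise run recovers 218 candidates partitioning into 94
secreted and 124 unconfirmed.

Choices worth stating:

* **Dropout defaults to 0.** The planted tissue templates encode *observed*
  detection patterns, which already embed the real experiment's
  missingness; applying dropout on top would double-count noise. Dropout
  is a first-class parameter (`replicate_dropout`, or `degrade_dataset()`
  with coupled randomness, under which presence is provably monotone) for
  robustness experiments.
* **Score model.** Targets N(30, 4) and decoys N(12, 4) are well separated,
  so essentially all planted presence survives the 1 % FDR filter; decoy
  PSMs are 25 % of target PSMs. Separability is a parameter, not an
  assumption — overlap it to study the filter.
* **Planted expression share.** The secreted group's MAG expression is
  rescaled so that its accumulated-RPKM share within the candidate set is
  exactly `secreted_share` (default 0.911, high MAG expression being the
  expected profile of true SFPs). The complementary unconfirmed share is
  then 8.9 %. Integer read-count rounding perturbs the realized share by
  well under 0.01 points.
* Protein identifiers are drawn at random and encode nothing; planted truth
  lives only in the `truth` table, so the pipeline stays blind.

What the generator does **not** emulate: spectra and peptide-level
properties (scores are drawn, not computed), sequence-level signal peptides
(flags are planted, not predicted), shared peptides across proteins,
correlated replicate failures, and compositional biases of real DGE
libraries. Passing tests therefore demonstrate that the *rules* are
implemented exactly and recover planted structure — not that the upstream
search, SignalP or expression estimates are accurate on real data.

## Numerical and degenerate-input behaviour

Cutoff scans consider every observed score, so results are exact, not
grid-approximated. Shares over a partition sum to 100 within 1e-6 absolute;
a zero-RPKM candidate set yields an empty share table with a warning rather
than a division error. Empty call sets give all-zero summaries and
header-only reports. Readers validate every row and fail with the file line
on the first malformed value; nothing is silently dropped. Writing and
re-reading any table reproduces it field-for-field.

## Problem sizes

The shipped tests enumerate all $2^6$ evidence profiles against an
independently written oracle, compare the FDR scan with a brute-force scan
on 1000 random PSM instances (up to 80 targets and 40 decoys each, a
quarter with tied integer scores), run the full pipeline on the
332-protein study-shaped dataset, and check share conservation on 100
random partitions of up to 218 proteins — sizes at which every oracle is
exact and the whole suite runs in well under a minute.

## Known limitations

Protein inference ignores peptide sharing; FDR control is at PSM level
(no protein-level q-values); male-specificity is presence/absence at a
fixed threshold; the functional-category keyword ruleset is a curated
reconstruction and should be extended per study; and "unconfirmed" status
is, by construction, homology transfer — it cannot distinguish a true
transferred SFP from an abundant FRT-resident protein.
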