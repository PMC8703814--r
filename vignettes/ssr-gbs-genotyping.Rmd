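---
title: "Amplicon-based microsatellite genotyping: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplicon-based microsatellite genotyping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrgbs)
library(dplyr)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are codominant length
polymorphisms: alleles differ by the number of copies of a 2-5 bp motif.
They remain the workhorse of cultivar identification in clonally
propagated crops, because decades of reference databases exist and because
fragment sizes can be scored from tiny or degraded DNA. Classical scoring
by PCR and capillary electrophoresis (PCR-CE) is accurate but manual:
electropherograms are read by eye, and slippage/stutter artifacts make
that reading skilled work.

Sequencing the same amplicons on a short-read instrument ("SSR-GBS")
replaces the electropherogram with read counts per *digital allele
length* - the exact merged-read length in base pairs, primers included.
This package implements that pipeline end to end and, crucially, the
calibration layer that makes an automated sequencing-based caller agree
exactly with an existing CE database, so that both assays can feed one
variety-identification database.

## Pipeline model

1. **Merging.** Each paired-end read pair is merged into one amplicon
   sequence. Candidate gapless alignments between R1 and the reverse
   complement of R2 are enumerated over all offsets (including
   read-through "outie" orientations). A candidate is admissible when its
   overlap is within `[min_overlap, max_overlap]` (defaults 10 and
   300 bp) and its mismatch fraction is at most `max_mismatch_density`
   (default 0.5). Among admissible candidates the package maximises the
   alignment score `matches - 2 * mismatches`, breaking ties by lower
   mismatch density, then shorter merged length, then innie orientation.
   A pure longest-overlap rule was rejected because at a permissive
   mismatch density a longer but half-wrong overlap can displace a short
   exact one; the score makes the exact overlap win while still
   tolerating sequencing errors. Consensus bases take the
   higher-quality read at disagreements (ties go to the forward read).
   The contract that matters downstream is only that error-free and
   low-error pairs reproduce the true amplicon length, which is asserted
   by simulation round-trips.

2. **Demultiplexing.** A merged read is assigned to a marker when it
   begins with the marker's forward primer and ends with the reverse
   complement of its reverse primer, each anchored, substitutions only,
   with at most `max_mismatches` (default 0) mismatches; IUPAC codes in
   primers match their base sets. Both read orientations are tried.
   Reads matching no marker or more than one are counted as unassigned
   or ambiguous, never silently assigned. Indels are not tolerated
   because an indel in a primer would shift the digital length, whose
   integrity is the point of the method.

3. **Counting.** The allele is the full merged length. Counts per
   (variety, marker, length) are reduced to the four most common alleles
   with frequencies over the *total* depth of the cell. Only the top two
   alleles are ever used for calling; ranks three and four are reported
   because they reveal stutter bands and other artifacts to QC.

4. **Calling.** With per-marker threshold `alpha`: if the first allele's
   frequency `f1 > alpha` the genotype is homozygous for that allele;
   if `f1 <= alpha` it is heterozygous for the first and second alleles.
   The boundary is strict, with no epsilon; `f1 == alpha` is a
   heterozygote. Cells with no reads, with depth below `min_depth`
   (default 10 reads), or with `f1 <= alpha` but only one observed
   allele, are reported as missing with a status rather than called.

## Calibration against a CE reference

Given profiles for varieties that already have CE genotypes:

* **Size offset.** CE sizes are estimates against a size standard and
  differ from true sequence length by a marker-specific constant. The
  package defines `ce_offset = CE - GBS` and estimates it as the mode of
  the per-allele differences, pairing sorted alleles positionally within
  each variety; ties prefer the smaller absolute offset. The positional
  pairing uses reference zygosity (top allele for reference homozygotes,
  top two for heterozygotes), which avoids the circularity that calling
  would itself require a threshold.

* **Feasible alpha interval.** A reference heterozygote is reproduced by
  any `alpha >= f1`; a reference homozygote by any `alpha < f1`. The
  feasible set is therefore `[max het f1, min hom f1)`, reported as
  `alpha_min`/`alpha_max`, and it is valid only if every variety's top
  (or top-two) alleles equal the reference alleles after offset
  correction - no threshold can repair an allele-identity conflict. The
  reported optimum is the interval midpoint rounded *half-up* at two
  decimals (`alpha_midpoint()`); half-even rounding would misreport
  midpoints like 0.745. A grid-search oracle (calling every variety at
  each alpha on a 0.01 grid and keeping perfectly concordant values) is
  used in the test suite to confirm the closed-form endpoints.

* **Dropout.** A reference allele with no match even among the top four
  sequenced alleles (after offset correction) is a dropout - the
  signature of a null allele from primer-site variation. Varieties below
  `min_depth` are skipped: absent reads are not evidence of a null
  allele.

* **Classification.** Precedence: average depth `< 50` reads (the
  panel-survey convention) makes a marker `low_depth`; otherwise any
  dropout makes it `dropout`; otherwise an infeasible interval is
  `stutter_error` when every offending allele sits exactly one motif
  unit from the first allele (the stutter position), else `discordant`;
  otherwise `suitable`. Only suitable markers enter the automated
  database (`calibrated_panel()`).

* **Repeatability.** Between replicate runs, the Pearson correlation of
  first-allele frequencies over shared varieties (at least three) is the
  repeatability statistic.

## Locus statistics and discrimination

Allele frequencies come from gene counting (two copies per typed
variety), with missing cells excluded marker-wise. `He = 1 - sum(p^2)`
(Nei's gene diversity; an unbiased small-sample variant is available via
`unbiased = TRUE` but is not the default, since reference tables in this
field report the plain estimator), `PIC = He - sum_{i<j} 2 p_i^2 p_j^2`,
and `Ho` is the fraction of heterozygous typed varieties. Variety
discrimination checks for pairs identical at every mutually typed marker.
The dendrogram uses the shared-allele distance
`d = 1 - shared/(2 * markers)` (the package documents this choice; no
single canonical metric exists for SSR fingerprinting) and UPGMA
agglomeration via `stats::hclust(method = "average")`, returned as an
`ape` tree with ultrametric leaf heights at half the merge distance.
Approximately-unbiased bootstrap p-values are out of scope; a plain
bootstrap over markers could be added by resampling columns, and would
not be comparable to AU values.

## The simulator

`sim_marker_panel()` + `sim_config()` + `simulate_dataset()` generate
paired FASTQ with known truth. The generator emulates what matters to
length-based calling:

| phenomenon | default | rationale |
|---|---|---|
| read depth | negative binomial, mean 200, size 5 | overdispersed depths spanning roughly tens to thousands, as seen across real marker panels |
| stutter (-1 motif unit) | 10% for dinucleotides, 1% for motifs >= 3 bp | stutter is the dominant artifact for 2 bp motifs and the reason tri-/tetra-/pentanucleotide panels are preferred |
| slippage (+/-1 bp) | 1%, symmetric | the 1 bp satellite peaks seen in amplicon sequencing |
| amplification bias | het allele ratio uniform in [1, 1.3] | pushes het `f1` off 0.5, as multiplex PCR does |
| substitution errors | 0.001/base | typical short-read scale; affects demultiplexing, not length |
| dropout | explicit (marker, variety, allele) list, factor 0 | models primer-binding-site variants |
| qualities | constant Phred 35 | quality modelling is irrelevant to length-based genotyping |

Flanks and primers are rejection-sampled so no primer occurs internally,
and read length is validated so every amplicon's two reads overlap by at
least 10 bp. Everything is deterministic given the configuration seed.

What the simulator does **not** model: PCR chimeras, index hopping,
quality-score decay, polymerase-specific error spectra, and length
homoplasy (different sequences of equal length). Passing simulated tests
therefore demonstrates the pipeline's arithmetic and logic, not
robustness to every laboratory artifact; the bundled reference survey of
a real 116-variety apple/pear/tea panel is the desk-scale link to real
data.

## Numerical and design choices

* Strict threshold boundary (`f1 > alpha` homozygous), no epsilon.
* Half-up rounding only where two-decimal reporting conventions require
  it (`alpha_midpoint()`); all internal arithmetic is full precision.
* Profile count ties break toward the smaller allele length; offset ties
  toward the smaller absolute value; UPGMA ties resolve by input label
  order - all total orders, so every result is deterministic.
* Per-variety `min_depth` (default 10) is deliberately separate from the
  per-marker average-depth threshold (default 50): the former hides
  single uncallable cells, the latter discards markers.
* Genotype tables are long tibbles; `"a/b"` cells with `a <= b` and
  `"NA"` for missing values in the CSV representation; marker panels are
  TSV with a fixed header.

## Problem sizes in the test suite

The suite validates merging on 200-read round-trips, the alpha interval
against the grid oracle on 100 random fixtures, and the full pipeline on
a simulated panel of 20 varieties by 6 markers at a mean depth of 500
reads (about 60,000 read pairs), which the package processes in well
under a minute. The acceptance script reruns the same computations from
scratch and additionally reproduces the bundled reference survey's
summary numbers (mean optimum threshold, interval widths, per-species
heterozygosity averages, the 27-of-37 suitability outcome, and the -4 bp
minimum CE size difference).

## Known limitations

* Diploid calling only; the top-two rule cannot express triploid or
  chimeric genotypes.
* No stutter-aware correction at call time: dinucleotide markers whose
  heterozygotes hide behind stutter are meant to be excluded by
  calibration, not rescued.
* Demultiplexing tolerates substitutions but not indels in primers.
* The CE offset is assumed constant per marker; dye- and
  composition-dependent nonlinearity across the allele range is not
  modelled, which matches how such databases are used in practice.
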