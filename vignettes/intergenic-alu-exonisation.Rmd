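---
title: "Detecting intergenic Alu exonisation from splice-junction evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intergenic Alu exonisation from splice-junction evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aluexon)
library(data.table)
```

## The biological problem

*Alu* elements are primate-specific ~300-bp SINE retrotransposons. Inserted
in antisense orientation, their sequence carries cryptic splice signals —
a pyrimidine-rich tract feeding a 3' splice site and potential 5' splice
sites — that the spliceosome can recognise, creating a cryptic exon
("exonisation"). Most studied exonisation events are intronic. This package
targets a distinct configuration: *Alu* elements in the **intergenic** region
downstream of a gene's last genuine polyadenylation site. When RNA
polymerase II reads through the polyA site before cleavage, the nascent
transcript exposes the downstream *Alu*; if its cryptic 3' splice site wins
the kinetic competition against cleavage/polyadenylation, the *Alu*-derived
exon is spliced onto the gene and a **new transcript 3' end** is formed.
Two mechanisms are distinguishable from junction evidence:

* **terminal-exon skipping** — a junction runs from an annotated donor
  upstream of the terminal exon directly to the *Alu* acceptor, removing the
  terminal exon (and its 3' UTR) entirely;
* **cryptic 5' splice-site activation** — a donor inside the terminal exon
  body splices to the *Alu* acceptor, truncating the 3' UTR.

Both may co-occur in one gene. The package detects such events from aligned
split reads plus standard annotation tracks, quantifies them, and provides
the comparative-genomics filter that asks whether an annotated human
isoform carries an *Alu*-derived 3' extension absent from the mouse
orthologue.

## Pipeline model

The pipeline consumes predicted exons (e.g. from a transcript assembler run
permissively), a RepeatMasker-style *Alu* track, gene annotation (GTF), a
polyA-site track, and split-read alignments for two conditions (a control
and a condition in which exonisation is derepressed, called `kd`
throughout). Stages:

1. **Detection.** A predicted exon becomes a candidate *Alu* exon iff
   (i) its acceptor or donor lies inside an *Alu* element antisense to the
   exon strand, (ii) that splice site coincides exactly with a junction
   observed in `min_junction_reads` or more reads, and (iii) no other
   predicted exon overlaps it on the same strand. Identical predictions are
   collapsed before the overlap test, so duplicates are not ambiguity.
2. **Gene linkage.** Candidates are linked to genes by breadth-first search
   over the junction graph (junction endpoints, closed over predicted exon
   bodies), up to `max_hops` (default 3) hops; ties prefer the nearest
   upstream gene.
3. **Locus classification.** The last genuine polyA site of the linked gene
   is the strand-wise most downstream annotated site across all its
   transcripts. A candidate lying entirely downstream of it is
   **intergenic**; `distance_bp` is measured from the cleavage position to
   the gene-proximal exon boundary. Everything else is **intronic** and is
   reported but not scenario-classified.
4. **Scenario assignment.** Junctions into the *Alu* acceptor are split by
   their donor: annotated donors upstream of the terminal exon support
   skipping; donors strictly inside the terminal exon body support cryptic
   5'ss activation; both classes at `min_reads` or more give `both`.
5. **Quantification.** Splicing contribution, downstream cryptic exon
   count, and per-condition inclusion (below).

## Quantities and their estimators

**Splicing contribution** at the *Alu* 3' splice site is the fraction of
junction-spanning reads among all reads overlapping the acceptor. A read is
*junction-spanning* when it contains the exact intron gap ending at the
acceptor, *continuous* when one aligned block covers at least `flank`
(default 10) nt on **each** side of the splice site. The one-sided reading
of "on either side" was rejected deliberately: a read touching only one
side cannot distinguish spliced from unspliced molecules. The flank is
switchable. With no qualifying read the value is reported absent rather
than zero.

**Inclusion** is the molar fraction of the gene's transcripts containing
the *Alu* exon, estimated per condition from isoform-discriminating reads:

* *Alu*-isoform support: junction reads into the *Alu* acceptor.
* canonical support: for skipping, junction reads into the terminal-exon
  acceptor; for cryptic 5'ss activation (and `both`), reads overlapping the
  polyA-proximal terminal-exon body beyond the cryptic donor — the only
  region the *Alu* isoforms do not retain (for cryptic events the
  terminal-exon acceptor junction is shared by both isoforms and is
  therefore uninformative).

Raw counts are biased by isoform length: a junction is captured by a
uniformly placed read of length $L$ with probability
$w/(M - L + 1)$, where $M$ is the isoform length and $w \le L - 1$ the
read-start window spanning the junction. The estimator therefore
normalises each count by its capture window (an effective-length
correction, as in isoform-abundance estimation) before forming the ratio;
isoform structures are reconstructed from the annotation, the call and the
downstream cryptic exon chain. For `both` genes the two *Alu* structures
are mixed with weight `both_mix` (default 0.5). The returned counts allow
a binomial standard error on the denominator.

**Relative isoform abundance** from FPKM tables is the FPKM sum of
*Alu*-exon-containing isoforms over the FPKM sum of all isoforms of the
gene per tissue, absent where the gene is silent. For reporting,
`log2(FPKM + 1)` is provided. A gene is flagged *tissue-specific* when the
spread (max − min) of the relative abundance across expressed tissues
exceeds `spread_threshold` (default 0.10, echoing the 10%-inclusion
screening convention for tissue panels); silent tissues are excluded from
the spread.

**Ortholog filter.** A human/mouse pair passes iff (i) some human
transcript extends strand-wise beyond the human exon corresponding to the
mouse terminal exon, (ii) at least one *Alu*-flagged human exon lies
entirely downstream of that exon, and (iii) some such *Alu* exon has no
corresponded (conserved) exon downstream of it. Exon correspondence is an
input — computing orthology or exon-level alignment is out of scope — and
"conservation" is read at the annotation level, the only interpretation
the input supports; criterion (iii) uses exists-semantics over *Alu* exons
so that a conserved exon wedged between two *Alu* exons does not veto a
clean extension further downstream.

## The synthetic-data generator

Every statistical claim of the package is validated against data with
planted truth. `generate_annotation()` lays out genes (alternating
strands) on one chromosome, each with three 150-bp constitutive exons
(800-bp introns) and an 800-bp terminal exon whose 3' end carries the
genuine polyA site; a second genuine site upstream is added with
probability 0.3 so the "last site" logic is exercised. Event genes get an
antisense *Alu* element whose 120-bp exon sits at a distance sampled
log-uniformly over 41 bp–21.4 kb — the envelope such events span in vivo;
the generator plants the distance as the classifier measures it (cleavage
position to gene-proximal boundary). Cryptic-5'ss genes carry a cryptic
donor 500 bp into the terminal exon; with probability 0.26 an event gains
one or two further downstream cryptic exons; a new polyA position follows
the last planted exon. Event-free genes receive a decoy antisense *Alu*
downstream, so specificity is tested against a realistic background, and
their predicted-exon track contains only annotated exons (a noise-free
assembler).

`simulate_reads()` draws each read from the *Alu* isoform with the
planted per-condition inclusion probability (binomial per read; `both`
genes mix the two structures with weight 0.5) and places read starts
coverage-uniformly along the chosen isoform on a deterministic stratified
grid. The grid guarantees that every junction of an isoform receiving at
least $1 + (M - L)/(L - 1)$ reads is spanned — the property behind the
exact-recovery tests — while the binomial isoform draw preserves the
sampling noise that the inclusion estimator must survive. Default
inclusion levels are uniform on [0, 0.15] under control and [0.1, 0.8]
after derepression, mirroring the regime where such exons are near-silent
until a repressor is lost. There is no sequencing-error or coverage-bias
model: all statistics consume junction geometry and block positions, not
base calls. The simulator also emits mature-isoform reads only — no
unspliced pre-mRNA readthrough — so the splicing contribution at every
simulated acceptor is 1 by construction; the contribution statistic is
instead exercised against hand-built mixed read sets and an independent
per-read classifier. Consequently, passing tests demonstrate correctness
of the coordinate logic and estimators under ideal alignment, not
robustness to alignment artefacts, soft-clip ambiguity, incomplete
splicing or PCR duplicates in real data.

`generate_fpkm_matrix()` gives event genes a canonical and an *Alu*
isoform; per tissue, total expression is log-normal and the *Alu* share is
Beta-distributed around the gene's knockdown inclusion (concentration 30),
with ~5% of gene/tissue pairs silenced to exercise the undefined
denominator. FPKM values are rounded to 4 decimals and the stored truth is
the ratio of the written values, so recovery is exact by construction.

## Numerical and design choices

* Internal coordinates are 0-based half-open throughout; GTF converts at
  the boundary. This makes adjacency-versus-overlap unambiguous and
  confines ±1 arithmetic to two I/O functions.
* A polyA "site" is a single cleavage position; wider track intervals
  resolve to their strand-wise 3'-most base.
* Distance is measured to the *Alu* exon's gene-proximal boundary by
  default; `distance_to = "alu_element"` switches to the element boundary
  (the minimum-gap reading), since the field reports both.
* Junction-to-splice-site matching is exact (`fuzz = 0`): both simulated
  and aligner-derived junctions are base-precise. A fuzz window exists but
  is off by default.
* `min_junction_reads = 1` and `min_reads = 1`: the detection criterion is
  "supported by junction-spanning reads", and one exact junction read is
  already strong evidence; thresholds are configurable for noisy libraries.
* `max_hops = 3` covers gene → *Alu* exon → cryptic exon chains observed
  in practice; deeper chains would need a larger cap.
* SAM dialect: single-end, M/N/S only, FLAG 0x10 for strand. Junction
  assignment is coordinate-based and ignores read strand, so unstranded
  libraries work; D/I/H/P/=/X records are rejected loudly rather than
  silently misinterpreted.
* PolyA-to-gene assignment uses the track's name column when it matches a
  gene id, else the nearest same-strand gene within 10 kb — polyA track
  formats vary, and mis-assignment beyond that window is likelier than a
  true orphan site.
* Degenerate inputs: 0/0 splicing contribution, zero-denominator inclusion
  and silent-gene relative abundance are reported absent (`NA`), never
  coerced to 0; genes without polyA sites fall back to the gene 3' end
  with a warning; unlinked candidates are retained with
  `locus_class = "unlinked"`.

## Problem sizes used in validation

The bundled checks run a 200-gene survey at depth 500 (read length 75 nt,
50% event genes, scenario mix 0.45/0.37/0.18) for exact planted-truth
recovery, a 60-gene run at depth 2000 for inclusion calibration, a
110-gene run for oracle equivalence of the splicing contribution
(>10,000 reads, >50 acceptors), 1,000 random matrices for the abundance
identities, and the 8-class ortholog truth table. These sizes were chosen
to give every stochastic check a comfortable margin while keeping a full
validation run in the minutes range on one core.

## Known limitations

* The detector consumes *predicted* exons; exon discovery from raw
  coverage is out of scope, so sensitivity is bounded by the assembler.
* Junction evidence cannot see polyadenylation directly: the "new" polyA
  site of an *Alu* isoform is not called, only the splice architecture.
* Inclusion estimation assumes uniform read starts within an isoform;
  strong 3' bias (degraded RNA, some library preparations) would bias the
  effective-length correction.
* The ortholog filter trusts the input correspondence; it cannot detect
  conservation that the correspondence fails to record.
* Differential-inclusion significance testing between conditions is out of
  scope; the package reports per-condition estimates with their counts.

## A worked run

```{r worked-run}
cfg <- run_config(out_dir = file.path(tempdir(), "alu_demo"),
                  sim = simulation_config(n_genes = 30L, seed = 11L),
                  log_level = "quiet")
res <- run_pipeline(cfg)
res$calls[locus_class == "intergenic",
          .(gene_id, scenario, distance_bp,
            splicing_contribution = round(splicing_contribution, 2),
            downstream_cryptic_exons,
            inclusion_control = round(inclusion_control, 2),
            inclusion_kd = round(inclusion_kd, 2))]
```

```{r compare}
cmp <- compare_to_truth(res$calls, file.path(cfg$out_dir, "truth.tsv"))
c(sensitivity = cmp$sensitivity, specificity = cmp$specificity)
```
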