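# aluexon

Detection, classification and quantification of **intergenic *Alu*
exonisation** events from RNA-seq splice-junction evidence.

## The problem

*Alu* elements — primate-specific ~300-bp SINE retrotransposons — carry
cryptic splice signals when inserted antisense to a gene. Beyond the
well-studied intronic case, *Alu* elements in the intergenic region
*downstream of a gene's last genuine polyadenylation site* can be
exonised: RNA polymerase II reads through the polyA site before cleavage,
and the cryptic 3' splice site in the *Alu* competes kinetically with
polyadenylation and terminal-exon splicing. The result is a new transcript
3' end, via one of two mechanisms distinguishable from junction reads:

* **terminal-exon skipping** — splicing from an annotated upstream donor
  directly to the *Alu* acceptor replaces the whole terminal exon;
* **cryptic 5' splice-site activation** — a donor inside the terminal exon
  body splices to the *Alu* acceptor, truncating the 3' UTR

(both can co-occur in one gene). `aluexon` is for transcriptomicists who
have split-read alignments plus standard annotation tracks and want these
events called, mechanistically classified and quantified, with a
simulation harness that validates every statistic against planted truth.

## What it computes

Candidate *Alu* exons are predicted exons with a splice site inside an
antisense *Alu* element, exactly matching a junction with at least
`min_junction_reads` reads, and no overlapping predicted exon. Candidates
are linked to genes through the junction graph (≤ `max_hops` hops) and
classified **intergenic** when entirely downstream of the gene's last
genuine polyA site. Per intergenic call the package reports:

* **distance** (bp) from the polyA cleavage position to the gene-proximal
  *Alu*-exon boundary;
* **scenario** from junction donors: upstream annotated donor → skipping;
  donor strictly inside the terminal exon → cryptic 5'ss; both → `both`;
* **splicing contribution** — junction-spanning reads over all reads
  covering the 3' splice site (continuous reads must align ≥ 10 nt on
  each side);
* **downstream cryptic exons** reachable by the junction chain leaving the
  *Alu* exon donor;
* **inclusion** per condition — isoform-discriminating read counts with an
  effective-length (capture-window) correction, so the estimate tracks the
  molar fraction of *Alu*-isoform transcripts.

Two further modules cover the comparative side: tissue-wise **relative
abundance** of *Alu*-exon-containing isoforms from FPKM tables
(`sum(FPKM_alu) / sum(FPKM_all)` per gene and tissue, with `log2(FPKM+1)`
reporting and a tissue-specificity flag), and the three-criterion
**human/mouse ortholog filter** for annotated *Alu*-derived 3' extensions:
(i) the human transcript extends beyond the exon corresponding to the
mouse terminal exon, (ii) an *Alu* exon lies downstream of it, (iii) no
conserved exon follows the *Alu* exon.

## Worked example

The package ships a synthetic-data generator that plants events with known
truth, which doubles as the quickest demonstration:

```r
library(aluexon)

cfg <- run_config(out_dir = file.path(tempdir(), "alu_demo"),
                  sim = simulation_config(n_genes = 30L, seed = 11L),
                  log_level = "quiet")
res <- run_pipeline(cfg)   # simulate -> detect -> classify -> abundance

res$calls[locus_class == "intergenic",
          .(gene_id, scenario, distance_bp,
            contribution = round(splicing_contribution, 2),
            cryptic_exons = downstream_cryptic_exons,
            incl_ctrl = round(inclusion_control, 2),
            incl_kd = round(inclusion_kd, 2))]
#>     gene_id               scenario distance_bp contribution cryptic_exons
#>  1: gene002 terminal_exon_skipping         203            1             0
#>  2: gene003 terminal_exon_skipping          59            1             0
#>  3: gene005 terminal_exon_skipping         157            1             0
#>  4: gene007            cryptic_5ss        2447            1             0
#>  5: gene011 terminal_exon_skipping          45            1             0
#>  6: gene012 terminal_exon_skipping        1124            1             0
#>     incl_ctrl incl_kd
#>  1:      0.01    0.53
#>  2:      0.11    0.29
#>  3:      0.07    0.49
#>  4:      0.03    0.40
#>  5:      0.03    0.58
#>  6:      0.03    0.52
#> ... (15 intergenic calls in total)
```

Each row is one called *Alu* exon: `gene002` skips its terminal exon in
favour of an *Alu* exon 203 bp past the polyA site; its estimated
inclusion rises from 1% under control conditions to 53% in the
derepressed (`kd`) condition. `contribution = 1` means every read at the
acceptor is junction-spanning (the simulator emits mature transcripts
only). Recovery against the planted truth:

```r
cmp <- compare_to_truth(res$calls, file.path(cfg$out_dir, "truth.tsv"))
c(cmp$sensitivity, cmp$specificity)
#> [1] 1 1
```

On real data, point the same stages at your own files via
`run_config(stages = c("detect", "classify"), paths = list(gtf = ...,
alu_bed = ..., polya_bed = ..., predicted_bed = ..., sam_control = ...,
sam_kd = ...))`. A thin command-line wrapper with subcommands
`simulate | detect | classify | abundance | orthologs | run | compare`
lives at `inst/cli/aluexon`.

The methods vignette (`vignettes/intergenic-alu-exonisation.Rmd`)
documents the model, the estimators, the simulator's assumptions and the
package's numerical choices.

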