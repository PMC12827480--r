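# metadecay

Motif-integrated analysis of m6A methylation, AU-rich elements (AREs) and
mRNA decay in activated CD8+ T cells — as a tested, reusable R pipeline
with a ground-truthed synthetic-data generator.

## The problem

Two 3'UTR features independently destabilise mRNAs: N6-methyladenosine
(m6A), deposited in RRACH pentamers (R = A/G, H = A/C/U), and AU-rich
elements (WWAWW pentamers, W = A/U). When an RRACH sits within a few
nucleotides of an ARE, the pair may act as a distinct regulatory unit — an
*ARE-flanking m6A site* — marking transcripts that decay sharply upon
T-cell activation ("meta-unstable" mRNAs). Testing this requires
integrating three signal types on a common motif map:

* **crosslink tracks** (miCLIP-style): per-nucleotide event counts, where a
  crosslink is the read start minus one; high-confidence crosslinks are
  those inside peaks with counts at or above the 0.7 region quantile, and
  each 5-mer gets a positional enrichment z-score against distal
  background resamplings (k = 5, proximal window 10 nt, distal 150 nt,
  smoothing 6);
* **conversion pileups** (GLORI-style): methylation read out as the
  unconverted fraction A/(A+G) (forward strand; T/(T+C) reverse), sites
  called at depth >= 15 and ratio >= 0.1;
* **metabolic-labelling time courses** (SLAM-seq-style): T>C conversion
  rates over a uridine chase fitted to y(t) = exp(-k t); t1/2 = ln(2)/k,
  kept when R-squared > 0.5.

Downstream, 3'UTR x (sample, motif-class) count matrices are normalised by
median-of-ratios size factors and clustered (crosslink clusters c1–c4,
conversion clusters ci/cii); half-life distributions are compared by
two-sample Kolmogorov–Smirnov tests stratified by RRACH-to-ARE distance
(±3/5/15/25/50 nt); and a random-forest classifier with *conditional*
permutation importance predicts unstable (< 3.0 h) versus stable (> 5.3 h)
transcripts from ten m6A-signature features.

Deposited sequencing data are not shipped; a seed-deterministic generator
(`generate_transcriptome()`, `simulate_crosslinks()`, `simulate_glori()`,
`simulate_slam()`, `assign_modules()`) produces every input with a
ground-truth manifest, so all recovery claims are scored exactly.

## Worked example

The numbered scripts under `analysis/` run the whole study over files in
`results/` (`Rscript analysis/01_simulate.R` … `07_classifier.R`). What
they print, and what it means:

```
02: scanned 2356 RRACH, 3618 ARE, 864 CRACH 3'UTR sites; 78% of AREs have
    a RRACH within 50 nt (median |distance| 22 nt)
04: called 6152 m6A site records (795 unique positions); 23.7% of m6A
    counts lie within +/-4 nt of an ARE centre; inhibitor retains 38% of
    the DMSO metagene signal
05: Day5 medians by planted site class:
    composite 1.53 h < isolated 1.73 h < none 3.55 h
06: clusters sized 57/53/49/41; KS D vs no-signal by ARE distance shell:
    (0,3]=0.88, (3,5]=0.74, (5,15]=0.81, (15,25]=0.63, (25,50]=0.43
07: test balanced accuracy 83%, F1 91%, AUC-ROC 0.90
```

Line 04 shows the composite-site signature: a quarter of called m6A counts
sit within ±4 nt of an ARE centre, and METTL3 inhibition removes most of
that signal. Line 05 shows meta-instability ordered by planted site class,
line 06 shows the Kolmogorov–Smirnov separation from the no-signal group
shrinking as the RRACH-to-ARE distance grows, and line 07 shows the
half-life classes are predictable from the m6A signature features.

The same workflow is available programmatically:

```r
library(metadecay)
cfg <- default_config()
cfg$seed <- 1
res <- run_pipeline(cfg)
res$fraction_near_are          # share of m6A counts within +/-4 nt of AREs
res$half_life_summary$Day5     # median + quartiles, activated state
res$report                     # held-out classifier metrics and curves
```

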