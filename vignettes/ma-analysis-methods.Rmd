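---
title: "Methods: mutation-accumulation analysis for haploid microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-accumulation analysis for haploid microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mamut` implements the complete computational analysis of a
mutation-accumulation (MA) experiment in a haploid microbe such as
*Chlamydomonas*: a synthetic-data generator that emulates the statistical
structure of such an experiment, the callable-site and mutation-calling
filter cascade, per-site per-generation rate estimation with
overdispersion and spatial-clustering tests, sequence-context feature
engineering, GC-corrected spectrum statistics, an NG86-style Ka/Ks
estimator, and a regularized (elastic-net) model of site mutability with
calibration and cross-dataset prediction. The `analysis/` scripts run the
stages in order on a simulated experiment and write their tables under
`results/analysis/`.

# The experimental design being modelled

An MA experiment propagates clonal lines through repeated single-colony
bottlenecks, so that nearly all non-lethal mutations fix by drift rather
than selection. Sequencing the endpoints against the ancestor's reference
genome yields de novo mutations; the per-site per-generation rate is

$$\mu = \frac{N_\mu}{N_c \times N_{lines} \times t}$$

where $N_\mu$ is the number of accepted mutations, $N_c$ the callable
genome length in bp, $N_{lines}$ the number of lines, and $t$ the number
of generations. Generations per growth assay follow
$t = (\log N_t - \log N_0)/\log 2$ from colony counts before and after
growth; lines without assays receive the mean of the measured lines.
Stratified rates (per line, contig, feature class or variant class) adjust
numerator and denominator per stratum.

# The synthetic-data generator

The generator defines the study conditions under which every downstream
stage is tested. Its defaults emulate the design of a *Chlamydomonas* MA
experiment:

* **Genome**: GC-rich (target 0.66) multi-contig nuclear genome; the
  default configuration uses 2 Mb across 4 contigs so the full analysis
  runs in minutes on one CPU. A configurable fraction of the sequence is
  overwritten with tiled 1--6 bp repeat units (GC-matched on average) and
  annotated as repeats; gene models (5'UTR, CDS exons, introns, 3'UTR) are
  laid down with intergenic gaps, giving roughly 30--40% coding sequence.
* **Lines and generations**: 26 lines, 788 generations.
* **Rate heterogeneity**: each line's rate is multiplied by a lognormal
  draw (meanlog $-3.01$, sdlog $1.15$ — the shape fitted to real per-line
  rates), normalized to mean 1 so the configured base rate stays the
  expected per-site rate. Per-line event counts are Poisson given the
  multiplier; SNMs and INDELs share the multiplier, which reproduces the
  strong observed between-line SNM/INDEL count correlation ($r > 0.7$ at
  sdlog $\ge 1$).
* **Spectrum**: folded 6-type probabilities defaulting to a strongly
  C$\to$T-dominated, transition-rich spectrum (C$\to$T carries 52% of
  SNMs). Site selection is reweighted by base composition so the marginal
  folded spectrum of generated SNMs converges to the configured
  probabilities; alternate alleles are then drawn conditionally on the
  source base.
* **Context boosts**: named canonical *upstream* trinucleotide contexts
  multiply site mutability (default `CTC = 5, CAC = 5`). A boost named CTC
  elevates the final C of a CTC run on either strand — the reading
  consistent with the TC/CC substrate preference of cytidine-deaminase
  style mutators. The magnitude is not published; 5x is used as a
  conservative default, and property tests plant a 10x effect to verify
  recovery.
* **INDELs**: 24% of events (matching the observed DEL+INS share of all
  mutations), split 56.6%/43.4% deletions/insertions, with geometric
  lengths of mean 3 bp (deletions) and 2 bp (insertions) per the observed
  length summaries. The generating length law is not published; geometric
  is the simplest memoryless choice consistent with the medians.
* **Spike-ins**: probe mutations every 27 kb at deterministic positions,
  planted per line to estimate line-specific callability.

Event positions are drawn effectively without replacement across the
experiment: recurrent same-site hits are vanishingly rare at real genomic
scale, and at the reduced synthetic scale they would be a discreteness
artifact that breaks the biallelic single-line structure of true MA data.

**What the generator does not model**: read-level errors, alignment
artifacts, diploid genotypes, structural variants beyond short INDELs and
the scored classes, and realistic repeat families. Call-quality noise is
parametric and per-site (low-MQ blocks, low-DP and low-GQ sites, rare
multi-line alternate-read artifacts) because the calling filters operate
on summary fields only. Passing tests therefore demonstrate the
correctness of the *analysis* under the stated statistical structure, not
robustness to raw-sequencing pathologies.

# Callable sites and the filter cascade

A site is callable iff all of: MQ $\ge$ 50; site QUAL $\ge$ 100 for
nuclear contigs (70 for organelles); combined depth across lines $\ge$ a
threshold whose default is 167 for nuclear contigs — documented for the
original dataset as one standard deviation below the mean combined DP, and
available as a reusable `mean - 1 SD` rule recomputed per dataset; and
$\ge$ 3 lines haploid-genotyped at the maximum GQ of 99 (the focal line
counts towards the three — the alternative reading is not materially
different and is not implemented).

A candidate mutation is accepted iff its site is callable; the alternate
allele is present in exactly one line; that line has GQ 99; the record is
biallelic; focal depth $\ge$ 6; at most 1/6 of the focal reads carry the
reference allele (a fraction comparison, so 2 of 12 passes and 3 of 12
fails); and no site within 10 bp (inclusive) has $\ge$ 14 lines with more
than 1/6 alternate reads. The cascade is a pure conjunction, so the
accepted set is independent of rule order, and tightening any single
threshold can only shrink it; both properties are tested. Rejections are
logged with the first failing rule. Manual inspection of INDEL/SV
candidates is out of scope; the rejection log doubles as the review list.

Line-specific callability is the fraction of spike-in probes recovered by
the same cascade from per-line probe-planted call sets. The contamination
screen computes share(i, j) — the fraction of line i's alternate alleles
also carried by line j — and flags pairs exceeding the off-diagonal mean
plus 5 SD; rate estimation can then exclude flagged lines while retaining
their mutations for context analyses.

# Rates, overdispersion and clustering

Per-line SNM counts are summarized by $\lambda$ (mean) and $\sigma^2$
(sample variance); their ratio measures overdispersion relative to the
Poisson expectation of 1, computed under the documented assumption of
equal generations across lines. The KS statistic of counts against
Poisson($\lambda$) uses both ECDF sides and a parametric-bootstrap
p-value, because the classical KS null is invalid for discrete
distributions with estimated parameters; the original analysis used a
continuous KS here, which is noted but not reproduced.

Distribution fitting ranks normal, lognormal, gamma, Poisson and
exponential maximum-likelihood fits by AIC. Discrete and continuous
families are compared on the same numeric vector, as the original analysis
did; this mixes probability masses with densities and is retained
deliberately as a documented caveat (the Poisson-vs-lognormal ordering on
genuinely Poisson data holds in the large majority of draws, and the test
asserts exactly that).

The neutral null for between-line variance draws, per replicate, one
Poisson count per line with mean $\mu N_c t$ and records the sample
variance; 1,000 replicates give the null median and 95% interval. This
replaces an external forward simulator: under a haploid, neutral,
no-recombination model with equal generations the per-line count is
exactly Poisson, so nothing more is needed.

Spatial clustering is tested two ways: the inter-mutation distance (IMD)
between SNMs on the same contig, pooled across lines, against IMDs of the
same per-contig counts placed uniformly on callable sites (1,000
iterations, two-sample KS against the pooled null, with a separate
< 10 bp short-range summary including adjacent-pair dinucleotides); and
per-window SNM counts in 1, 10, 100 and 500 kb sections against the same
null. Ties make the two-sample KS conservative for the windowed counts;
the type-I error checks therefore bound the rejection rate from above.

# Sequence context

Window statistics are computed in windows of $w \in \{2, 10, 100, 1000\}$
bp extending upstream and downstream of the site, including the site
(total length $2w + 1$, i.e. 5, 21, 201, 2001): GC content; Shannon
entropy $E = -\sum_b p_b \log_2 p_b / 2$ normalized to $[0, 1]$; and
linguistic complexity $L$, the number of distinct substrings over all
lengths divided by its maximum $\sum_k \min(4^k, n - k + 1)$. The
$\Delta$-statistics ($\Delta GC$, $\Delta E$, $\Delta L$) are the standard
deviation of the statistic across all $W$ windows of length
$W \in \{5, 21, 201, 2001\}$ that contain the site — a single SD across
overlapping windows, not an average of per-phase SDs (the description
admits both readings; the former is implemented, the latter noted as an
alternative). These window lengths make the two scale families exactly
consistent. Sites closer than the window to a contig edge, or with
ambiguity codes in the window, get missing values rather than imputations
and are dropped downstream.

Distinct-substring counting uses a suffix automaton in C++ (the count is
$\sum_s \mathrm{len}(s) - \mathrm{len}(\mathrm{link}(s))$ over automaton
states), making exact sliding-window $L$ linear in window length; the
implementation is verified against brute-force substring enumeration in
the tests. The external tool originally used for these statistics
publishes no formula; the definition here is therefore documented
explicitly and is not claimed to be numerically identical to it.

Trinucleotide contexts of a site are the upstream, surrounding and
downstream triplets including the site, canonicalized so the focal base is
A or C: if it is G or T, all three triplets are reverse-complemented and
upstream/downstream swap. This yields exactly 32 canonical triplets per
slot and makes every context feature invariant under reverse
complementation of the genome (a tested property). Feature classes resolve
overlapping annotation by precedence CDS > 5'UTR/3'UTR > intron, with
unannotated sites intergenic; distances to the nearest feature of each
class are 0 inside a feature.

Alternate-DNA-conformation motifs are scanned with configurable arm/loop
parameters: palindromes (arm $\ge$ 5 equal to the reverse complement of
the opposite arm, loop 0--5), mirrors (arm $\ge$ 5 equal to the reverse of
the opposite arm, loop 0--5), G-quadruplexes (four runs of $\ge$ 3 G with
loops 1--7) and triplexes (homopurine or homopyrimidine mirror repeats,
arm $\ge$ 6, loop $\le$ 8). The defaults are chosen to be detectable in
21-bp windows, the scale at which enrichment near mutated sites is
evaluated (proportion of windows with $\ge$ 1 motif per group,
Kruskal-Wallis rank test, 1,000-sample bootstrap CIs). The original
scans used external binaries with unpublished thresholds, so cross-tool
numeric identity is not claimed.

# Spectrum and Ka/Ks

SNMs are folded onto six types with reference base A or C. Under equal
per-type rates the expected share of a C-source type is $gc/3$ and of an
A-source type $(1-gc)/3$, since a site must carry the source base; the
deviation is observed share over expected share. This reading of the GC
correction exactly reconciles a 52% C$\to$T share at GC = 0.66 with the
published 2.35-fold deviation, which is treated as confirmation. The
genome-mean GC (0.66) is the default correction baseline; conditioning on
callable-site composition instead is exposed through the `gc` argument.
Cross-dataset comparison divides per-type deviations.

Ka/Ks uses NG86-style equal-weight pathway counting on the concatenation
of all coding sequences carrying at least one SNM: per-codon synonymous
site fractions are the fraction of the three possible changes at each
position that preserve the amino acid; observed substitutions are
classified by codon effect; and the ratio is
$(N_{obs,N}/N_{sites,N})/(N_{obs,S}/N_{sites,S})$ with a Fisher exact test
on the 2x2 counts. No transition/transversion weighting is applied, and
numerical identity with the external calculator used on the real data is
not claimed.

# Modelling mutability

The feature matrix takes one row per site (all accepted SNMs plus random
non-mutated callable sites), drops rows with any missing feature, expands
categorical predictors into indicators, removes near-zero-variance columns
(fewer than 2 distinct values, or minority frequency below $10^{-4}$), and
is standardized — centered and scaled to unit SD — using *training-row
statistics only*, so held-out rows never leak into the fit.

The mutability model is penalized logistic regression with elastic-net
mixing $\alpha$ (default 0.5; the original mixing value is unpublished,
and 0.5 weights the ridge and lasso penalties equally, which suits the
strongly correlated context predictors). Each of 10 replicates draws
$10^5$ random non-mutated rows (or all available at reduced scale)
together with all mutated rows, holds out 25%, and selects the penalty
strength at minimum cross-validated deviance over 10 label-stratified
folds (fold stratification is a design choice here; the original fold
assignment is unstated). The minimum-deviance rule rather than the
1-SE rule is used because the goal is predictive ranking of correlated
predictors, not maximal sparsity. Coefficient medians and 95% intervals
come from the replicate ensemble. Class imbalance is left as-is for this
model, matching the original raw imbalanced training sets.

Calibration bins predicted mutability to one decimal, computes the
observed mutated fraction per bin, and fits a least-squares line weighted
by bin occupancy; slope and $r^2$ summarize agreement. Cross-dataset
prediction applies one dataset's scaling and coefficients to the shared
feature columns of another, reporting schema mismatches. The binary
C$\to$T classifier trains the same elastic-net machinery on SNM sites only
(site-GC features removed), with optional class balancing: down-sampling,
up-sampling, or SMOTE-style synthesis of minority rows by interpolating
towards nearest minority neighbours (implemented in-package); accuracy on
the held-out 25% is compared with the majority-class baseline by an exact
binomial test. The 6-class multinomial spectrum classifier is deliberately
omitted: it never exceeded chance on the real data, and only the binary
task is scientifically informative.

# Numerical and design choices

* Coordinates are 1-based closed everywhere inside the package (the
  Bioconductor convention of IRanges/Biostrings, which back the interval
  and sequence operations); VCF and GFF agree natively, and BED output
  converts to 0-based half-open on write.
* All randomness flows from explicit seeds; derived per-stage seeds stay
  below $2^{31}$. Rerunning any stage with the same configuration is
  byte-identical, and every output table carries a configuration hash and
  seed in a header comment.
* Degenerate inputs fail loudly: empty sequences, non-positive
  denominators, spectra not summing to 1 (tolerance $10^{-9}$), constant
  vectors for scale-parameter fits, single-class training labels.
* The callable-site denominator $N_c$ is exposed per variant class; the
  published large-deletion/inversion rates are consistent with a different
  denominator than the SNM analyses, and which one was used is not stated,
  so nothing is hard-wired.
* Problem sizes in the tests and scripts: the default synthetic scale is a
  2 Mb genome with 26 lines; property tests use 60 kb--2 Mb genomes,
  10,000-event spectrum checks, 100-seed type-I error checks at 100--200
  null iterations, and 1,000-replicate Poisson nulls. These sizes were
  chosen so the whole suite completes in a few minutes while keeping every
  statistical check comfortably powered.

# Known limitations

* The quality-noise model is per-site and parametric; correlated artifacts
  (mapping errors tracking repeat families, batch effects between lines)
  are not represented.
* The generator's INDEL length law and context-boost magnitudes are
  field-plausible defaults, not published quantities.
* AIC comparison across discrete and continuous families, and the
  two-sample KS on tied discrete window counts, are retained for
  faithfulness and documented rather than corrected.
* Ka/Ks is a counting estimator; codon-model maximum-likelihood methods
  would differ on real data.
* Coefficients and calibration $r^2$ on synthetic data characterize the
  method, not any real genome; real-data values depend on features of
  sequencing data the generator does not emulate.
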