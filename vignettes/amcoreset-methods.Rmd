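---
title: "Methods: comparative transcriptomics of the AM symbiosis core gene set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative transcriptomics of the AM symbiosis core gene set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amcoreset)
library(dplyr)
```

## The scientific problem

Arbuscular mycorrhizal symbiosis (AMS) is the ancient mutualism between
Glomeromycotina fungi and plant roots: the fungus forms arbuscules inside
cortical cells and trades mineral nutrients for plant sugars and lipids.
Host plants respond to colonization with a transcriptional program that is
partly conserved across flowering plants. `amcoreset` implements the
analysis chain used to identify that conserved program for a focal species
by comparative transcriptomics:

1. **Quantification** — read-level quality filtering and RPKM expression
   values from gene-level read counts.
2. **Differential expression** — an empirical-noise (NOISeq-style) caller
   that contrasts mycorrhizal against control roots without a parametric
   dispersion model.
3. **Conservation analysis** — per-species sets of regulated genes are
   compared through orthogroup membership; orthogroups regulated in
   several species define a cross-species "core set" of candidate
   symbiosis genes for the focal species.
4. **Promoter scanning** — presence of the mycorrhiza-associated
   MYCS/CTTC cis-element (exact or one mismatch) in promoter sequences.
5. **Validation quantities** — Trouvelot mycorrhization parameters from
   root-fragment class scores, qPCR relative expression, and two-group
   t-tests.

Every stage operates on plain tibbles and composes with the pipe; the
synthetic-data module generates all inputs with planted ground truth, so
the full pipeline is exercisable without any external download.

## Expression quantification

Reads are filtered before alignment-level counting: a read is discarded
when more than 50% of its bases have Phred quality ≤ 5, or when more than
10% of its bases are unknown (`N`). The fraction comparisons are strict
(`>`) and the quality comparison inclusive (`≤`), so a 10-base read with
exactly five bases at Q5 is kept. Qualities are fixed to Phred+33; no
offset guessing is attempted.

Expression is normalized as RPKM — reads per kilobase of gene model per
million uniquely aligned reads:

$$\mathrm{RPKM}(g, s) = \frac{10^9 \, C_{gs}}{N_s \, L_g}$$

with $C_{gs}$ the reads uniquely aligned to gene $g$ in sample $s$, $N_s$
the column total, and $L_g$ the gene model length in bases. Note that the
name of the method fixes the direction of the length correction: longer
genes collect more reads at equal molar abundance, so RPKM *divides* by
length. Formulations that multiply by $L_g/10^3$ occasionally appear in
print; they invert the intended correction and are not implemented. The
useful internal identity — used as a test invariant — is that the
length-kb-weighted RPKM values of a sample sum to $10^6$ (reads per
million).

A gene is **detected** when it has at least one read in every sample. By
default the differential caller runs on detected genes only
(`detected_only = TRUE` in `noiseq()`), since genes absent from entire
replicates carry no replicate-noise information; the flag exists because
placing the filter before or after calling is a reporting choice, not a
statistical one.

## The empirical-noise differential expression model

The caller follows the replicate-based empirical-noise design. For each
gene, the **signal** is the pair

$$M = \log_2 \frac{\bar{x}_1'}{\bar{x}_2'}, \qquad
  D = \lvert \bar{x}_1 - \bar{x}_2 \rvert,$$

where $\bar{x}_1, \bar{x}_2$ are mean RPKM over mycorrhizal and control
replicates. Zero means are replaced by $k = 0.5$ RPKM *inside the
log-ratio only* ($\bar x'$); $D$ keeps the unsubstituted means. The value
0.5 is the conventional pseudo-expression for this family of methods; it
only matters for genes expressed in exactly one condition, where any
$k \in (0, 1]$ preserves the ranking.

The **noise distribution** pools, over every gene and every unordered pair
of replicates within the same condition, the points
$(\lvert\log_2(a'/b')\rvert, \lvert a - b \rvert)$ — with a 3+3 replicate
design this gives $6G$ points for $G$ genes. Pooling across genes is the
defining trait of the method: the noise a gene is compared against comes
from the whole experiment, which makes the probability estimate stable at
three replicates but also means highly expressed genes dominate the upper
tail of the $d$ coordinate. Raw pooled points are used; no smoothing or
binning is applied (the alternative is undocumented in the method family's
common usage, and raw pooling keeps the estimator exactly reproducible).

The **probability** that a gene is differentially expressed is the
fraction of noise points its signal strictly dominates:

$$P = \frac{\#\{(m, d) : m < \lvert M \rvert \ \wedge\ d < D\}}{\#\text{noise}}.$$

Strict dominance with ties counting against the gene is deterministic and
conservative, and makes the brute-force double-loop oracle in the test
suite bit-exact. $P \ge 0.8$ is equivalent to odds
$P/(1-P) > 4$; `deg_odds(1)` returns `Inf`.

A gene is called a DEG when $\lvert M \rvert \ge \log_2 2$ **and**
$P \ge 0.8$, both thresholds inclusive; the direction is `up` iff
$M > 0$. No multiple-testing correction is applied — the probability
threshold *is* the decision rule in this framework.

Relabeling the two conditions flips the sign of every $M$ and swaps the
up/down sets exactly; this symmetry is a property test.

## Orthogroup conservation analysis

Orthogroups — sets of genes descended from a single ancestral gene, as
produced by orthogroup-inference tools in their tab-separated one-row-per-
orthogroup format — are the unit of cross-species comparison. Each gene
belongs to at most one orthogroup; parsing enforces this and never lets a
partially valid table escape.

An orthogroup is *regulated in species s* (per direction) when it contains
at least one DEG of $s$. The analysis then derives:

* **Venn partition** — each regulated orthogroup is assigned to the exact
  subset of species supporting it; all $2^S - 1$ regions are enumerated,
  and cumulative "supported by ≥ n species" queries are exposed.
* **Core set** — focal-species DEGs whose orthogroup is regulated in at
  least 2 other species (i.e. ≥ 3 of 5 species overall). Same-direction
  support is the default. For down-regulated genes the choice matters:
  commonly down-regulated orthogroups are rare, and a down-regulated focal
  gene may sit in an orthogroup that other species *up*-regulate. Both
  rules are implemented (`same_direction = FALSE` counts any-direction
  support); neither is asserted as uniquely correct.
* **Conserved-but-not-focal** — orthogroups regulated in ≥ 3 non-focal
  species with no focal DEG of that direction: candidate symbiosis genes
  the focal species either lacks or regulates below threshold.
* **Classification** — every focal DEG lands in exactly one of
  `no_ortholog` (no orthogroup, or an orthogroup without other-species
  genes), `ortholog_not_regulated`, `shared_1`, `shared_ge2`; the
  categories partition the DEG set, so nothing is silently dropped.
* **Curated cross-reference** — entries of a curated gene list (e.g.
  functionally characterized AMS genes, or genes phylogenomically
  conserved in AM hosts) are resolved through their orthogroup to the
  species supporting them, flagging entries outside all orthogroups.

All output tables are sorted by orthogroup then gene id for reproducible
diffs.

## Promoter cis-element scanning

The scanner reports every window, on both strands by default, whose
Hamming distance to the motif is at most `max_mismatch` (default 1,
matching the "exact or single-nucleotide mismatch" criterion used for the
MYCS/CTTC element). Coordinates are 1-based on the forward strand; a
minus-strand match is reported at the leftmost forward-strand base of its
window. `N` never matches anything — a deterministic, conservative rule.
The consensus shipped as default, `CTTCTTGTTC`, is the CTTC element from
the mycorrhizal phosphate-transporter promoter literature; the scanner is
motif-agnostic and the motif is an explicit configuration value because
consensus variants circulate.

## Phenotype quantification

Mycorrhization is scored per ~1 cm root fragment: a colonization class
0–5 (trace to >90% of the fragment) and an arbuscule class A0–A3. With
$n_i$ fragments in class $i$, $N$ fragments total and $N_{myc}$ with class
≥ 1, the Trouvelot parameters are

$$F = 100\,\frac{N_{myc}}{N},\qquad
  M = \frac{95 n_5 + 70 n_4 + 30 n_3 + 5 n_2 + n_1}{N},\qquad
  m = M \frac{N}{N_{myc}},$$

$$mA_j = \frac{\sum_{\text{myc frags in } A_j} w}{N_{myc}}\cdot\frac{100}{m},
  \qquad a = \frac{100\,mA_3 + 50\,mA_2 + 10\,mA_1}{100},\qquad
  A = a\,\frac{M}{100}.$$

The class weights 95/70/30/5/1 and arbuscule weights 100/50/10 are the
canonical values of this scoring system and are exposed in the
configuration. Under this convention $m$ is the intensity restricted to
mycorrhizal fragments and $M$ the intensity over the whole root system,
hence $m \ge M$ whenever $0 < F < 100$ and $A \le a$ always; these bounds
are property-tested over hundreds of random fragment tables along with
permutation and duplication invariance. The degrading-arbuscule variant applies the same
$a$/$A$ formulas to a re-scored degrading-arbuscule class column. Scoring
fewer than 30 fragments per root warns (the recommended minimum) but does
not error.

qPCR relative expression assumes perfect doubling per cycle (efficiency
2, no standard-curve correction): abundance $2^{-\Delta C_t}$ against the
reference gene, fold change $2^{-\Delta\Delta C_t}$ against the calibrator
group's mean $\Delta C_t$. Group comparisons default to Student's
pooled-variance t-test (Welch available), reported unadjusted.

## What the synthetic data emulate — and what they do not

The generators (`gen_orthogroup_universe()`, `gen_regulation()`,
`gen_counts()`, `gen_promoters()`, `gen_fragment_table()`) are
seed-deterministic and return their planted truth, so every analysis stage
has a recovery test in the noise-free limit.

`gen_counts()` draws negative-binomial counts (Poisson at dispersion 0)
with gene-wise control means log-uniform on [100, 1000] by default and a
3+3 replicate design, the standard bulk RNA-seq noise model at moderate
sequencing depth. All synthetic genes are 1 kb long: equal lengths keep
RPKM proportional to counts, so planted fold changes remain interpretable
after normalization. The test suite exercises the caller on 2000 genes
with 200 planted 4-fold effects at dispersion 0.05 — at these settings
the caller recovers planted genes at ≥ 0.9 recall with ≤ 0.1 false calls
on null genes. Two real-data features are *not* emulated: library-size
differences between samples (planting many strong effects shifts totals
and biases $M$ compositionally — visible in the generator tests when 10%
of genes are planted) and correlated genes; passing tests therefore
demonstrate correctness of the estimator, not robustness to compositional
or batch artifacts.

`build_paper_fixture()` is different in kind: a fully deterministic
(RNG-free) five-species universe constructed so that the conservation
stage reproduces, exactly, the published summary counts of the study this
pipeline models — 245 up / 37 down focal DEGs, 28 orthogroups
up-regulated in all five species, 106 in at least four, 186 focal up
genes shared with ≥ 1 species (143 orthogroups), a 153-gene up core set,
181 conserved-but-not-focal orthogroups, and 84 of 138 curated entries
with focal up-regulation. Only those published counts are encoded; every
other degree of freedom (full per-region Venn values, non-focal DEG set
sizes) is an arbitrary deterministic choice and must not be read as an
empirical claim. Two published breakdowns are mutually inconsistent at
the ±1 level (the no-ortholog / not-regulated / shared partition sums to
246, not 245, for the up set); the fixture resolves this in favour of the
explicitly pinned counts (33 orphans, 186 shared) and absorbs the
difference in the unpinned category (26 not-regulated). The three
down-regulated core genes are realized through any-direction support
(`same_direction = FALSE`), consistent with only one orthogroup being
commonly down-regulated. A fixture self-check re-derives every pinned
count at construction time and errors on any mismatch.

## Numerical and design choices

* Probability computation is an exact dominance count (chunked outer
  comparisons, no approximation); it agrees with a double-loop oracle up
  to 10^4 noise points in the tests.
* Ties in the dominance count go against the gene; thresholds are
  inclusive; zeros are substituted only inside log-ratios.
* Venn patterns use the declared species order; empty regions are listed
  with zero counts rather than omitted.
* Orthogroup files accept exactly one dialect (header starting with
  `Orthogroup`, one column per species, comma-separated gene lists) — no
  auto-detection, so parsing is bit-exact.
* The pipeline runner validates its manifest before any computation
  (fail-fast), writes deterministic TSV outputs, and records thresholds
  and the seed in `summary.json`.
* Problem sizes in the test suite (up to 200 random universes of up to
  10^4 orthogroups for oracle equivalence, dominance oracles at 10^4
  noise points, 2000-gene count simulations, property sweeps of one to
  two hundred cases each) were chosen as the smallest sizes at which the
  asserted properties are statistically meaningful.

## Known limitations

* Alignment, orthogroup inference, and transcript-level quantification
  are out of scope; the pipeline consumes counts and orthogroup tables.
* The empirical-noise probability is not a p-value; it is not calibrated
  for multiple testing and should not be combined with FDR machinery.
* Cross-species comparisons depend entirely on the orthogroup table's
  quality; paralog-rich orthogroups can register "support" from a gene
  whose regulation is unrelated to symbiosis.
* The motif scanner is consensus-based (Hamming distance); it does not
  model position-specific preferences (no PWM), and motif presence is not
  evidence of function.
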