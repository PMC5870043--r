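---
title: "Dosage, cis/trans and compensation analysis of aneuploid transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage, cis/trans and compensation analysis of aneuploid transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Interspecific crosses in the *Brassica* A/C species complex produce
aneuploid lines in which a single chromosome of one subgenome is added to,
or substituted for, its homoeologous partner in the other: a monosomic
alien addition line carries one extra C chromosome on top of a euploid
A-genome diploid, and a substitution line carries one C chromosome in
place of one member of an A-chromosome pair. Bulk RNA-seq of such lines
against the euploid progenitor answers three questions:

1. **Which chromosome changed dosage?** A monosomic chromosome shows a
   genome-wide halving of transcript output, visible as a ~1-unit downward
   shift in per-gene log2 expression ratios along that chromosome.
2. **Where are the expression changes?** Differentially expressed genes
   (DEGs) on copy-number-altered chromosomes are *cis* effects (dosage
   acting directly); DEGs on the unchanged, disomic chromosomes are
   *trans* effects (regulatory ripples through the rest of the genome).
3. **Are one-dose genes buffered?** For each gene on the monosomic
   chromosome, is its expression consistent with a strict halving
   (non-compensated), significantly above it (compensated), or
   significantly below it (anti-compensated)?

`aneuploidr` implements this pipeline from a gene-level count matrix
onward, plus a negative-binomial simulator that generates data with known
karyotype, trans-effect and compensation ground truth, so every stage can
be validated against a truth table rather than eyeballed.

## Quantification and normalization

Counts are converted to FPKM with the per-sample column total as the
library size:

$$\mathrm{FPKM}_{gs} = \frac{c_{gs} \cdot 10^9}{L_g \, N_s},
\qquad N_s = \sum_g c_{gs},$$

where $L_g$ is the gene's exonic length in bp. Using the column sum makes
the transform exactly invertible (a property the test suite asserts), and
keeps the package self-contained — it never sees alignment-level mapped
totals.

Total-count normalization has a well-known failure mode: expression is
compositional, so a large change on a high-abundance transcript rescales
every other gene's FPKM in that sample. In a leaf transcriptome the top
transcripts hold a substantial share of the library, and in a simulated
genome of a few thousand genes the effect is stronger still — we observed
entire null comparisons shifted by more than a unit of log2 when a
dominant gene carried a planted fourfold effect. `normalize_fpkm()`
therefore applies the standard median-of-ratios correction: each sample is
rescaled by the median ratio of its values to a per-gene geometric-mean
reference, computed over genes positive in all samples, with factors
standardized to geometric mean 1. `run_pipeline()` applies it once,
genome-wide, right after `compute_fpkm()`. It should never be applied to a
small or mostly-perturbed subset of genes (for instance only the monosomic
chromosome), where the median ratio would absorb the very signal under
test.

## Dosage scanning

For each chromosome, `scan_dosage()` takes genes with positive mean FPKM
in both groups, computes per-gene $\log_2(\bar{x}_{test}/\bar{x}_{ref})$,
and calls the copy number $c \in \{1,2,3\}$ whose center $\log_2(c/2)$ is
nearest to the median ratio. This is deliberately parameter-free: the
quantity being formalized is "the box plot for this chromosome sits a unit
lower", and the nearest-center rule is its minimal decision version. A
Wilcoxon signed-rank p-value of the ratios against zero is reported as
supporting evidence but plays no role in the call — with hundreds of genes
per chromosome it is essentially always tiny for any real shift, so it
cannot discriminate copy numbers.

Genes expressed in only one group are excluded from ratios (the log is
undefined) but counted. An alien chromosome absent from the reference —
the C chromosome in an A-genome euploid — yields no usable ratios at all;
it is reported descriptively (`n_test_only`, mean test FPKM) with
`no_call`, never forced into a copy-number call. `min_genes` (default 10)
guards against calling chromosomes from a handful of genes.

## DEG calling

A gene is tested if its mean FPKM is positive in at least one group. The
reported effect is `log2((mean_test + 1)/(mean_ref + 1))` on group means;
the pseudocount bounds the fold changes of near-zero genes. A gene is a
DEG when $|\mathrm{log2fc}| \ge 1$ and BH $q < 0.05$ (both thresholds are
arguments).

The per-gene p-value is the one place where the test choice matters. A
per-gene Welch t on three replicates has ~2–4 degrees of freedom; its
critical value at $q$-level significance is so large that even genuine
fourfold changes are detected in barely half of cases — we verified this
both by noncentral-t computation and by simulation, and no choice of
threshold repairs it because the problem is the variance estimate, not the
effect. The default (`method = "moderated"`) therefore moderates the
per-gene variance across genes with an intensity-dependent prior (limma,
`trend = TRUE`) on log2(FPKM + 1) replicate values, which is the standard
remedy for three-replicate designs. The plain per-gene Welch t remains
available as `method = "welch"`, and the decision rule (twofold + BH
$q < 0.05$) is identical under both.

`summarize_comparison()` reports DEG counts, up/down percentages to two
decimals, and the directional bias test: a two-category equal-proportion
chi-square on (n_up, n_down), **without** continuity correction. The
uncorrected statistic is the one whose p-values reproduce the published
bias tests this package's acceptance checks recompute (e.g. counts
1561/1770 give $p = 2.93\times10^{-4}$); the Yates-corrected variant does
not. p-values are kept in full double precision; no reporting floor such
as $2.2\times10^{-16}$ is ever imposed internally.

## Cis/trans partitioning

`altered_chromosomes()` compares two karyotypes (named copy-number
vectors over a shared chromosome universe) and returns the chromosomes
whose copy number differs — for a substitution line versus the euploid
this is both the lost A chromosome and the gained C chromosome.
`partition_degs()` then labels each located DEG *cis* if its gene lies on
an altered chromosome (including the alien chromosome's own genes) and
*trans* otherwise; it reports the trans percentage, the directional bias
chi-square on the trans set, and the count of dosage-opposing genes
(up-regulated DEGs on a reduced chromosome). "Disomic" always means copy
number 2 in both karyotypes being compared. No positional clustering test
along chromosomes is attempted.

`chromosome_susceptibility()` asks whether trans effects spread evenly:
per disomic chromosome, a 2×2 chi-square (uncorrected) of
(DEG, non-DEG) × (this chromosome, all other disomic chromosomes), BH
corrected across chromosomes. The uncorrected test was chosen to match the
package's other chi-square statistics; with per-chromosome counts in the
hundreds the correction is immaterial.

`overlap_degs()` computes Venn-region counts for two or three DEG lists.
Each gene belongs to exactly one region — the set of lists containing it —
so region counts always sum to the union size, an invariant the tests
assert for arbitrary inputs. With `direction_aware = TRUE` each region is
split into `up`/`down` (same direction in every containing list) and
`mixed`, so "shared and consistently down-regulated" is a single row of
the output rather than a different partition.

## Compensation classification

For genes on the monosomic chromosome the null hypothesis is *expression
in the test line equals half the reference expression*. It is expressed
exactly by halving the reference replicates: a two-sample test between
$\log_2(x_{test}+1)$ and $\log_2(x_{ref}/2+1)$. Not rejected at `alpha`
(default 0.05, raw — classification is per-gene, not FDR-controlled):
`non_compensated`. Rejected above the halved expectation: `compensated`;
below: `anti_compensated`. Genes with reference mean FPKM ≤ 0.1 — the
floor of the lowest expression bin — are `non_expressed` and not tested;
this threshold is a package convention, chosen so that the class partition
and the bin partition share an edge. As in DEG calling, the default
variance is moderated across genes (`method = "moderated"`), with the
per-gene Welch form (`classify_one_dose_gene()`, `method = "welch"`)
retained; when both sides have zero variance the gene is classified by the
sign of the difference and flagged `degenerate`.

Reference-expression bins are right-closed: 0 is `non_expressed`,
(0, 0.1] `sub_threshold`, (0.1, 10] `low`, (10, 100] `medium`, (100, ∞)
`high`. The strict-inequality convention common in publication tables
leaves the edge values 0.1, 10, 100 unassigned; closing intervals on the
right makes binning a total function, and the `sub_threshold` bin gives
the (0, 0.1] range — expressed but below the lowest bin floor — an
explicit home instead of silently dropping it.

`compensation_crosstab()` tabulates classes by bin with row percentages
and a per-row equal-proportion chi-square of
(compensated + anti_compensated) versus non_compensated, plus the overall
class proportions including `non_expressed`.

## The simulator

`simulate_experiment()` draws counts from a negative binomial
parameterized by mean and dispersion, $\mathrm{Var} = \mu + \phi\mu^2$
(default $\phi = 0.05$, a typical biological-replicate dispersion for
inbred plant material; the single knob is deliberate). Expected counts are
$\mu_{gs} = N \cdot w_g / \sum_g w_g$ with
$w_g = b_g \cdot L_g^{kb} \cdot d_{g} \cdot 2^{\lambda_g} \cdot k_g$:

* $b_g$ — baseline expression, log-normal with log2 mean 2.5 and sd 2.2.
  These values reproduce roughly the low/medium/high expressed-gene
  proportions seen in leaf transcriptomes (~62/34/4%). Note that $b_g$ is
  a *relative* abundance: realized FPKM in a simulated genome of a few
  thousand genes is inflated by a common factor relative to a full
  transcriptome, because FPKM of every gene depends on the whole genome's
  composition. Between-group comparisons are unaffected.
* $L_g$ — exonic length, log-uniform in [300, 10000] bp, which exercises
  the length normalization across its realistic range.
* $d_g$ — the dosage factor, copies/2 from the group's karyotype
  (an absent chromosome gives 0), with optional per-chromosome overrides.
* $\lambda_g$ — trans-effect log2 fold change for a configurable fraction
  of eligible genes, drawn from $N(0, 1.5)$ truncated to $|\lambda| \ge 1$
  (symmetric, so no directional bias is built in). Eligible genes lie on
  chromosomes disomic in both the group and the reference *and* have
  baseline FPKM ≥ 2: with a pseudocount of 1 and a twofold decision gate,
  a twofold reduction of a gene below ~2 FPKM cannot pass the gate even in
  expectation, so planting "truth" there would create ground truth that no
  decision rule could measure.
* $k_g$ — the compensation factor on monosomic chromosomes. Every gene on
  a one-copy chromosome receives a class from `compensation_mix` (default
  0.64/0.08/0.28 for non-compensated/compensated/anti-compensated, the
  relative class frequencies reported for expressed one-dose genes in the
  substitution line this design emulates). `non_compensated` keeps the
  pure dosage factor 0.5; `compensated` draws uniformly in (0.5, 1];
  `anti_compensated` uniformly in [0.05, 0.5). Uniform draws rather than
  point values exercise the classifier's rejection boundary, where calls
  are genuinely undecidable.

Per-sample expected totals equal `library_size` (default $10^7$ fragments,
a typical mapped yield) exactly; realized totals vary by NB sampling,
which for a heavy-tailed baseline law is dominated by the brightest genes.
One master seed drives everything, with per-stage substreams derived
deterministically from it, so a fixed seed reproduces the experiment bit
for bit while changes to one stage leave the others' draws intact.

The default group set mirrors the three-line study design: a euploid
A-genome reference (all 10 A chromosomes at 2 copies, 9 C chromosomes
absent), an addition line (+1 copy of C01), and a substitution line
(A01 at 1 copy, C01 at 1 copy).

**What the simulator does not emulate.** Reads, mapping and multireads
(counts are drawn directly); homoeologous cross-mapping between the A and
C subgenomes, which in real data inflates apparent expression of retained
homoeologs; correlated co-expression and batch effects; length- or
GC-dependent coverage bias; positional structure such as dysregulated
domains (trans effects are placed uniformly at random). Passing the
recovery tests therefore demonstrates that the statistics are implemented
correctly and have the intended operating characteristics under an
idealized NB model — not that real aneuploid data will be this clean.

## Numerical and testing choices

* The exact signed-rank null distribution is computed by a
  generating-function convolution over doubled midranks, so ties are
  handled exactly; up to $n = 25$ the exact path is used, above it a
  normal approximation with tie and continuity correction. The test suite
  checks the exact path against full $2^n$ enumeration and the
  approximation against the exact distribution at $n = 25$.
* BH q-values, Welch t and the chi-square distribution functions are
  delegated to base R; the suite cross-checks them against direct step-up
  evaluation, the hand Welch–Satterthwaite formula, and the closed form
  $p = 2\Phi(-\sqrt{\chi^2})$ at one degree of freedom.
* Problem sizes in the validation suite — 200 genes per chromosome over
  20 seeds for karyotype recovery, ~1000 genes with ~100 planted fourfold
  trans effects for recall/FDR, 500 genes per chromosome for compensation
  recovery — are large enough that the pass thresholds (95% karyotype
  recovery, 0.9 recall with FDR ≤ 0.1, 80% class recovery with ≤ 10%
  false rejection) sit well inside the observed margins, while keeping the
  whole suite under a minute.

## Limitations

The moderated test assumes the log-scale mean–variance relationship is
smooth across genes; strongly bimodal dispersion would weaken it. The
dosage scan assumes most of a chromosome's genes follow dosage — a
chromosome on which compensation were nearly universal would, by design,
not be called reduced (its transcriptional output genuinely is not
reduced). Compensation classes are per-gene hypothesis tests at raw
`alpha`; class *proportions* therefore inherit the usual
multiple-testing caveats and should be compared between conditions, not
read as absolute rates. FPKM-unit thresholds (the 0.1 non-expressed floor,
the bin edges) are conventions inherited from the literature and should be
revisited for libraries much deeper or shallower than ~10M fragments.
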