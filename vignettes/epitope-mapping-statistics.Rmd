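---
title: "Statistical epitope mapping from peptide-microarray substitution data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical epitope mapping from peptide-microarray substitution data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

High-density peptide microarrays can tile a protein antigen as overlapping
L-mer windows (typically L = 15, step 1) and additionally display every
single-amino-acid substitution of every window. After incubation with an
antibody sample and a fluorescent secondary, the signal of each substituted
peptide relative to its native parent reveals which residues the antibody
requires: substitutions at contact residues abolish binding, substitutions
elsewhere leave it unchanged. episcan turns such an intensity table plus the
antigen FASTA into (i) per-peptide epitope calls, (ii) per-residue selectivity
profiles rendered as signed sequence-logo scores, and (iii) gap-tolerant
epitope regions — without manual inspection of hundreds of thousands of spots.

## Substitution values

For every native window the replicate spot intensities are summarised by
their median (midpoint of the central pair for an even count). Each
substitution derivative is rescaled by that reference:

$$x = \frac{I_{\text{variant}}}{\max(I_{\text{native median}},\ \text{floor})}$$

so that 1 means no effect, values below 1 signal loss, and values above 1 a
heteroclitic gain. The floor (default 1 Au) guards against ratios on
near-zero references; it is an *absolute* quantity and deliberately not
scale-free, whereas everything downstream of the ratios is. Ratios are
canonicalized to 7 significant digits when they are formed. Fluorescence
intensities carry at most 4–5 physically meaningful digits, and the
canonicalization makes every downstream statistic invariant *at the bit
level* to the unit in which intensities are recorded: `fl(c·x)/fl(c·y)`
differs from `fl(x/y)` in the last IEEE bit for a substantial fraction of
inputs, so without a documented output precision no implementation could be
exactly scale invariant.

A bootstrap standard error of the native median (resampling the N replicate
copies, default 10,000 resamples) is available as a per-peptide
quality-control statistic. It does not enter any test: the calling procedure
below uses only the pooled within-column variance, and mixing the two
variance sources would change the meaning of its degrees of freedom.

## Per-peptide epitope calling

The substitution values of one native peptide form a position-specific
scoring matrix (PSSM): 19 replacing amino acids × L positions, the native
cell of each column structurally absent. With $\mu_i$ the column means, the
pooled variance is

$$S^2 = \frac{\sum_i \sum_j (x_{ij} - \mu_i)^2}{\sum_i n_i - L},
\qquad SE_i = \sqrt{S^2 / n_i},$$

and position $i$ is called part of the epitope when the mean relative signal
loss exceeds the least-significant difference,

$$1 - \mu_i > LSD_i = t_d \, SE_i,$$

a one-tailed rule: heteroclitic positions (means above 1) can never be
called. The critical value $t_d$ is the $1-\alpha$ quantile of the
one-tailed Dunnett max-t distribution with $m = L - 1$ comparisons,
$\nu = \sum_i n_i - L$ degrees of freedom, and correlation $\rho = 1/2$.
$\alpha$ defaults to $10^{-4}$, the conventional demonstration level for
this assay class; it is exposed as `--alpha`.

### The Dunnett engine

No suitable multivariate-t implementation is available to this package, so
the distribution is computed from first principles. Writing
$T_i = (\sqrt{\rho} Z_0 + \sqrt{1-\rho}\, E_i + \delta_i)/W$ with
$W = \sqrt{\chi^2_\nu / \nu}$,

$$P\!\left(\max_i T_i \le q\right) =
  \int_0^\infty f_W(w) \int_{-\infty}^{\infty} \varphi(z)
  \prod_{i=1}^m \Phi\!\left(\frac{q w - \delta_i + \sqrt{\rho}\,z}
  {\sqrt{1-\rho}}\right) dz\, dw,$$

evaluated by nested Gauss–Legendre quadrature: 128 nodes on $z \in [-8, 8]$
and 96 nodes on the chi scale truncated at tail mass $10^{-11}$ per side
(skipped entirely above $\nu = 10^5$, the known-variance limit). Measured
absolute accuracy against the Student-t reduction at $m = 1$ is below
$10^{-10}$, comfortably inside the $10^{-6}$ design target. Quantiles come
from Bonferroni-based bracketing plus `uniroot`. For $m = 1$ the closed-form
(noncentral) Student-t is used by default; the quadrature path stays
reachable via `method = "quadrature"` and is validated against both the
closed form and a seeded Monte-Carlo oracle that simulates the max-t
construction directly. The noncentral form is implemented for generality,
but the pipeline always tests against fixed nulls, so $\delta = 0$
throughout.

Two caveats on calibration, both verified by simulation during development:

* Classical Dunnett correlation $\rho = 1/2$ arises from a shared *estimated*
  control mean. Here the control is the known constant 1, which makes the
  position statistics nearly independent; using the $\rho = 1/2$ quantile is
  then very slightly anticonservative (the independent-case critical value is
  marginally larger). We keep $\rho = 1/2$ as the conventional choice for
  this procedure; the family-wise error in the i.i.d.-noise null world
  measures ≈ 0.05 at $\alpha = 0.05$, inside three binomial standard errors.
* The native reference is itself estimated from R replicate copies. Its
  noise shifts all substitution values of a peptide jointly, a variance
  component the pooled within-column $S^2$ cannot see. With R = 50 (the
  motivating full-scale design) this is negligible for small $\alpha$; with
  few copies and liberal $\alpha$ it inflates the family-wise error well
  beyond nominal. This is a limitation of the published LSD procedure
  itself, not of the implementation; `bootstrap_native_se()` exists
  precisely so users can screen unstable natives.

## Per-residue selectivity

One protein residue appears at up to L different frame positions of the
overlapping peptides. Its substitution matrix pools, over the peptides in
which that residue was called epitopic, the 19 substitution values per frame
plus the native column, which is filled with each included peptide's
replicate ratios (copy intensity / median, distributed around 1). Two
inclusion readings are implemented because the source description is
ambiguous: `"position"` (default) includes a frame only if the residue
itself was flagged in that peptide; `"peptide"` includes any peptide
carrying any flag. The default avoids diluting the matrix with frames
outside the binding register. For alanine-scan data, which has no
per-peptide calls (see below), all covering frames are included
(`"all"`).

With $\mu_i$ the per-amino-acid means, $\mu_g$ the grand mean over all
present cells (native column included), and $S^2$ the pooled within-column
variance with $\nu = N - K$ degrees of freedom ($K$ = columns with data),
each amino acid is tested against the global mean:

$$t_i = \frac{\mu_i - \mu_g}{SE_i}, \qquad
  SE_i = S\sqrt{\frac{(1 - n_i/N)^2}{n_i} + \frac{N - n_i}{N^2}}.$$

$SE_i$ is the exact standard error of the contrast $\mu_i - \mu_g$,
accounting for $\mu_i$ being part of $\mu_g$. This choice (rather than the
naive $S/\sqrt{n_i}$) is what makes the procedure *condense exactly* to a
pooled two-sample Student t-test when only two columns exist — the
alanine-scan degenerate case, which the package verifies to $10^{-9}$
against an independent t-test implementation. The p-value is the one-sided
upper Dunnett tail at $|t_i|$ with $m$ = number of replacing amino acids
with data; the direction is carried separately by the sign of $t_i$. A
residue is *selective* when any replacing amino acid has $p_i < \alpha$.

Logo scores are $raw_i = -\mathrm{sign}(t_i)\log_{10} p_i$ (p-values clamped
at $10^{-300}$), rescaled so that $\sum_i |s_i| = 1 - \mu_g$: the total
letter height of a logo column equals the mean relative signal change caused
by substituting that residue, positive letters mark amino acids with means
above $\mu_g$ (tolerated/favoured), negative ones below (disfavoured). When
every $p_i = 1$ the rescale is defined as all-zero.

Selective residues are merged into regions allowing internal gaps of at most
2 non-selective residues and keeping regions with at least 4 selective
residues; region strings print native letters at selective positions and
`'-'` in gaps. Both thresholds are exposed (`--min-region-length`,
`--max-gap`).

### Alanine-scan data

A single-substitution design leaves at most one value per PSSM column, so
$\sum n_i - L \le 0$: the per-peptide test has no degrees of freedom and the
sliding per-peptide table is not produced (the run log says so). The
residue-level analysis still works — with one replacing column it is the
two-sample t-test described above — so logos and regions are still emitted.

## The synthetic-data generator

`generate_dataset()` emulates the full-substitution array design: a random
20-letter protein, L-mer windows at step 1 (defaults L = 15), R replicate
native copies (default R = 5, a desk-scale stand-in for the 50-copy
full-scale design), and one copy of every substitution (or only alanine
substitutions in `alanine_only` mode). Planted epitopes multiply the
intensity of any variant substituting an epitope residue with a
non-tolerated amino acid by an effect factor (default 0.1, a strong
contact-residue knockout); peptides overlapping an epitope gain signal over
baseline (defaults 100 + 400 Au, matching the order of magnitude of
native-binding intensities in published tables, where epitope-bearing
natives sit near 500 Au and background near 50–100 Au); noise is
multiplicative log-normal with CV 0.1, a realistic spot-level variability
for fluorescence arrays. Tolerated-amino-acid sets model chemical-class
selectivity (e.g. a position accepting all non-polar residues) without
claiming class frequencies. Identical configurations and seeds give
byte-identical tables.

What a green synthetic test does **not** establish: the generator has no
spatial artefacts, no scanner saturation, no batch effects, no peptide
synthesis failures, and independent noise per spot — real arrays violate all
of these to some degree. Conclusions about statistical calibration transfer
only to the extent that spot noise is independent and roughly log-normal.

## Numerical and design choices

* Coordinates are 1-based and inclusive everywhere; frame positions run 1..L.
* Ambiguous mappings (a peptide equally consistent with more than one
  window) are excluded from statistics and counted in the run log; native
  assignment takes precedence over substitution assignment.
* Matching is exact over the 20-letter alphabet; masked (`X`) positions
  never match.
* Duplicate measurements of the same PSSM cell are averaged; the residue
  matrix keeps duplicates as independent values.
* Columns with no data are reported uncallable and never flagged.
* $\mu_g$ includes the native column, following the matrix-wide reading of
  the global mean.
* Degenerate variance (all values identical) yields $p = 1$ everywhere and a
  non-selective residue.
* The degrees of freedom for the residue test are $N - K$, the pooled
  within-column variance df. The alternative reading "total values minus
  number of replacing amino acids" fails to reproduce the t-test
  condensation by one degree of freedom; with the native column counted
  among the K groups, both readings coincide.
* `run_pipeline()` outputs are plain TSV, re-readable by the package's own
  readers; rerunning a configuration reproduces identical files.

## Limitations

* Unbalanced designs still use $\rho = 1/2$ as an approximation.
* Reference (native median) noise is invisible to the pooled variance; see
  the calibration caveat above.
* Inter-array normalisation, background subtraction and spot-level quality
  control are out of scope: the input table is taken as quantified.
* Region boundaries follow a fixed merge rule; biologically overlapping
  epitopes inside one region are not deconvolved.
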