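---
title: "Seed-gene correlation screens and candidate networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-gene correlation screens and candidate networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenet)
```

## The discovery procedure

`screenet` implements a three-stage in-silico procedure for nominating
upstream regulators of a gene of interest (the *seed* gene) from paired
expression compendia:

1. **Screen.** Within each dataset independently, every transcript is
   correlated (Pearson) to the seed transcript over pairwise-complete
   samples. A transcript passes when $|r| > \tau$ with a strict
   inequality; the default threshold is $\tau = 0.55$, a deliberately
   conservative operating point for compendia of tens-to-hundreds of cell
   lines, where such an $|r|$ corresponds to analytic p-values many orders
   of magnitude below conventional cutoffs.
2. **Intersect.** Candidates are the transcripts passing in *both*
   datasets. Because the two datasets are independent samples of the same
   underlying biology, a genuine co-regulation signal should replicate not
   only in magnitude but in *direction*: each candidate is flagged
   concordant when the sign of its correlation to the seed agrees across
   datasets. Discordant candidates are retained and flagged, never
   silently dropped — discordance is itself informative.
3. **Network.** Candidates become *focus* genes that nucleate networks
   grown over a user-supplied gene–gene interaction edge list. Growth is
   greedy and interconnectivity-driven, capped at 35 nodes per network,
   and each network is scored by a right-tailed Fisher's exact test on the
   enrichment of focus genes within it.

The per-dataset screen deliberately thresholds on $r$, not on adjusted
p-values: replication across two independent datasets is the error
control, which is why no multiple-testing correction is applied within a
dataset.

## Statistical details and assumptions

**Correlation and p-values.** For a transcript with $n$ complete pairs
against the seed, the analytic two-sided p-value uses the exact null
distribution of $t = r\sqrt{(n-2)/(1-r^2)}$, Student $t$ with $n-2$
degrees of freedom. This is the standard transform; it assumes
approximate bivariate normality of the (log-scale) intensities. A seeded
permutation alternative is provided
(`correlation_p_permutation()`, $p = (1 + \#\{|r_{perm}| \ge
|r_{obs}|\})/(1+B)$) for data where that assumption is doubtful; it is
never zero and is deterministic given its seed. Correlations over fewer
than `min_pairs` complete pairs (default 10) or against a zero-variance
vector are *undefined* rather than errors: real arrays contain flat
probes, and a screen should annotate them, not abort.

**Probe handling.** When the seed is given as a symbol, the annotated
probe with the highest variance is used (ties: lexicographically smallest
probe id). At symbol-level matching, a symbol passes in a dataset if any
of its probes passes, represented by its max-$|r|$ probe. Feature-level
matching (the default when both datasets share a platform) mirrors
probeset-level candidate tables. Symbols are uppercased at load and
matched exactly; alias resolution is out of scope because it cannot be
made deterministic without an external dictionary.

**Network growth.** Commercial pathway tools describe their algorithm
only as maximizing interconnectivity within size-capped networks. The
implementation here is a *documented greedy interpretation* of that one
sentence, chosen for determinism and auditability — exact reproduction of
any proprietary tool is explicitly not claimed:

* seed each network with the unassigned focus gene having the most
  evidence edges to other unassigned focus genes;
* repeatedly admit the gene adding the most edges to the current node set
  (unassigned focus genes preferred over connectors, then by edges added,
  then lexicographically), requiring at least one added edge;
* stop at `max_nodes` (default 35) or when no candidate qualifies;
* a focus gene belongs to exactly one network; connector genes may recur.

Every tie anywhere in the package breaks lexicographically, so runs are
bit-reproducible without seeds. `direct` and `indirect` evidence edges
count equally in growth and scoring; the distinction is preserved as an
edge attribute for display (solid vs dashed edges in the usual figure
style, with node colours carrying the correlation sign).

**Scoring.** Each network is scored by the right tail of the
hypergeometric distribution on the $2\times2$ table (focus membership
$\times$ network membership) over a declared background universe,
computed as a log-space sum of `dhyper` terms for stability; the score is
$-\log_{10} p$. The background defaults to the number of distinct genes
in the evidence file and is overridable — with a genome-scale background
the same network scores far higher, so scores are only comparable under a
fixed background. The contingency definition is an assumption of this
package (proprietary tools do not publish theirs).

## The synthetic generator

`synth_spec()` plants a single-latent-factor module: sample $s$ draws
$z_s \sim N(0,1)$, module gene $g$ takes
$x_{gs} = s_g \beta_g z_s + \varepsilon$, $\varepsilon \sim N(0,
\sigma^2)$, and background genes are iid $N(0,1)$. Two datasets are
independent draws sharing loadings, so the expected correlation between
module genes $g, h$ is

$$ r_{gh} = s_g s_h \frac{\beta_g \beta_h}
  {\sqrt{(\beta_g^2+\sigma^2)(\beta_h^2+\sigma^2)}}, $$

which lets tests dial the screen's operating point exactly. The defaults
are the study conditions the package is designed around: 166 and 76
samples (the sizes of the two public lung cancer cell-line compendia this
kind of screen is typically run on), a module of seed + hub + 20 members
among 5000 background genes, common loading $\beta = 2$ at $\sigma = 1$
(expected within-module $|r| = 0.8$), and five members negatively loaded
so the sign-concordance logic and signed display annotation are always
exercised. `simulate_evidence()` emits a star of `direct` edges from the
hub to every module gene plus Erdős–Rényi `indirect` background edges.

A single shared factor is the *minimal* structure producing the
phenomenon of interest — a transcript set correlated to the seed in two
independent datasets with full sign concordance and a hub-centred
interaction neighbourhood. What it does **not** emulate: probe effects,
batch structure, intensity-dependent variance, heavy tails, correlated
background blocks, or partially overlapping sample sets. Passing the
synthetic recovery tests therefore demonstrates the pipeline's logic and
calibration, not robustness to microarray artefacts; on real arrays the
usual normalization upstream of this package is assumed.

## Numerical and design choices

* Strict `>` at the threshold: boundary $|r| = \tau$ fails.
* Missing-value tokens `null`, `NA`, `NaN`, and empty (case-insensitive)
  — the permissive union of common expression-file dialects.
* Values are assumed log-scale; `log2_transform` applies $\log_2(x+1)$
  with a hard error on negatives. No autodetection.
* $r = \pm 1$ maps to the smallest positive double rather than $p = 0$.
* Fisher tails are exact (log-space sums), verified in tests against
  full-table enumeration to $10^{-12}$ for all margins $\le 30$ and
  against `stats::fisher.test(alternative = "greater")`.
* Candidate ranking defaults to `min_abs_r` — a candidate is only as
  strong as its weaker dataset; `mean_abs_r` is available.
* An empty candidate set has *undefined* concordance (reported `NA`,
  `concordance_report()` errors) — never a silent 1.0.
* The CLI (`inst/cli/screenet.R`) exposes `simulate`, `screen` and `run`;
  standalone `meta`/`network` subcommands are intentionally absent since
  candidates and networks always derive from in-memory screen results
  inside `run`, and the exported stage functions are the programmatic
  interface. Exit codes: 1 usage, 2 validation, 3 I/O.

## Problem sizes used by the test suite

Unit tests run on compact instances (5-member modules, tens of background
genes, 40–120 samples). The statistical acceptance tests use the design
scale the defaults mirror: 20 replicates of 5022 genes × 166/76 samples
for module recovery and hub identification, 500 replicates at $n = 50$,
$B = 200$ for permutation calibration, and exhaustive Fisher enumeration
for all margins $\le 30$. These sizes give the recovery assertions
comfortable statistical headroom (per-gene failure probability at the
default design is $\sim 2\times10^{-5}$) while keeping the suite fast.

## Limitations

* Greedy network growth is order-dependent by construction; it is
  deterministic, but not guaranteed to maximize any global
  interconnectivity objective.
* Scores depend on the declared background; compare networks only within
  a run.
* Feature-level intersection requires a shared platform; cross-platform
  runs must use symbol matching and inherit its collapse rule.
* The generator's single factor cannot express multiple overlapping
  modules or partial concordance scenarios beyond sign flips.
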