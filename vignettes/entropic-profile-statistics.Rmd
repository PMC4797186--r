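---
title: "Multi-resolution entropic-profile statistics: models, moments and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution entropic-profile statistics: models, moments and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroprof)
```

This vignette is the package's own account of the science it
implements: the statistics, the probabilistic model behind them, the
parameters that matter, the places where the design was genuinely
open, and what the validation suite does and does not establish.

## From counts to entropies

Alignment-free statistics summarise a sequence by its word content.
The classical family works at a fixed word length $k$: with $A_w$ and
$B_w$ the counts of word $w$ in sequences $A$ and $B$, and
$\tilde A_w = A_w - (l_A - k + 1)\,p^A_w$ the count centred by its
expectation under a background model,

$$D_2 = \sum_w A_w B_w, \qquad
D_2^S = \sum_{w}\frac{\tilde A_w \tilde B_w}
  {\sqrt{\tilde A_w^2+\tilde B_w^2}}, \qquad
D_2^* = \sum_{w}\frac{\tilde A_w \tilde B_w}
  {\sqrt{(l_A-k+1)p^A_w\,(l_B-k+1)p^B_w}}.$$

Their weakness for regulatory sequences is the fixed resolution: the
best $k$ tracks the (unknown, heterogeneous) binding-site length.

The *simple entropy* of a word $w$ of length $L$ replaces its count
with a weighted average over all of its suffixes,

$$SE_w = \frac{\sum_{k=1}^{L} a_k\, c_{w,k}}{\sum_{k=1}^{L} a_k},$$

where $c_{w,k}$ counts the length-$k$ suffix of $w$ and
$a_k = e^{-(L-k)^2/(2\sigma^2)}$ is a Gaussian kernel centred at the
maximum resolution. The pairwise statistics `ep2` and `ep2star` are
$D_2$ and $D_2^*$ with counts replaced by entropies; `ep2star` centres
each $SE_w$ by its exact expectation and divides by a pooled variance
term (below). A sequence's word universe is always the full $4^L$
(centred statistics receive non-zero contributions from absent
words); the practical limit is $L \le 10$.

## The background model and its stationarity assumption

Backgrounds are order-0 (Bernoulli) or order-1 Markov models with base
distribution $\mu$ and transition matrix $\pi$; order 0 is represented
with $\pi(a,b)=\mu(b)$ so both orders share one evaluation path.
Estimation uses letter and dinucleotide frequencies over non-N
positions with an additive pseudocount (default 1), which keeps every
word probability strictly positive — words of probability zero would
break the standardised statistics. The occurrence probability of a
word is the stationary chain product
$\mu(w) = \mu(w_1)\prod_j \pi(w_{j-1},w_j)$.

All moment formulas assume the chain is *stationary*: the occurrence
probability of a word must not depend on position. An arbitrary pair
$(\mu,\pi)$ is not stationary, and the exact-moment identities
genuinely fail for it (our enumeration tests demonstrate this). The
package follows the convention of using the empirical letter
distribution as the initial distribution rather than the left
eigenvector of $\pi$; for models estimated from sequences of a few
hundred bases or more the difference is far below the noise of the
counts. Where the test suite needs an *exactly* stationary order-1
model it constructs one with $\mu$ equal to the stationary vector of
$\pi$.

## Exact moments of variable-length word counts

Writing $Y_i(w)$ for the indicator that $w$ occurs at position $i$ of
a sequence of length $l$, the count $c_w=\sum_i Y_i(w)$ has
expectation $(l-k+1)\mu(w)$, and

$$\mathrm{Var}[SE_w] =
\frac{\sum_{k'}\sum_{k''} a_{k'}a_{k''}\,
  \mathrm{Cov}[c_{w,k'},c_{w,k''}]}{(\sum_k a_k)^2}.$$

Because occurrences overlap, the covariances are not Poisson-like.
Two cases arise.

**Variance of one count.** Three groups of index pairs: identical
positions (Bernoulli variance), overlapping shifts $1 \le d < k$
(driven by the word's autocorrelation: the shift-$d$ term fires only
when the length-$(k-d)$ suffix equals the prefix, with the conditional
extension probability), and gapped placements $d \ge k$, where the
joint probability involves $\pi^t$, the $t$-step transition between
the word's last and first letter.

**Covariance of a word and its suffix** ($w''$ the length-$k''$ suffix
of $w'$, $k''<k'$). The decomposition runs over the shift $d$ of
$w''$ relative to $w'$: zero shift, right shifts (overlapping for
$d<k'$, gapped beyond), left shifts (overlapping for $d<k''$, gapped
beyond). Each term is the exact joint occurrence probability times
the exact number of position pairs at which both indicators can fire:

* zero shift: $l-k'+1$ pairs — and the joint event additionally
  requires $w''$ to be a *prefix* of $w'$ (both words start at the
  same position; since $w''$ is a suffix, the configuration is
  otherwise impossible). This indicator is easy to miss: without it
  the covariance is systematically overestimated for words such as
  $w'=\mathrm{AC},\,w''=\mathrm{C}$;
* right shift $d$: $\min(l-k'+1,\; l-k''+1-d)$ pairs, with the
  aligned-placement indicator (is $w''$ the substring of $w'$ starting
  at offset $d+1$?) while $w''$ fits inside $w'$, and the
  suffix–prefix indicator with a conditional extension product once it
  hangs off the end;
* left shift $d$: $l-k'+1-d$ pairs, suffix($w''$)–prefix($w'$)
  indicator and the extension of $w'$ beyond the overlap;
* gapped terms on both sides: $\pi^t$ factors, $t \ge 1$.

Every branch was validated against an exhaustive enumeration oracle:
probability-weighted moments over *all* $4^l$ sequences for
$l = 3,\dots,6$, all words up to length 3 and all suffix pairs, under
uniform and skewed order-0 models and a stationary order-1 model,
agreeing to $10^{-10}$. Monte-Carlo checks at $l=50$ (50 000
replicates) confirm the variance of $SE_w$ for self-overlapping
(`AAAA`, `ATAT`) and non-overlapping (`ACGT`) words.

**Neglected terms.** For scoring, the gapped ($\pi^t$) sums are
dropped (`include_nonoverlap = FALSE`), treating occurrences separated
by a gap as independent. Under order-0 models this is *exact* (the
bracket $\pi^t(a,b)/\mu(b)-1$ vanishes identically). Under order-1
chains the dropped sums contribute at the same $O(l)$ order as the
variance itself, so their relative weight converges to a
chain-dependent constant rather than vanishing — about 10–30 % for a
strongly mixing artificial chain, but below 2 % for the weakly
correlated models actually estimated from DNA. The tests assert this
convergence rather than a (false) decay to zero. Because the dropped
terms can push a tiny assembled variance below zero in corner cases,
`entropy_variance` clips negative results to a floor of $10^{-12}$
with a warning.

## Conventions that the definitions leave open

* **The `ep2star` denominator.** The pooled variance term of the
  standardised entropy statistic is not fully determined by its
  definition. The default is the geometric mean
  $\sqrt{\mathrm{Var}_A[SE_w]\,\mathrm{Var}_B[SE_w]}$ with each
  variance exact under the respective sequence's own model, mirroring
  how $D_2^*$ pools the two sequences. A Poisson-style option divides
  by $\sqrt{E_A[SE_w]\,E_B[SE_w]}$ instead; with it, `ep2star` at
  $\sigma \to 0$ equals `d2star` at $k=L$ to machine precision (the
  tests check $\sigma=0.01$ at $10^{-6}$), which is the honest
  operationalisation of the claim that a vanishing kernel width
  collapses the multi-resolution statistic onto its fixed-resolution
  ancestor.
* **Centering and $D_2^*$ pooling.** Each sequence is centred with a
  model estimated from itself; the $D_2^*$ denominator is the
  geometric mean of the two per-sequence expected counts. For equal
  lengths and shared models this is the textbook $(n-k+1)p_w$;
  for unequal lengths it is the symmetric extension.
* **Reverse complements.** With `revcomp = TRUE` the word universe
  collapses to canonical classes (lexicographic minimum of $w$ and its
  reverse complement; palindromes are singletons). Per sequence, the
  class value is $\max(SE_w, SE_{\mathrm{rc}(w)})$ — only the
  strongest strand signal is kept — and the expectation and variance
  attached to the class are those of the chosen word (ties resolve to
  the canonical representative). This is one defensible choice among
  several (mean, min, both-strand counting are alternatives).
* **PPV pairing.** Positive pairs are all unordered pairs within the
  positive set, negative pairs all unordered pairs within the negative
  set; equal set sizes then give equal pair counts, as the protocol
  requires. Ties straddling the half-way cutoff are counted
  fractionally, which makes the protocol deterministic and gives the
  exact complement identity `ppv(pos, neg) + ppv(neg, pos) = 1`.

## The simulator: what it emulates, and what it does not

`build_experiment_sets` emulates the standard benchmark for
regulatory-sequence measures: a negative set of plain background
sequences and a positive set carrying implanted motifs. Backgrounds
are sampled from a Markov model or cut as windows from a user-supplied
FASTA pool (e.g. real intergenic sequence). The default synthetic
background is an AT-rich order-0 composition
$(\mu_A,\mu_C,\mu_G,\mu_T)=(0.3,0.2,0.2,0.3)$, a realistic intergenic
base composition. Implantation scans left to right and, at each
position, with the stated per-position insertion probability,
overwrites the next letters with a motif drawn uniformly from the
family, then jumps past it: implants never overlap, sequence length is
preserved, and every implant is logged. Reference descriptions of the
pattern-transfer scheme leave the per-sequence vs per-position reading
open; the per-position Bernoulli reading used here is recorded in the
output metadata, and the expected implant count obeys a simple
skip-process recursion that the tests verify by simulation. Positives
are derived from the *same* background draws as negatives (a paired
design) unless `paired = FALSE`, which is the right null when no
signal is implanted — with a paired design and insertion probability
0 the two sets are literally identical and the PPV is trivially 0.5.

The generator does **not** emulate: binding-site degeneracy (motifs
are implanted verbatim, no PWM sampling or mutation), compositional
heterogeneity along real genomes, repeats, or correlated motif
co-occurrence. Strong benchmark results on these fixtures therefore
show that a measure recovers shared exact motif content over a clean
background; performance on real enhancers can only be bounded, not
proven, this way. Notably, on a homogeneous synthetic background even
the unstandardised $D_2$ retains some power (mean PPV $\approx 0.65$
in the implanted-family benchmark) because nothing else perturbs the
counts; on real genomic backgrounds its power collapses — a gap worth
remembering when reading simulation tables.

## Parameters at a glance

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `L` / `k` | 4 | word length (resolution); 4 is the strongest all-round choice for enhancer-scale comparisons at `sigma = 0.7` |
| `sigma` | 0.7 | Gaussian kernel width (in units of word length); 0.7 favours the top two-three resolutions, matching the unknown spread of binding-site lengths |
| `phi` | 0.5 | geometric smoothing of the per-position profile (dimensionless) |
| `order` | 1 | background Markov order; order 1 discriminates better than order 0 on genomic backgrounds |
| `pseudocount` | 1 | additive smoothing; guarantees positive word probabilities |
| `revcomp` | TRUE (scoring) | strand-symmetric scoring via canonical classes |
| `include_nonoverlap` | FALSE | drop gapped covariance terms (exact for order 0; small stable correction for estimated order-1 models) |
| `variance` | "exact" | `ep2star` denominator convention; "poisson" recovers `d2star` as `sigma` vanishes |
| `var_floor` | 1e-12 | clip for negative assembled variances |

## Degenerate inputs and numerical notes

Words overlapping an N are excluded from every count, and N breaks
dinucleotide adjacency during estimation; all-N sequences are
rejected. A constant per-position profile has zero standard
deviation; its standardised values are defined as 0 and flagged.
`d2s` terms with both centred counts zero contribute 0. Matrix powers
$\pi^t$ use repeated squaring in the scalar API and an incremental
product in the vectorised moment tables (needed only when the gapped
terms are on). All whole-universe computations are vectorised over
integer word indices — suffix extraction, prefix extraction and every
overlap indicator reduce to modular arithmetic, and the trailing
transition products to ratios of precomputed word-probability tables
— so scoring 20 sequences of 4 kb at $L=5$ takes well under a second.

## Validation scale

The enumeration oracle runs at $l \le 6$ and word length $\le 3$
(exact, $10^{-10}$); Monte-Carlo variance checks use 50 000 replicates
at $l = 50$, $L = 4$, $\sigma \in \{0.5, 1.5\}$; the null-PPV check
uses 50 replicate experiments of 10 sequences of 500 bp; the
implanted-family benchmark uses the five-motif family
(`AGCCA`, `GCCA`, `TAGCCA`, `CCAG`, `AGCCAG`), 4 kb sequences,
insertion probability 0.008, $\sigma=0.6$, $L=5$, 10 sequences per
set and 5 replicates, where `ep2star` separates the sets almost
perfectly while `d2` stays below 0.65. These sizes were chosen so the
whole suite re-runs in about half a minute; none of the conclusions
changes at larger sizes.

## Known limitations

Markov orders above 1 are not implemented (the moment formulas extend,
the code does not); full-universe statistics are limited to
$L \le 10$; the moments of two *different* length-$L$ words (as
opposed to a word and its suffixes) are not provided; and the
reverse-complement treatment interacts with standardisation through
the argmax convention described above, which is a modelling choice,
not a derived result.
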