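---
title: "Methods: covering rough-set reduction and grey prospect-theory decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covering rough-set reduction and grey prospect-theory decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phedkit)
```

phedkit supports two stages of public-health emergency decision making that
are usually handled by separate tools: *knowledge acquisition* — reducing a
noisy, partially redundant decision table to the cheapest set of condition
attributes that still classifies events correctly, and extracting ordered
decision rules from it — and *scheme selection* — ranking candidate response
schemes whose evaluations are uncertain (intervals, linguistic judgements)
using cumulative prospect theory, optionally aggregated over several
departments. This vignette explains the models behind both stages, the
parameters that matter, and the choices made where the design was genuinely
open.

## Covering decision tables

A decision table is a universe $U$ of events, a family
$\Delta = \{C_1, \dots, C_n\}$ of *coverings* (one per condition attribute;
blocks may overlap, generalising partitions) and a decision partition
$U/D$. Raw attributes are turned into coverings by `granulate()`:

* symbolic attributes partition $U$ by equal values;
* numeric attributes use $\delta$-neighbourhood granulation: the block of
  $x$ is $\{y : |a(y) - a(x)| \le \delta \cdot \mathrm{range}(a)\}$, so
  $\delta \in (0, 1]$ sets the granule width as a fraction of the attribute
  range. Smaller $\delta$ gives finer blocks, more effective blocks, and
  typically larger positive regions; the useful range in practice is
  roughly 0.05–0.25 (default 0.15). A constant attribute degenerates to a
  single block covering $U$, carrying no information, and is handled
  explicitly.

For one covering, the neighbourhood $N(x)$ is the intersection of all
blocks containing $x$; the positive region collects the objects whose
neighbourhood lies inside a single decision class — the objects the
attribute classifies with certainty.

## The family method and reducts

A block is *effective* when it is a subset of one decision class. The
membership condition is the linchpin of the whole reduction: we define the
effective approximation set as exactly those (covering, block) pairs, which
makes every effective block the antecedent of a certain rule and reproduces
all intermediate sets of the six-object walkthrough shipped as
`worked_example_table()`.

For each object, the *related family* $r(x)$ is the set of coverings owning
an effective block that contains $x$; the deduplicated collection of the
$r(x)$ is the family of the table. A *reduct* is a minimal set of coverings
hitting every family member. `all_reducts()` computes all of them by
building the discernibility CNF (one clause per family member) and
expanding it to a minimal DNF by distribution with absorption — exact, and
cheap at the table sizes where enumerating every reduct is meaningful
(tens of attributes). Objects covered by no effective block make the table
locally inconsistent; they are reported in a diagnostics field rather than
silently dropped, and a table whose family is empty raises an error
instead of returning an empty reduct.

## A-DRE: cost-aware greedy reduction and rules

Exhaustive reduct enumeration is exponential, so the working algorithm
(`adre_reduce()`) transforms the family into a hypergraph — one vertex per
covering (carrying its acquisition cost), one hyperedge per family
member — and finds a cheap hitting set greedily. The selection criterion
had to be fixed here: we use the classical weighted set-cover rule, picking
the vertex that maximises (currently uncovered edges hit) / cost, ties
broken by input order. Greedy covers need not be minimal, so the cover is
then pruned, dropping members highest-cost-first while the remainder still
hits every edge; the output is therefore always a minimal hitting set,
which is what "reduct" means, and positive-region preservation against the
full attribute set is verified and reported on every run.

Rules are read off the reduct: one rule per effective block of each
retained covering, with

* support $= |B| / |U|$ — the fraction of all events the antecedent
  matches, and
* coverage $= |B| / |X_d|$ — the fraction of the rule's decision class it
  matches.

Rules are ranked by coverage, then support (both descending), then
covering cost (ascending), then a deterministic serialisation key. Coverage
leads the key because a rule that accounts for most of its class is the one
whose antecedent most strongly determines the consequent; ranking by it
first also keeps the ordering stable under subsampling of the majority
class. Classification is by the first matching rule in rank order — ordered
rules avoid conflicts between overlapping antecedents — with a
majority-class default for unmatched records. `evaluate_rules()` wraps the
pipeline in stratified, seeded k-fold cross-validation (default 5 folds);
held-out objects are matched through the originating full-table block of
each learned rule, which is how a covering-based rule generalises to an
object that was not in the training restriction.

## Grey cumulative prospect theory

Scheme selection values outcomes relative to a reference point, not in
absolute terms. Each scheme $\times$ criterion $\times$ time-frame entry is
a *grey value*: a scalar, an interval $[a, b]$, or linguistic terms
resolved through an ordered scale. The default scale is a seven-point
tiling of $[0, 1]$ (VP $[0, 0.1]$, P $[0.1, 0.25]$, MP $[0.25, 0.4]$,
M $[0.4, 0.55]$, MG $[0.55, 0.7]$, G $[0.7, 0.85]$, VG $[0.85, 1]$);
any ordered tiling can be substituted. A two-term entry such as
$[G, M]$ denotes a value known only to lie somewhere across both terms and
resolves to the spanning interval.

The pipeline per scheme and criterion:

1. **Editing.** The entry is compared with the per-criterion reference
   $R_j$ by interval subtraction; for cost criteria the sign is flipped so
   that falling below the reference counts as a gain.
2. **Valuation.** Deviations pass endpoint-wise through the value function
   $v(d) = d^\alpha$ for $d \ge 0$ and $v(d) = -\lambda(-d)^\beta$ for
   $d < 0$: concave over gains, convex over losses, and steeper for losses
   by the loss-aversion factor $\lambda$.
3. **Weighting.** Each state's probability is distorted by
   $\pi(p) = p^\gamma / [p^\gamma + (1-p)^\gamma]^{1/\gamma}$ with
   $\gamma = \chi$ on the gain branch and $\gamma = \delta$ on the loss
   branch; the branch of a state is chosen by the sign of its deviation
   midpoint. $\pi$ fixes 0 and 1, reduces to the identity at $\gamma = 1$,
   and is monotone only for $\gamma \gtrsim 0.28$, which is why the
   constructor restricts $\chi, \delta$ to $(0.28, 1]$.
4. **Aggregation.** The weighted values are summed over states into an
   interval prospect value $V_{ij}$; the cumulative prospect value of a
   scheme is $U_i = \sum_j \omega_j \cdot \mathrm{mid}(V_{ij})$, and
   schemes are ranked by $U_i$.

Parameter defaults are the canonical experimentally estimated values
$\alpha = \beta = 0.88$, $\lambda = 2.25$, $\chi = 0.61$,
$\delta = 0.69$; all five are exposed in `prospect_params()` and in the
YAML run configuration, because elicited decision-maker attitudes vary.

Several conventions had to be fixed where the underlying model family
leaves them open, and each is deliberately the simplest member of its
class: time frames without stated probabilities are treated as
equiprobable states; interval prospect values are collapsed to midpoints
only at the final weighting step (keeping interval arithmetic as long as
possible); scalar criteria are compared unscaled against their scalar
reference, with no cross-criterion normalisation, since the reference
vector is already expressed per criterion in the criterion's own units.
Under these conventions the shipped rescue case (`covid_case_matrix()`,
three schemes over four time frames) selects scheme x2 with a strictly
positive margin, and the full ranking is x2 > x3 > x1. The *absolute*
cumulative prospect values depend on every one of these conventions plus
the linguistic scale and the five parameters, so they are comparable only
between runs sharing a configuration; the ranking is much more robust, and
the test suite asserts ranking invariance under scheme relabelling and
weight rescaling, monotone decrease of $U$ in $\lambda$, and the
closed-form linear limit ($\alpha = \beta = \gamma = 1$, $\lambda = 1$,
scalar inputs), where $U$ reduces to the weighted mean deviation from the
reference.

## Multi-department aggregation

Departments submit interval prospect matrices on shared scheme/criterion
axes. The group consensus $V^*$ is the entry-wise endpoint mean — chosen
for idempotence: a unanimous group reproduces its shared matrix exactly.
Department $k$'s distance to consensus is
$d_k = \sum_{ij} (|V^{k,L}_{ij} - V^{*L}_{ij}| +
|V^{k,U}_{ij} - V^{*U}_{ij}|)/2$, and weights are inverse-distance,
$w_k \propto 1/(1 + d_k)$, normalised — bounded, monotone, and uniform
when everyone agrees. The comprehensive matrix $V^{**} = \sum_k w_k V^k$
is a convex combination, so every aggregated endpoint stays inside the
departments' envelope, and the selected scheme maximises the
criterion-weighted midpoint utility of $V^{**}$. Collaboration structure
between departments (synergy, communication cost) is not modelled; a
per-department multiplier hook lets a caller rescale influence when such
information exists externally.

## Synthetic data: what it emulates and what it does not

Real emergency-response decision tables of the kind this package targets
(tens of events by ~15 numeric attributes, a 3-level response decision)
are generally not public, so `synth_table()` generates structurally
matched stand-ins, and its defaults (81 objects, 15 coverings, 3 classes)
mirror that scale. The decision partition is drawn first; a planted subset
of "informative" coverings is built purely from within-class blocks, so
all their blocks are effective and the planted set hits every related
family; the remaining coverings are noise, built from blocks forced to
straddle classes, so they own no effective block and can never enter a
reduct. The `consistency` dial (default 1) merges that fraction of
informative blocks across class boundaries, eroding the planted
structure. Block sizes are drawn from `blocks_per` (default 2–5), a range
at which granulated numeric attributes typically land.

This construction gives an unambiguous ground truth for recovery tests
(at consistency 1, a reduct can only contain planted coverings), which is
its purpose — but it is idealised: real attributes are correlated, noise
attributes are partially rather than completely uninformative, and
class-conditional block structure is rarely exact. Passing recovery tests
therefore demonstrates correctness of the reduction machinery, not
expected accuracy on field data. `synth_evaluation()` similarly emulates
only the *shape* of a grey evaluation matrix (mixed scalar / interval /
linguistic entries, Dirichlet state probabilities), not any
epidemiological dynamics. Test and example problem sizes throughout (30–81
objects, up to 15 coverings, 100–200 replicates) are chosen so exhaustive
oracles remain feasible alongside the algorithms they check.

## Numerical and degenerate-input choices

* Block membership thresholds in numeric granulation include a `1e-12`
  slack so boundary objects are kept under floating-point representation
  of $\delta \cdot \mathrm{range}$.
* Probability vectors must sum to 1 within `1e-9`; criterion and
  department weights within `1e-8`.
* Greedy ties (equal hit/cost ratio) go to the earliest input index;
  serialisation orders are fixed (objects and coverings keep input order,
  sets are stored sorted) so every result, including JSON output, is
  byte-stable for a given input and seed.
* Equal cumulative prospect values are reported as a tie; the listed
  "selected" scheme is then just the serialisation-order representative.
* Zero-range numeric attributes, single-class decisions, empty reducts,
  unknown linguistic terms and non-covering block families all raise
  informative errors or documented degenerate results rather than
  propagating silently.

## Limitations

* Reduct enumeration is exponential in the number of coverings by nature;
  `all_reducts()` is intended for small attribute counts, with
  `adre_reduce()` as the scalable path.
* The greedy cover is an approximation; it achieves the optimum on the
  shipped worked example under both cost settings, and the suite checks it
  is never better than the exhaustive optimum, but no approximation ratio
  beyond the classical set-cover guarantee is claimed.
* Prospect rankings depend on elicited parameters, the linguistic scale
  and the reference vector; absolute utilities are not comparable across
  configurations.
* The group model aggregates fixed matrices; iterative consensus-reaching
  negotiation is out of scope.
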