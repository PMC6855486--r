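---
title: "Degree-polynomial complexity measures for directed graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-polynomial complexity measures for directed graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degpoly)
```

## The model

Most classical complexity descriptors target undirected graphs, yet the
networks that matter in systems biology, transport and manufacturing —
signalling cascades, metabolic routes, bills of material — are directed.
`degpoly` implements a family of descriptors built from nothing but the out-
and in-degree distributions of a simple digraph (no loops, no multi-edges).

For a digraph $G = (V, E)$, let $a_j^{out}$ be the number of vertices with
out-degree exactly $j$. These counts are the coefficients of the
*out-degree polynomial*

$$P_{G,out}(x) = a_k^{out} x^k + \dots + a_1^{out} x + a_0^{out},$$

with $k$ the maximum out-degree; $P_{G,in}$ is defined the same way from
in-degrees. Since every vertex falls in exactly one degree class,
$\sum_j a_j = |V|$, and counting edge endpoints gives
$\sum_j j\,a_j = |E|$ — both identities hold in each direction and are
asserted throughout the test suite.

$P_G$ has only non-negative coefficients, hence no positive zeros
(Descartes' rule of signs: no sign changes). The trick is to shift it: for
a real parameter $\alpha$ define

$$P^*_G(x) = \alpha - P_G(x).$$

When $a_0 < \alpha < \sum_j a_j$ the coefficient sequence of $P^*$ has
exactly one sign change, so $P^*$ has a unique positive zero $\delta$; and
because $P^*(0) = \alpha - a_0 > 0$ while $P^*(1) = \alpha - \sum_j a_j <
0$, that zero lies in $(0, 1)$. The pair
$(\delta_{out}(G), \delta_{in}(G))$ is the package's atomic complexity
quantity.

### Choosing $\alpha$

The admissible interval is open: $(a_0, \sum_j a_j)$ — for a graph-built
polynomial, $(a_0, |V|)$. Zeros of a polynomial vary continuously with its
coefficients, so nearby $\alpha$ give nearby $\delta$; a canonical choice
is what makes values comparable across graphs. The default policy
(`min_integer`) takes the smallest integer strictly inside the interval.
When the interval contains no integer at all — e.g. the out-star on 9
vertices, with interval $(8, 9)$ — the midpoint is used and the selection
is flagged `midpoint`. An `explicit` policy validates a user-supplied
value against the bounds. These rules reproduce every $\alpha$ used in the
package's worked examples, including the $\alpha = 8.5$ star case.

### The indices

From the two zeros the package derives

* $I_1 = \delta_{out}$, $I_2 = \delta_{in}$;
* $I_3 = (I_1 + I_2)/2$, the arithmetic mean;
* $I_4 = (\sqrt{I_1} + \sqrt{I_2})/2$, the mean of square roots;
* $I_5 = |\ln I_1| + |\ln I_2|$ (natural logarithm);
* $I_7 = |E| / (|V|^2 - |V|)$, the ordinary edge density.

The numbering deliberately skips $I_6$ to stay aligned with the
literature this family comes from. On $(0,1)$, $x \le \sqrt{x}$, so
$I_3 \le I_4$ always; $I_5$ is antitone in each zero, which is why its
correlations with $I_1$–$I_4$ come out negative on every generated class.
The definitions of $I_3$ and $I_4$ render ambiguously in parts of the
source literature; the forms above are the unique simple readings that
reproduce all four printed reference values for both the dense and the
path example (0.646131/0.803478 and 0.125/0.353553), which is how they
were fixed before the implementation was written.

```{r example}
ex <- example_polynomials()
measures_from_polynomials(ex$g1_out, ex$g1_in)
```

## Numerical choices

The zero is isolated with `stats::uniroot` (Brent's method) on $(0, 1)$:
the bracket is guaranteed by the sign conditions above, the method is
derivative-free, and uniqueness means any sign-change bracket converges to
*the* zero. The bracket tolerance is $10^{-12}$ with an iteration cap of
200; the returned object carries the residual $|P^*(\delta)|$ and the
iteration count. Coefficients are held as exact integers, so the
admissible interval and the integer candidate set involve no floating
point at all. User-facing printing rounds $\delta$ to 6 decimals; internal
values keep full precision. Linear and monomial polynomials admit closed
forms ($\delta = (\alpha - a_0)/a_1$ and
$((\alpha - a_0)/a_k)^{1/k}$) which the tests use as oracles against the
iterative path, together with a $10^6$-point grid-scan bracketing oracle
on random polynomials.

Degenerate inputs are rejected rather than patched: an edgeless direction
has a constant polynomial and no admissible $\alpha$ (error), explicit
$\alpha$ outside the open bounds is an error naming both bounds, and
`compare_zeros` reports `"equal"` only below an absolute tolerance of
$10^{-9}$.

## Zero-dominance comparisons

Two digraphs can be ordered by their zeros at a shared admissible
$\alpha$ (the intersection of the two open intervals). Two sufficient
criteria are implemented alongside direct solving:

* **Linear bound** (`linear_zero_bound`): when $P_G$ is linear its zero is
  $(\alpha - a_0^G)/a_1^G$ in closed form, and
  $\delta^\alpha(G) > \delta^\alpha(H)$ whenever $\alpha$ is strictly less
  than $P_H$'s polynomial part evaluated at that zero. The special case
  $a_0^H = a_0^G$, $a_1^H = a_1^G$ with some higher-order coefficient
  positive holds for *every* shared $\alpha$ (`linear_dominance_always`).
* **Coefficient dominance** (`coefficient_dominance`): if
  $a_i^G \le a_i^H$ for all $i$ with strict inequality for some
  $i \ge 1$, then $\alpha - P_G > \alpha - P_H$ pointwise on $(0,1)$ and
  the ordering follows for any shared $\alpha$. A looser published variant
  of this condition compares only the leading coefficient against the
  others; its own proof, however, uses the full coefficient-wise
  comparison, so the package implements the coefficient-wise form (sound,
  and satisfied by the shipped demo pair).

`compare_zeros` always solves both zeros directly and records whether
each applicable criterion's prediction matches the computed ordering —
the criteria are certificates, never a substitute for the computation.

The fixture set ships two variants of the 23-vertex hierarchical demo
polynomial: `hier23_out` ($x^8 + x^7 + 5x^5 + 10x + 6$), used by the
dominance walkthrough and consistent with its printed bound 14.920 and
zero 0.099995, and `hier23_out_alt` (the $5x^2$ form, consistent with an
edge count of 35). The two transcriptions circulate side by side in the
source material; the package commits to the one the printed numbers
require and keeps the other available rather than guessing an intent.

## Homogeneity of the zero set

How much does $\delta$ depend on the $\alpha$ convention? For each integer
candidate $\alpha^{(1)} < \dots < \alpha^{(k)}$, solving gives zeros
$\delta^{(1)} < \dots < \delta^{(k)}$ (strictly increasing, since $P$ is
strictly increasing on $(0,1)$). Their spread is summarised by

$$h(S) = \frac{1}{k(k-1)} \sum_{i=1}^{k} \sum_{j=1}^{k}
  \left|\delta^{(i)} - \delta^{(j)}\right|,$$

a double sum over *ordered* pairs (the $i = j$ terms vanish), i.e. twice
the unordered-pair sum under the $1/(k(k-1))$ normaliser — the mean
absolute difference over distinct ordered pairs. It is permutation
invariant, bounded by the zero range, and zero iff all zeros coincide;
$k = 1$ gives $h = 0$ by convention (a singleton is perfectly
homogeneous). For the directed path on 9 vertices the candidate zeros are
exactly $1/8, \dots, 7/8$ and $h = 1/3$ — the tests verify this against a
literal brute-force double sum. Small $h$ across a generated class is the
numerical face of the continuity theorem: changing $\alpha$ by $\pm 1$
perturbs only the constant coefficient of $P^*$.

## The random graph classes

Three generators emulate the study conditions the measures were designed
around; their defaults are the study conditions, not tuning knobs.

* **G1** — directed Erdős–Rényi: $n = 9$, edge count $m$ drawn uniformly
  from $[8, 36]$ (the stated bounds; the edge-count law itself is not
  specified in the source, and uniform is the simplest reading of
  "randomly selected"), then $m$ distinct ordered pairs uniformly at
  random ($G(n,m)$, directed). Weak connectivity is enforced by rejection.
* **G21** — 4-level hierarchical digraphs, $5 \le |V| \le 30$: $|V|$
  uniform, split into four non-empty levels by a uniform composition;
  every non-root vertex gets one mandatory upward edge (adjacent level
  with probability 0.7, otherwise a jump of at least two levels), then
  extra upward edges uniformly among the unused upward pairs. The total
  edge count is drawn uniformly between the mandatory count and
  $\lceil 1.5|V| \rceil$ (capped by the number of admissible upward
  pairs): the level-size and edge-count laws are not pinned down by the
  class definition, and the $1.5|V|$ ceiling matches the density of the
  class's printed 23-vertex, 35-edge example. All of these knobs are
  exposed in `class_spec` so users can vary them.
* **G22** — as G21 with $|V| = 20$ and $m$ uniform in $[8, 30]$
  (level compositions incompatible with the drawn $m$ are rejected and
  redrawn, so both constraints hold exactly).

A mandatory upward edge per non-root vertex does **not** by itself imply
weak connectivity (a second root-level vertex can remain untargeted), so
the hierarchical generator also rejection-samples to connectivity.
`sample_class` additionally filters to pairwise non-isomorphic samples,
as the study protocol demands: an incremental degree-class-count hash
bucket plus exact VF2 checks within a bucket — graphs here have at most
30 vertices, so exact isomorphism is cheap and the quadratic all-pairs
comparison is avoided.

What the generators deliberately do *not* emulate: real directed networks
have hubs, reciprocity and community structure that neither class
produces. Green tests say the measures behave as designed on these
reference ensembles, not that they summarise any particular biological
network well.

## Correlation analysis at desk scale

`correlate_class` generates a class, computes the measure table and the
Spearman rank correlation matrix (average ranks for ties — degeneracy
makes ties common, so the tie convention matters). The reference results
this reproduces were computed on 20,000 (ER) and 500 (hierarchical)
graphs; the package's default study size is 2,000 for the ER class and
200 for the hierarchical classes, which keeps a full run in seconds on
one core while leaving the rank correlations stable to well under a
percentage point. At that size the $I_3$–$I_4$ correlation lands within
$\pm 0.01$ of the reference 0.9989, and the sign pattern (all $I_1$–$I_4$
pairs positive, every $I_5$ entry negative) reproduces; entries that
depend on fine generator details that the class definitions leave open
(especially those involving $I_1$ vs $I_2$) are only expected to match in
sign and coarse magnitude.

```{r correlate, eval = FALSE}
res <- correlate_class(class_spec("G1", size = 2000, seed = 1))
res$correlation
```

## Known limitations

* The measures are functions of the degree-class multiset only: any two
  digraphs with the same out- and in-degree distributions are
  indistinguishable (the shipped path and hub fixtures share an
  out-polynomial while being non-isomorphic — degeneracy is reduced
  relative to single-degree indices, not eliminated).
* The $\alpha$ convention is a modelling choice; the homogeneity module
  quantifies, per graph, how much hangs on it.
* Exact isomorphism filtering is practical only for small graphs; for
  vertex counts far beyond the study classes a canonical-labelling
  backend would be needed.
* Weak connectivity is the connectivity notion throughout — the
  star/path reference graphs are not strongly connected, so strong
  connectivity would exclude the very examples the measures are
  calibrated on.
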