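---
title: "Prior and posterior linear pooling of expert opinion in discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior and posterior linear pooling of expert opinion in discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnpool)
```

## The model

A discrete Bayesian network over nodes $V$ factorises its joint
distribution as $P(X) = \prod_{v \in V} P(X_v \mid X_{\mathrm{pa}(v)})$,
each factor a conditional probability table (CPT) over the node's finite,
ordered state space. Every marginal or conditional query reduces to
marginalising and conditioning this product; `bnpool` answers such queries
exactly by variable elimination, with no sampling anywhere in the core.

When the CPTs come from an elicitation, each of $n$ experts supplies a
complete CPT set over one *shared* structure: the experts agree on the
nodes, states and arcs but hold their own probabilities. (Pooling over
differing structures is a different problem and is out of scope.) Opinions
are combined with the linear opinion pool
$P(X) = \sum_{i=1}^{n} w_i P_i(X)$, with $w_i > 0$, $\sum w_i = 1$, and
equal weights $w_i = 1/n$ by default — appropriate when each respondent's
experience is taken as equally informative, and the only weighting the
package's defaults assume. Arbitrary fixed weights are supported;
performance-based weight *estimation* is not.

The pool can enter the workflow at two points:

* **Prior Linear Pooling** (`pool_prior()`): each CPT row of the pooled
  network is $\sum_i w_i \, p_{i,\text{row}}$. One network results, and
  every subsequent query runs on it.
* **Posterior Linear Pooling** (`pool_posterior()`): each expert's own
  network is propagated under the query's evidence, and the resulting
  marginals at the target nodes are pooled with the same weights.

Pooling always happens at individual nodes, never jointly across several
nodes: linear pools do not preserve multivariate independence, and pooling
marginals node-wise avoids ever forming a pooled joint.

The two methods coincide in two exactly-testable situations — when all
experts are identical, and at root nodes queried without evidence (reading
a root's marginal is linear in the CPT, so averaging commutes) — and differ
in general. The package keeps a standing regression of the two-expert chain
whose PrLP and PoLP values at the child are 0.50 and 0.56: conditioning a
pooled table is not the same operation as pooling conditioned models.

Without evidence, a PoLP marginal equals the corresponding marginal of the
weighted *mixture* of the experts' joint distributions; the test suite
checks this identity against brute-force enumeration. Under evidence the
identity fails by design: the conditioned mixture would reweight expert $i$
by $P_i(\text{evidence})$, whereas PoLP pools the per-expert posteriors
with the panel weights unchanged. We implement the unweighted reading —
each expert's voice keeps its weight regardless of how well their model
predicted the evidence — and treat Bayesian-mixture reweighting as a
documented alternative, not behaviour. A fixed counterexample (the worked
chain with the child observed) pins down both the existence and the
direction of the discrepancy.

### Impossible evidence

If the evidence has probability zero under some expert's network, that
expert has no posterior. `pool_posterior()` errors by default, naming the
experts; with `drop_impossible = TRUE` it excludes them, renormalises the
remaining weights and warns. Both behaviours are explicit because silently
imputing an opinion would fabricate one; the same policy applies in
`per_expert_marginals()`. Inference itself raises a typed
`bnpool_impossible_evidence` condition carrying $P(\text{evidence})$ rather
than returning `NaN`.

## Subgroups: two routes

Subgroup questions ("do female respondents see Human Factors differently?")
arrive in two structurally different ways, and `subgroup_report()` supports
both:

* **Filter route** (`subgroups =`): covariates attached to the experts
  select a sub-panel; weights are renormalised proportionally
  ($w_i / \sum_{j \in S} w_j$, so equal weights stay equal) and the pool is
  recomputed. This is the natural route for PoLP, where each respondent has
  their own network. By linearity, the subgroup-weight-weighted average of
  subgroup PoLP marginals recomposes exactly into the full-panel pool — an
  invariant the tests check to 1e-12.
* **Conditioning route** (`subgroup_evidence =`): when the subgroup is a
  node of the network itself, it is clamped as evidence in the single
  pooled model. This is the natural route for PrLP.

The two routes answer different questions (composition of the panel vs
conditioning within a model) and are deliberately kept distinct in the
interface.

## The synthetic panel generator

No elicitation response model is implied by the pooling methods themselves,
so the generator commits to the minimal normalised-probability noise
family: expert $i$'s version of a CPT row with consensus value $p$ is drawn
$\mathrm{Dirichlet}(\kappa p)$, so the expected row is the consensus row
and $\kappa$ (concentration, dimensionless, default 20 in the packaged
fixture) controls the spread — per-entry variance
$p_k(1-p_k)/(\kappa+1)$. Covariates are assigned by exact largest-remainder
counts from the stated frequencies and then shuffled, which is why the
packaged panel reproduces its 46/53, 32/67, 85/14 composition exactly
rather than in expectation. Systematic subgroup opinion differences are
injected *before* the noise: a `subgroup_effect()` moves the probability of
one state of one node's CPT by exactly $\delta$ (clipped to stay inside
$(0,1)$), rescaling the complementary states proportionally, so the
injected effect is recoverable on its own scale — the difference of
subgroup-pooled PrLP entries estimates $\delta$ with standard error
$\sqrt{(v_1/n_1 + v_2/n_2)}$, $v = p(1-p)/(\kappa+1)$, and the tests demand
recovery within two standard errors.

What the generator emulates: between-expert heterogeneity around a shared
consensus, covariate-linked mean shifts, exact panel composition, equal
weights. What it does not: within-expert incoherence, rounding to coarse
elicitation scales, correlated errors across a single expert's rows,
non-response, or any fitting of $\kappa$/$\delta$ to real data. Passing
tests therefore demonstrate that the machinery recovers what this noise
family plants, not that real elicitations behave this way.

The packaged `wayfinding_fixture()` is a six-node binary schematic of
airport wayfinding (Human Factors, Environmental Factors, Communication,
Visual Elements of Communication, Navigation Pathway, Wayfinding) with a
99-respondent synthetic panel. Its edge set is a schematic reading of the
node descriptions, not a transcription of the full 49-node wayfinding
model, whose topology and CPTs are unpublished; **all CPT values in the
fixture are synthetic by construction**, and the shipped network file is
named `*_synthetic.xml` accordingly. The two planted effects (Inexperienced
respondents rate Wayfinding 0.10 less Effective; Female respondents rate
Human Factors 0.05 more Good) are this package's own choices, picked so
that subgroup machinery has a known signal to find at $n = 99$.

## Numerical and design choices

* **Canonical CPT layout.** Rows are keyed by parent joint states in
  declared parent order, enumerated with the *last* parent varying fastest.
  One fixed layout makes tables, files and pooled results bit-comparable;
  both file formats and the JSON schema use it.
* **Normalisation tolerance.** A CPT row must sum to 1 within 1e-9;
  constructors renormalise rows off by at most 1e-6 with a warning
  (elicited probabilities are typically rounded to a few decimals) and
  reject anything worse. Validation reports, rather than exceptions, come
  from `validate_network()` / `validate_panel()`, so a candidate object can
  be inspected for *all* its violations at once.
* **Elimination order.** Min-degree on the factor interaction graph with a
  lexicographic tie-break: determinism matters more than optimality at the
  tens-of-nodes scale this package targets. Correctness does not depend on
  the order; the enumeration oracle (`enumerate_joint()`, capped at 2^20
  joint states) is the independent check, and the suite compares the two
  routes on 100 random networks of up to 8 binary nodes with evidence sets
  of size 0–2 at 1e-10.
* **Pooled rows are renormalised** after averaging; in exact arithmetic the
  average of normalised rows is normalised, so this only absorbs float
  error and keeps downstream invariants tight (homogeneous collapse is
  asserted at 1e-12).
* **Quantiles and spread.** `describe_spread()` uses the sample (n−1)
  standard deviation — respondents are a sample — and type-7
  linear-interpolation quantiles, the default of mainstream numeric stacks;
  the convention is fixed in tests.
* **Determinism.** Generators are pure functions of their inputs and a
  seed, restore the caller's RNG state, and thread one seed through
  covariate assignment and all draws. File writers emit canonical output
  with probabilities at 17 significant digits, so writes are byte-stable
  and write→read round-trips are value-identical.
* **Identifiers.** State labels are case-sensitive exact strings
  ("Good" ≠ "good": silent merging across experts would be worse than an
  error). Classic-BIF identifiers cannot contain spaces, so networks using
  multi-word node names (like the wayfinding fixture) serialise to XMLBIF
  or panel JSON; the BIF writer refuses them with a pointer to XMLBIF.

## Problem sizes in the checks

The property suite runs at deliberately small scale: random networks of
3–8 binary nodes (where brute-force enumeration is exact and fast), panels
of 2–8 experts for algebraic identities, the 99-expert fixture for subgroup
workflows, and 20 replicate panels of 500 experts at $\kappa = 50$ for
consensus recovery (pooled CPT entries within 0.03 of consensus, ≥95%
coverage). These sizes are chosen so the whole suite re-derives every
expected value from first principles in well under a minute per property
while still exercising the asymptotics the generator's algebra predicts.

## Limitations

* Exact inference only; networks whose treewidth makes variable elimination
  infeasible are out of scope, as are MAP queries and approximate methods.
* Linear pooling only — no logarithmic/geometric pools, no external
  Bayesianity, and no pooling across differing structures.
* Covariates are categorical; missing categories are carried as `NA` and
  never imputed, and an expert with a missing CPT fails validation rather
  than being filled in.
* The wayfinding fixture demonstrates workflow, not substance: its CPTs and
  planted effects are synthetic, and nothing here reproduces any published
  elicitation's numbers.
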