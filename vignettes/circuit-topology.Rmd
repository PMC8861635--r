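---
title: "Circuit-topology analysis of genome folds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circuit-topology analysis of genome folds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgenome)
```

## The model

A folded chromosome is represented as a bead-on-a-string polymer, one bead
per 100 kb, and its fold is reduced to a set of intra-chain *contacts*:
bead pairs `(i, j)` closer in space than a cutoff `r_c` (in particle radii),
or Hi-C bin pairs whose count clears a threshold. First neighbors
(`|i - j| <= 1`) are never contacts. Circuit topology then classifies every
*pair* of contacts `A = [i, j]`, `B = [r, s]` (closed integer intervals of
bead indices) by how their arcs are arranged:

* **series (S)** — the intervals are disjoint;
* **parallel (P / P⁻¹)** — one interval lies strictly inside the open
  interval of the other; the inner contact is P with respect to the outer,
  the outer P⁻¹ with respect to the inner;
* **cross (X)** — the intervals overlap without containment;
* **concerted series (CS)** — the intervals share exactly one contact site;
* **concerted parallel (CP / CP⁻¹)** — containment with a shared endpoint.

P and X are grouped as **entangled** relations (they compact the chain
locally); S is unentangled; concerted relations form their own subgroup and
are excluded from the entangled set by default (`entangled_set()` has an
`include_concerted` switch for sensitivity analysis).

Two classification conventions make the scheme total and exclusive, and both
are deliberate design choices:

1. **Concerted priority.** The S/P/X set conditions are stated for generic
   intervals; when an endpoint is shared, only the CS/CP conditions can hold
   simultaneously with them. Testing CS, then CP/CP⁻¹, then S/P/P⁻¹, then X
   yields exactly one code for every admissible pair. The test suite checks
   this exhaustively for all contact pairs with endpoints in 0..9 and against
   an independent set-algebra classifier on 10⁵ random pairs.
2. **Closed intervals at bead resolution.** "Strictly inside the open
   interval" means strict inequalities on endpoints (`r < i` and `j < s`).
   Since contacts are deduplicated, two contacts can never share both
   endpoints; that case is a caught error.

All pairwise codes are stored in the N×N **topology matrix** (N = number of
contacts, indexed in chain order of their left sites; diagonal excluded as
`NONE`). Everything else in the package is a functional of this matrix.

```{r taxonomy}
classify_pair(c(3, 7), c(1, 9))   # inner contact vs its envelope
m <- build_topology_matrix(lloop_fixture())
relation_counts(m)
```

## Descriptors

**Entangled fraction** — entangled unordered pairs over `N(N-1)/2`. Summing a
matrix row counts the entangled relations a single contact experiences;
crediting both endpoints of each contact projects those counts onto beads
(100 kb of sequence). For Hi-C-derived sets the per-contact counts are binned
at 1 Mb by the contact's *first* (smaller) site, and gene abundances are
binned by gene midpoint with abundances below 50 per bin zeroed before the
Pearson correlation. The both-endpoints crediting rule for the per-site trace
means a contact whose two sites fall in one bin contributes twice there; this
is the documented convention, chosen so the trace total is exactly twice the
row-count total.

**Clustering coefficient and trefoils** — contact sites become network nodes
and contacts edges; `C_n = e_n / K_n` with `K_n = k_n(k_n-1)/2`, averaged
unweighted over all nodes, with degree-<2 nodes contributing 0
(Watts–Strogatz convention; excluding them would make a single isolated edge
undefined rather than 0). The only three-contact arrangement that closes a
triangle is the *trefoil* — two CS contacts enveloped by a CP contact — so
the average clustering is nonzero exactly when trefoils exist. Cells are
split into high/low clustering states at 0.02 with an inclusive boundary
(the empirical gap between the two subpopulations is wide, so the boundary
rule is a convention, kept configurable).

**Topological fractal dimension** — the matrix is binarized (1 = entangled
cell), zero-padded to a power of two, and covered with boxes of side
`l = 1, 2, 4, ..., n_pad/2`; `D` is the least-squares slope of `log N(l)`
versus `log(1/l)`. Entangled-only binarization is the default because the
full matrix has a relation in *every* cell and cannot itself be the fractal
set; the binarized entangled set reproduces the diagonal L-pattern structure
the raw matrices show. Numerical choices: saturated scales (`N(l) = 1` or
`N(l) =` total set cells) are dropped from the fit; a set with no scaling
range (a point) gets `D = 0`; an all-zero matrix gets `D = 0` with a
warning; slopes outside `[0, 2]` beyond floating-point noise are clamped
with a diagnostic. `D` is divided by the contact count for cross-chromosome
comparison, since the raw dimension grows with N.

**Cumulative-window scans** — windows of 5, 10, ..., n beads grown from
either chain end; a contact belongs to a window only when *both* endpoints
are inside (the window must be a valid sub-chain), windows with fewer than
two contacts give `NA`, and the final window reproduces the whole-chain
value exactly. Series are smoothed with a local least-squares polynomial
filter (degree 2, window 15 beads = 1.5 Mb); at the edges the window shrinks
symmetrically, which keeps the filter exact on polynomials up to the degree
everywhere. This in-package smoother is used instead of a FIR implementation
precisely to get that edge behavior. Peaks are local maxima with topographic
prominence ≥ 0.2 (on the natural [0, 1] scale of the entangled fraction);
peak spacings are summarized by a histogram-mode with 10-bead bins, ties to
the smaller spacing. Convergence of the fractal-dimension trace is declared
at the smallest window from which all later values stay within a relative
0.05 of the full-chain value — the tolerance is a package default, reported
with the result, as no canonical value exists.

**L-patterns and L-loops** — the elongated parallel features along the
matrix diagonal. The length of a contact's L-pattern is the count of
entangled codes on its matrix line *rightward from the diagonal*; counting
one triangle of the matrix attributes each entangled pair to its earlier
contact and makes the lengths sum exactly to the entangled pair count
(a tested invariant). The motif model behind these patterns is the
*L-loop*: one or more enveloping *turns*, followed by small nested
*pockets*, repeated, with occasional *cross contacts* striping the pattern.
Operationally a turn is a contact that strictly envelops at least
`min_enveloped` (default 1) other contacts and is not a cross stripe (in X
relation with an earlier turn candidate — in the motif, cross contacts
arrive later along the loop than the turn they cut). Turns are grouped into
nested L-patterns by walking them in containment order: a group continues
while the outer turn directly envelops the next with no pocket of the outer
sitting disjoint from the next; such a pocket closes the group. The default
`min_enveloped = 1` is what makes a single outer-plus-pocket pair count as
one L-pattern, which is the degenerate base case of the motif. Segment
barcodes split the chain into 4 (or 8) equal-bead segments and credit each
contact's length to its smaller endpoint's segment, mirroring the 1 Mb
binning rule. Pooled lengths are split at the median of the *nonzero*
lengths, the median element going to the upper half.

```{r lloop}
lpattern_lengths(m)
turn_groups(m)
segment_barcode(lpattern_lengths(m), lloop_fixture(), 4)
```

## Statistical test selection

Group comparisons follow a fixed decision tree at α = 0.05 for diagnostics
and inference alike: Shapiro–Wilk normality on each sample and a
mean-centered Levene variance test decide among Student's t (normal, equal
variance), Welch's t (normal, unequal), Mann–Whitney U (non-normal, equal)
and Kolmogorov–Smirnov (non-normal, unequal); all two-sided. Confidence
intervals for means use the t distribution, appropriate for the small
per-cell chromosome counts this summarizes. No multiple-testing correction
is applied, matching the reporting conventions the pipeline feeds.

## Synthetic data: what it emulates, and what it does not

The package is exercised entirely on generated data.

* `random_chain()` is the null model: a lattice walk (grid step = one
  particle = 100 kb) confined to a box whose walls should be matched to the
  extent of a reference chain (`box_from_chain()`), forbidden from reversing
  its previous step. It is *not* self-avoiding — the null is an equilibrium
  globule, not a real polymer with excluded volume. Blocked walks restart
  from a fresh start point with a bounded retry budget; this choice (restart
  rather than per-move rejection) only matters in degenerate boxes.
* `trefoil_series(k)` produces k disjoint contact triples
  `{(6t, 6t+2), (6t+2, 6t+4), (6t, 6t+4)}`. The stride of 6 is the smallest
  spacing that keeps consecutive triples disjoint while respecting the
  first-neighbor exclusion; trefoils sharing a site would dilute the
  clustering coefficient below 1 and no longer represent trefoils in series.
* `lloop_fixture()` is the canonical nine-contact L-loop on a 124-bead
  chain. The exact coordinates are a fixture choice; the asserted properties
  (outer length 8, three turn groups, entangled fraction 27/36) are
  coordinate-independent consequences of the motif.
* `periodic_trace()` and `synthetic_expression()` plant a known periodicity
  and a known Pearson correlation, for recovery tests of the
  smooth → peaks → spacing pipeline and the expression coupling.

Passing tests on these generators demonstrates that the machinery measures
what it claims on inputs with known ground truth. They do **not** show that
real single-cell chromosome structures have any particular entangled
fraction, length scale or motif content: real data bring binary,
noisy, incomplete contact maps, population averaging, and resolution limits
that no generator here imitates.

## Problem sizes and defaults

Default analysis scales used throughout the tests: chains of 60–150 beads
(6–15 Mb) for walk and pipeline tests, contact sets of 30–1000 contacts for
property checks, 20 seeded replicates for the null-versus-structured
contrast, 150 seeded replicates (3 periods × 50) for length-scale recovery,
and 500 replicates for the null rejection rate. These sizes give stable
statistics for every property asserted while keeping the default suite
fast to run routinely.

Parameter defaults, with units: `r_c = 1.0` particle radii (supported range
0.5–2.0; the choice is ultimately a visual-inspection judgment on real
structures and stays a free parameter); Hi-C count threshold 250 (100–300
give the same qualitative behavior); 1 Mb bins; abundance floor 50 per Mb;
clustering split 0.02; scan step 5 beads; smoothing window 15 beads,
degree 2; prominence 0.2; convergence tolerance 0.05; 4 barcode segments.
`ct_config()` collects all of them and every pipeline run echoes its
configuration into the output manifest.

## Known limitations

* Relations are per-chromosome; trans-chromosomal contacts are out of scope.
* Contacts are binary: duplicate bead pairs within the cutoff collapse to
  one contact, so contact *frequency* information in bulk Hi-C is used only
  through the count threshold.
* Binary single-cell contact maps often cannot resolve the three-site
  triplets that produce trefoils, so clustering coefficients computed from
  such maps (rather than 3D models) can be degenerately zero.
* No Hi-C normalization (ICE or similar) is applied or planned; the package
  consumes count matrices as given.
* The L-loop machinery implements the canonical motif only; small variants
  of the pattern are classified by the same rules rather than taxonomized.
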