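---
title: "Folding engines: sparsification, Four-Russians, and their combination"
author: "rnassf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folding engines: sparsification, Four-Russians, and their combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnassf)
```

## The problem and the model

Single-sequence folding (SSF) asks for a maximum-score *secondary structure*
of an RNA string $s = s_0 s_1 \ldots s_{n-1}$ over $\{A,U,C,G\}$: a set of
base pairs $(k, l)$, each position in at most one pair, with no two pairs
crossing. The score of a structure is the sum of per-pair scores
$\beta(k, l)$; by default $\beta = 1$ for the Watson–Crick pairs
$\{A{:}U, C{:}G\}$ and $0$ otherwise (base-pair maximization). Any
non-negative *integer* pair scoring works; discreteness is load-bearing, as
explained below.

With the half-open substring convention $s_{i,j} = s_i \ldots s_{j-1}$, the
classic cubic recurrence is

$$
L[i,j] = \max\bigl(L^p[i,j],\; L^c[i,j]\bigr), \qquad
L^p[i,j] = \max_{k \in (i,j)} L[i,k] + L[k,j], \qquad
L^c[i,j] = L[i+1,j-1] + \beta(s_i, s_{j-1}),
$$

with $L[i,i] = L[i,i+1] = 0$ and a $-\infty$ sentinel below the diagonal
(surfaced as `NA` in R). The DP sweeps columns $j = 1..n$, rows
$k = j-1..0$ within a column; the answer is $L[0,n]$. The split-point
maximization $L^p$ is the cubic bottleneck, and every engine in this
package is a different strategy for spending less on it while producing
**bit-identical matrices**.

All engines return the same `ssf_result`; `tests/` and the cross-engine
assertions in `run_benchmark()` hold them to exact matrix equality.

## Operation counting

Engines are compared by *counted operations*, not wall-clock time, so the
comparison is compiler- and cache-independent. The package's fixed
convention:

* each candidate split point $k$ examined while computing some $L^p[i,j]$
  counts 1 (`split_comparisons`);
* each lookup-table build counts 1 (`mul_builds`, `max_builds`,
  `g_builds`);
* each gated MUL access that hits the cache counts 1 (`mul_lookups`);
* MAX-table hits and first-element shortcut resolutions are *reported*
  (`max_lookups`) but not totalled: they construct no entry and examine no
  split point.

`total_ops()` is the sum of the first three groups. The $L^c$ evaluation and
the final two-way max are never counted. Under this convention the baseline
engine performs exactly $\binom{n+1}{3}$ split comparisons — 43,680 /
349,504 / 2,796,160 at $n = 64/128/256$ — which pins the convention to a
closed form independent of this implementation.

## Sparsification: STEP and OCT candidates

Cell $(i,j)$ is **OCT** when every optimal folding of $s_{i,j}$ is
co-terminus (operationally $L = L^c > L^p$), and **STEP** when
$L[i,j] > L[i+1,j]$, i.e. position $i$ is paired in every optimal folding.
The candidate theorem behind the `sp` engine: some optimal split point $k$
of $(i,j)$ is either $k = i+1$ or satisfies "$(i,k)$ STEP and $(k,j)$ OCT".
The engine therefore keeps, per column, an incrementally grown list of OCT
rows (appended as cells finalize, so list maintenance costs nothing extra)
and examines only the mandatory $k = i+1$ plus STEP-filtered OCT rows.

One correctness subtlety is worth recording. A single-nucleotide
sub-instance $s_{k,k+1}$ admits no split point at all, so its only folding
is *vacuously* co-terminus — it is OCT in the semantic sense — yet the
operational inequality can never fire on a base cell ($L^p = L^c = -\infty$
there). Dropping it loses real optima: for a cell $(i, j)$ whose optimum
keeps $s_{j-1}$ unpaired atop a STEP prefix $(i, j-1)$, the only candidate
covering it is $k = j-1$ through the base cell $(j-1, j)$. The engines
therefore seed every column's candidate list (and the gate signatures
below) with row $j-1$, while the *reported* `oct` flags, `Z`, and
`sig_oct` stay strict: base cells are never flagged, matching the
classification convention used everywhere else in the package.

Observed sparsity is summarized per solve: `Z` (strict OCT cells,
$\le n^2/2$) and per-column STEP counts ($\le \lfloor k/2 \rfloor$ for the
default scheme). Pair-free sequences have no strict OCT/STEP cells at all,
so `Z` may fall to 0; the package records observed `Z` rather than
asserting any lower bound.

## Four-Russians with on-demand tables

Adding one nucleotide changes an optimal score by at most
$\beta_{\max}$, so consecutive entries of any $L$ column differ by a value
in $[0, \beta_{\max}]$: columns are *D-discrete* with
$D = \beta_{\max} + 1$. A length-$q$ D-discrete vector is representable as
$(x_0, \Delta)$ — first element plus the base-$D$ packing of its
differences, first difference most significant, $0 \le \Delta < D^{q-1}$.
Two consequences:

* the max-plus product of a fixed $q \times q$ block with a vector depends
  on the vector only through $\Delta$ (shifting by $x_0$ commutes with
  max-plus), so products are memoizable in a **MUL** table keyed by
  (row group, column group, $\Delta$), at most $D^{q-1}$ entries per block;
* the elementwise max of two encoded vectors depends only on
  $(\Delta_v, \Delta_w, h)$ with head gap $h = w_0 - v_0$, memoizable in a
  **MAX** table. If $h$ exceeds what the differences can recover, the
  larger-headed vector dominates outright. For $D = 2$ that threshold is
  $q - 1$; in general a D-discrete vector drops by up to $D-1$ per step, so
  the package uses $(q-1)(D-1)$ — the binary rule is the special case, and
  the general MAX key space grows to
  $D^{q-1} \cdot D^{q-1} \cdot ((q-1)(D-1)+1)$.

The `fr` engine tiles the matrix into $q \times q$ blocks
($q = \max(1, \lfloor \epsilon \log_D n \rfloor)$, $\epsilon \in (0, 0.5]$,
default $0.4$). For each column and each row group, contributions of all
*full* groups strictly between the row group and the column's group are
accumulated as one MUL access plus one Δ-max per block; the group
containing $i$ (a per-row prefix), the partial group containing $j$, and
the mandatory $k = i+1$ are evaluated per cell. Tables fill *on demand*:
an entry is built (at $O(q^2)$ or $O(q)$ once) only when some column
actually asks for it, so no preprocessing cost is paid for encodings that
never occur. `q` is capped (default 8) to bound table memory; $\epsilon$ at
the upper boundary $0.5$ is admitted so that, e.g., $n = 256$ yields
$q = 4$.

## The combined sparse Four-Russians engine

Per column-group and column, a $q$-bit `sigOct` signature marks which rows
of the subcolumn are OCT; per block, a `sigStep` signature marks which of
its columns contain a STEP cell. A block can contribute a *new* optimum to
$L^p[I_{g'}, j]$ only if the bitwise dot product
$\mathrm{sigStep}(g', g) \odot \mathrm{sigOct}(g, j)$ is 1, so the `sfr`
engine gates every MUL access on it. The gate is navigated through the
on-demand **G** table: key (column group, signature) mapping to the row
groups whose `sigStep` intersects it — built by one scan, then reused
across columns (signatures are final once a column group completes). As
each subcolumn of the current column finalizes, its classification and
signatures are tabulated and its contribution pushed through the G table to
exactly the row groups that can profit; per-cell work (prefix, partial
group, mandatory $k=i+1$) uses the sparsified candidate iteration. Gating
is pure pruning: with the gate disabled (`gated = FALSE`) matrices are
identical and only counters move.

Because the gated accesses are a subset of `fr`'s and the per-cell
candidates a subset of `sp`'s full-range candidates, the combined engine is
never behind `fr` structurally; that it also stays at-or-below `sp` on
every random instance tested (the dominance test in the suite) is the
empirical headline the benchmark reproduces.

## The wavefront simulation

The parallel formulation assigns one logical process per column; at round
$d$, column $j$ computes the subvector of rows $I_{g_j - d}$. The simulator
executes rounds serially and charges every counted event to the requesting
column (`col_ops`), so the asymptotic claims can be checked as accounting
identities (makespan = max column ops) without threads.

The scheduling contract is enforced, not assumed. Every block/vector read
(the table path) must come from a cell finalized in a *strictly earlier*
round — that is the invariant the parallel formulation rests on, and it
holds because a block
$(g', g)$ read at round $d = g_j - g'$ was finalized at round $g - g' < d$.
The per-cell reads ($L^c$ from column $j-1$; partial-group split points)
necessarily cross into the *same* round whenever adjacent columns share a
column group, so for those the simulator enforces the weaker lexicographic
order: finalized in an earlier round, or in the same round by a
strictly smaller column (within a round, columns advance in increasing
$j$). Any violation of either rule is a hard error, and the check is always
on in the simulator. When two columns demand the same missing MUL entry in
one round, the lowest-index column builds it once and is charged for it.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `scheme` | AU = CG = 1 | non-negative integer pair scores; sets $D = \beta_{\max}+1$ |
| `epsilon` | 0.4 | block-size factor, $q = \lfloor \epsilon \log_D n \rfloor$, in $(0, 0.5]$ |
| `q_max` (via [choose_q()]) | 8 | cap on $q$; bounds MUL/MAX key space |
| `min_loop` | 0 | minimum unpaired positions inside a pair; 0 matches the recurrence as stated, adjacent positions may pair |
| `gated` / `sparsified` | TRUE | signature gating in `sfr` / the simulator |

## What the random-sequence generator does and does not emulate

`random_sequence()` draws bases i.i.d. uniformly — the input model under
which the benchmark counts are collected (composition is recorded in every
report header). Uniform random RNA is *dense* in pairing opportunities:
scores grow linearly in $n$ and STEP/OCT cells abound, which is exactly the
regime where sparsification has work to prune. Real RNA differs in
composition bias, local structure, and thermodynamics; passing tests here
demonstrate algorithmic correctness and the counting relationships between
engines, not biological accuracy of predicted structures (base-pair
maximization is not a thermodynamic model; no stacking, loop penalties, or
pseudoknots).

## Numerical and design choices

* 0-based, half-open coordinates exactly as in the recurrence; matrices are
  $(n+1) \times (n+1)$, the answer at $L[0,n]$; sub-diagonal cells hold a
  sentinel surfaced as `NA`, never read as a score.
* Traceback tie-breaks, fixed for determinism: subproblems with $L = 0$
  emit nothing; the co-terminus branch is taken when optimal *and* its
  closing pair scores positively (a zero-score closing pair is always
  matched by a partition, so no zero pairs are ever emitted); otherwise the
  smallest optimal split point. The traceback verifies its own score
  against $L[0,n]$ and hard-fails on matrix inconsistency.
* MUL tables are keyed by block coordinates, not content hashes: the
  per-submatrix accounting stays legible in the counters, at the cost of
  not sharing entries between identical blocks.
* The G cache is unbounded by default (distinct builds are bounded by
  $\min(2^q, \text{OCT-bearing subcolumns})$ in practice); counters expose
  `g_builds` so growth is visible.
* Ambiguity codes (e.g. N) are rejected rather than scored 0, keeping the
  column-discreteness argument intact.
* Test and benchmark problem sizes — $n \le 256$, 20 replicates, 500
  small oracle instances — were chosen as the sizes at which every
  engine's asymptotic behaviour is already separated by the counters
  while the whole suite stays fast enough to run habitually.

## Worked example

```{r example}
sq <- random_sequence(76, 42)
res <- ssf_fold(sq, engine = "sfr")
res
tb <- ssf_traceback(res)
cat(format_dotbracket(sq, tb), "\n")
sapply(c("naive", "sp", "fr", "sfr"),
       function(e) total_ops(ssf_fold(sq, engine = e)))
```

## Known limitations

* Base-pair maximization only: no nearest-neighbor thermodynamics,
  partition function, or pseudoknots.
* Counters model comparisons and table events, not memory traffic; the
  simulator models dependency structure, not true concurrency.
* The Four-Russians tables live per solve; nothing is shared across calls.
* Absolute operation counts for the sparsified and table-based methods
  depend on the counting convention chosen, so they are comparable within
  one convention only; the baseline's closed form and the *ordering* of
  methods are convention-independent, and those are what the tests pin
  down.
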