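---
title: "Attractor observability in Boolean networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attractor observability in Boolean networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aobn)
```

## The problem

A synchronous Boolean network $G(V, F)$ models a gene regulatory system as
$n$ binary nodes $v_1, \dots, v_n$ (1 = expressed/active, 0 = not), each
updated by a Boolean function of its inputs, all nodes at once:
$v_i(t+1) = f_i(v(t))$. The global state (Gene Activity Profile) moves on a
functional graph over the $2^n$ states, so every trajectory eventually
enters a directed cycle — an *attractor*. A period-1 attractor is a fixed
point (singleton); period $p \ge 2$ is a cyclic attractor. Attractors are
commonly read as the stable cell types or disease states of the modelled
system.

*Attractor observability* asks: given the $m$ attractors
$S = \{S_1, \dots, S_m\}$ with sizes $l_1, \dots, l_m$, what is the minimum
number of **consecutive** nodes whose joint binary pattern identifies which
attractor the system occupies? A contiguous window is attractive in
practice because neighbouring probes (a small targeted panel) are cheaper
to read out than an arbitrary scattered node set, and because the general
(non-contiguous) minimal-key problem is NP-hard even over a binary
alphabet. The contiguous window found is therefore a candidate biomarker
panel.

Since $m$ distinct binary patterns need $\lceil \log_2 m \rceil$ bits, the
answer is never smaller than that threshold; `ao_threshold(m)` exposes it.

## The algorithm

For cyclic attractors the observed pattern depends on the phase of each
cycle, so the method enumerates *phase combinations*: each combination
picks one state from every attractor, giving an $m \times n$ matrix $A_i$;
there are $L = l_1 l_2 \cdots l_m$ combinations
(`enumerate_combinations()`, attractor 1 slowest-varying). For each
combination:

1. **Pairwise difference matrix.** For every unordered attractor pair the
   elementwise XOR of their rows is taken (`pair_xor_matrix()`), a
   $\binom{m}{2} \times n$ binary matrix. A 0 marks a column where the two
   attractors agree; a window fails to separate a pair exactly when it
   lies inside a run of 0's of that pair's row.
2. **Qualifying zero runs.** Every maximal run of consecutive 0's of
   length at least $\lceil \log_2 m \rceil$ is recorded, pooled over rows
   (`find_zero_runs()`). Shorter runs cannot defeat a window of at least
   threshold length and are ignored.
3. **Coverage shortcut.** If some column is covered by no qualifying run
   (`coverage_gap()`), any threshold-length window containing it separates
   every pair, so the combination's minimum equals the threshold and the
   scan of this combination stops.
4. **Run pruning.** Otherwise the runs are sorted by start column; among
   runs sharing a start only the longest is kept, and any run strictly
   contained in another is removed too (`prune_runs()`). The result has
   strictly increasing starts and ends.
5. **Window-length formula.** With pruned runs $B$, the combination's
   minimum is
   $\max\{\min_j [B(j,2) - B(j{+}1,1) + 3],\ \lceil \log_2 m \rceil\}$
   (`min_window_length()`): the inner term is the length of the shortest
   window extending one column past the end of run $j$ and one column
   before the start of run $j{+}1$, which no run can contain. A single
   pruned run spanning $1..n$ means some pair agrees everywhere; the
   combination gets `Inf`.

The overall answer is the minimum over combinations (`ao_solve()`); a
window counts as sufficient if *some* phase assignment makes the patterns
distinct. Achieving windows are recovered by a direct distinctness scan
(`recover_windows()`) and reported as 1-based closed intervals
`[start, end]`, matching the usual $x_1..x_n$ gene numbering.

### Containment pruning

Same-start deduplication alone leaves contained runs such as
$[4,7] \subset [3,9]$ in the pruned list, and the adjacent-pair formula can
then propose a window ending past column $n$. A run strictly contained in
another constrains no window that the containing run does not, so this
package removes contained runs as well. On the bundled mixed
singleton/cyclic example this is what makes every per-combination value
well defined (combination 3 otherwise yields an out-of-range candidate),
and the exhaustive scan then returns 4, 6, 3, 2 across the four
combinations.

### Phase semantics

Deeming a window sufficient when *some* phase combination separates the
attractors is a deliberate reading: an observer sampling a cyclic
attractor at an unknown phase might, under a stricter semantics, require
distinctness under *every* phase assignment. The bundled 7-gene example
shows the difference: columns 3–4 separate the four attractors for the
reported phase choice, while another phase of the third attractor collides
with the first. The package implements the some-phase semantics throughout
(it is what the window-length formula computes); an all-phase variant
would be a different, strictly harder problem and is out of scope.

## Supporting machinery

**Dynamics.** `read_boolean_rules()` parses one rule per line
(`name, expression` over `& | ! ^` and parentheses) into per-node truth
tables, little-endian in the input list (first listed input is the
lowest-order address bit). `transition_table()` and
`enumerate_attractors()` traverse the full state space iteratively with a
visited map — no $2^n \times 2^n$ matrices — and refuse beyond $n = 20$
nodes by default (`limit=`), a practical cap chosen because $2^{20}$
integer codes is where exhaustive traversal stops being instantaneous;
larger networks need dedicated attractor-detection machinery that is not
this package's topic. Attractors are rotated to start at their
lexicographically smallest state and sorted by it, so output order is
deterministic.

**Oracle.** `brute_force_min()` re-derives the answer from the definition
alone: it scans window lengths in ascending order, over all combinations
(its own `expand.grid` enumeration) and all start positions, testing
pairwise distinctness of restricted rows by string keys. It shares no code
with the zero-run solver, so agreement between the two is evidence of
correctness rather than tautology. Its guard refuses instances with
$L n^2 m^2$ beyond a budget (default $10^8$).

**Random instances.** `random_attractor_set()` draws every bit
independently and equiprobably, resampling whole sets until all
$\sum l_i$ states are pairwise distinct. Distinctness is enforced because
two attractors of a deterministic network can never share a state; it also
guarantees every phase combination has pairwise-distinct rows, so random
sets are always feasible. Cyclic "attractors" here are random distinct
state lists, *not* cycles of an actual network: the observability analysis
depends only on the listed states, and this is what the sensitivity
experiments require. What this generator does not emulate: the correlated,
sparse structure of real regulatory steady states (compare the Drosophila
rows, which share long identical stretches — exactly why that instance
needs 22 consecutive nodes while random instances of the same size need
about 6). Passing the random-instance tests therefore validates the
algorithm, not any claim about real networks; the Drosophila fixture is
the realistic end of the spectrum.

**Experiments.** `run_experiment()` repeats draw-and-solve `trials` times
and averages the minimum (numNode); `ao_sweep()` grids over $n$ or $m$.
In the package's own test runs the singleton regime uses $n = 200$,
$m = 20$ with 50 trials (mean numNode $\approx 5.9$) and the period-2
regime $n = 100$, $m = 4$ with 50 trials (mean numNode $= 2$); the
solver-versus-oracle comparison uses 500 random instances with
$m \in [2,6]$, $n \in [6,16]$ and per-attractor periods in $\{1,2,3\}$.
These sizes keep the whole suite under a minute while giving the
stochastic means standard errors well inside their tolerances.

## Numerical and interface choices

- All reported column indices are 1-based closed intervals; windows are
  linear, never wrap-around.
- Early termination is the default: the combination scan stops as soon as
  some combination attains the global lower bound
  $\lceil \log_2 m \rceil$. `exhaustive = TRUE` evaluates all $L$
  combinations and reports the per-combination minima; both modes return
  the same minimum (tested).
- Ties: *all* achieving (combination, window) pairs among the evaluated
  combinations are reported, ordered by combination id then start column.
- Degenerate inputs: $m = 1$ returns 0 (nothing to discriminate);
  an indistinguishable combination gets `Inf` rather than an error, and a
  result is flagged infeasible only if every combination is `Inf` —
  unreachable for sets built from distinct states, but kept for run-table
  level use.
- Sorting of runs uses R's stable `order()`; the choice of sorting
  algorithm is immaterial to the result.
- Attractor-set files are plain TSV (`attractor_id`, `phase`, then gene
  columns or one binary-string column); reports are JSON (schema
  `aobn-report/1`) or TSV. The Drosophila steady states ship verbatim as a
  60-character-per-line text file and are parsed at load, never
  transcribed into code.

## Limitations

- Synchronous updates only; asynchronous and probabilistic networks are
  out of scope.
- Exhaustive attractor enumeration is capped at $n = 20$; SAT/ILP-style
  attractor detection for large networks is not provided (attractor sets
  for large $n$ can be supplied directly as files).
- The solver's cost is $O(\binom{m}{2} n)$ per combination but the number
  of combinations is $\prod l_i$, exponential in the number of cyclic
  attractors; the early-termination rule usually saves most of this in
  practice, and the brute-force oracle is exponential by design.
- Only contiguous windows are considered; the general minimal
  distinguishing node set problem is NP-hard and not addressed.
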