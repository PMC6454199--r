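---
title: "Communication sparsity in distributed SNN simulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communication sparsity in distributed SNN simulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snncomm)
```

## The problem

In a distributed time-step spiking neural network (SNN) simulation, every
step has two phases: a *computation* phase (membrane and synapse updates)
and an *exchange* phase (spikes propagated to postsynaptic targets hosted
on other processes). At scale the exchange phase dominates: processes
must implicitly synchronise, perform a handshake to learn who will send
to whom, and then move the spike payload. `snncomm` reproduces the two
levers that attack this overhead — connectivity-aware neuron allocation
via hypergraph partitioning, and dynamic sparse census exchange — on a
single machine, by simulating over *virtual* processes. Dynamics are
computed once, globally; communication is accounted exactly, message by
message, per virtual process. Everything hardware-bound (wall-clock time,
MPI behaviour, interconnect contention) is deliberately out of scope: the
package reports counts and bytes, which are reproducible on any machine.

## The communication model

A network is mapped to a hypergraph $H = (V, E)$: one vertex per neuron,
and one hyperedge per presynaptic neuron containing that neuron and all
of its postsynaptic targets. The hyperedge is the unit of communication —
a spike is all-or-nothing, every target must be notified — so the
*connectivity-1* cost of an allocation,
$$\sum_{e \in E} \left(|\pi(e)| - 1\right),$$
with $\pi(e)$ the set of processes touched by hyperedge $e$, counts
exactly the interprocess notifications a spike on every neuron would
trigger. Cost 0 means no interprocess communication at all. Vertex
weights are `in-degree + 1`: synapse objects live on the postsynaptic
side, so incoming synapses dominate per-neuron work. The balance
constraint is the ratio of maximum to mean part load, kept below a
tolerance (default 1.001).

Two aggregate metrics summarise a run:

* **ARN** (average runtime neighbors): the mean, over processes and
  exchange steps, of the number of distinct processes a process sends
  payload to. Silent steps count (they dilute the average), ARN is at
  most $P - 1$ and 0 when $P = 1$.
* **Remote spikes**: the package exposes both a per-firing-event count
  (`remote_spikes`: firing neurons with at least one remote target) and a
  per-(spike, target process) count (`remote_spike_messages`). At
  realistic connectivity densities the per-event count is saturated —
  virtually every spike has some remote target under *any* allocation —
  so the per-message count is the one that discriminates between
  allocation strategies, and the one the comparison experiments report.

## Allocation strategies

Three allocators produce assignments over the same vertex set:

* `allocate_round_robin()`: neuron $i \to i \bmod P$. The load-balancing
  standard of neuronal simulators and the connectivity worst case.
* `allocate_random_balanced()`: a seeded random permutation placed
  greedily on the lightest part; balanced but connectivity-blind.
* `partition_hypergraph()`: multilevel partitioning minimising the
  connectivity-1 cut under the balance constraint.

The multilevel scheme is classic: *coarsening* by agglomerative
inner-product matching (the affinity of two vertices is
$\sum_{e \ni u,v} 1/(|e|-1)$, so small tight edges attract most; ties
break to the smaller combined weight, then the lower id), a *seed
partition* of the coarsest level (longest-processing-time greedy, which
bounds the load gap by one vertex weight and never leaves a part empty),
and *uncoarsening* with Fiduccia–Mattheyses refinement plus greedy
rebalancing at every level (a V-cycle). An FM pass visits boundary
vertices in a seeded random order, tentatively moves each to its
gain-maximal admissible part, locks it, and rolls back to the best prefix
of the move sequence — so a pass can explore through negative-gain moves
yet never returns a worse cut, and no accepted state violates the balance
constraint.

### Numerical and degenerate-input choices

* **Tolerance ladder.** The 1.001 default presumes $10^4$–$10^5$ vertices
  per part. When a single vertex weight exceeds the permitted slack
  (0.1% of a part load) the constraint is unattainable at that
  granularity; the working tolerance then relaxes stepwise through 1.01,
  1.05, 1.10, and on instances so small that even 1.10 leaves less than
  one vertex weight of slack it floors at one vertex weight above the
  mean load — the room any single-vertex move needs, and a bound some
  assignment always satisfies (the LPT guarantee). The tolerance actually
  used is reported on the assignment; an infeasible instance raises an
  error rather than returning an unbalanced result.
* **Coarsening stop.** Coarsening stops at `max(10 * P, 150)` vertices or
  when a level shrinks the instance by less than 5%. Cluster weights are
  capped (a third of the allowed part load, floored at twice the maximum
  vertex weight) so coarse vertices stay placeable.
* **Determinism.** All visit orders derive from the config seed;
  identical inputs give bit-identical assignments.
* **Ties.** Gain ties in FM break to the lighter target part, then the
  lower part id; matching ties to the smaller combined weight, then the
  lower vertex id.

The pass cap (`max_fm_passes = 10`, stopping early at the first
zero-gain pass) and the stop criterion are declared defaults, not
reconstructions of any external partitioner's internals.

## Census exchange patterns

Each exchange is a *census*: every process knows its send targets but not
its receive sources. Two patterns are accounted:

* **PEX** (personalized exchange): an explicit all-to-all handshake —
  every process sends one metadata unit to each of the other $P-1$
  processes, even to say "nothing coming" — followed by payload sends
  along flagged pairs. Handshake volume is exactly $P(P-1)$ units per
  exchange, independent of activity: quadratic growth that becomes the
  dominant cost at scale.
* **NBX** (neighborhood exchange): payload goes straight to actual
  targets; an asynchronous barrier replaces the handshake. The barrier
  token is counted as one message per process with a payload of zero
  bytes, so NBX metadata volume is identically 0.

Byte accounting is 4 bytes per neuron id and per metadata unit (the
32-bit address-event convention). Both patterns deliver identical id
multisets for identical traffic — the pattern can never change the
dynamics — and this equivalence is asserted, not assumed, in the test
suite. Timing is not modelled at all: implicit-synchronisation and
exchange *times* are hardware quantities, excluded by design.

## The simulator

Leaky integrate-and-fire neurons with exponential synaptic currents,
integrated by forward Euler at `dt = 0.1` ms (the integrator the tests
verify to first order against the closed-form relaxation; exact
exponential integration is a possible extension, Euler is the documented
baseline choice):

$$ i_{syn} \leftarrow i_{syn}\, e^{-dt/\tau_{syn}} + \textstyle\sum w_{arrived}, \qquad
   v \leftarrow v + \frac{dt}{\tau_m}\left(-(v - v_{rest}) + R_m (i_{ext} + i_{syn})\right). $$

A neuron fires when $v \ge v_{thresh}$ outside the refractory period; it
then resets and is clamped at $v_{reset}$ for $t_{ref}$. Neurons update
in ascending global id; spikes are delivered through a delay ring buffer
exactly `delay/dt` steps later. Because the engine never consults the
assignment for dynamics, the spike raster is bit-identical across all
allocation strategies and both communication patterns — the central
correctness property, asserted by the experiment harness on every grid
cell. Exchanges happen every step (`exchange_every = 1`): the benchmark
networks carry random per-synapse delays with a one-step minimum, the
regime in which message packing across steps is impossible.

### Initial conditions

The microcircuit parameter convention used here places the resting
potential (−45 mV) above the threshold (−50 mV), which with the constant
0.95 mA drive produces sustained tonic firing — the point of the
benchmark is steady, spatially uniform traffic, not biological realism,
and the apparent inversion is kept as specified rather than silently
corrected. A consequence is that identical initial conditions would put
the whole network in exact phase lockstep (every neuron firing on the
same step), which collapses every communication metric to a degenerate
all-or-nothing pattern. The default initial state therefore draws each
membrane potential uniformly between reset and threshold (seeded,
reproducible), standing in for the phase-spreading effect of a noisy
external drive; `init = "rest"` restores the lockstep behaviour when the
edge case itself is of interest. With the defaults the presets run at
roughly 60–70 spikes/s — above the 5–7 spikes/s the original
configuration quotes, which is unreachable under a deterministic constant
drive without fine-tuning; since every comparison below is a ratio of
communication counts between allocations of the *same* run, the rate
scales both sides equally.

## The benchmark generators

Both generators are table-driven Bernoulli samplers: each ordered neuron
pair covered by a rule connects independently with the rule's
probability (no autapses), and structure, weights and delays draw from
three separate named RNG streams, so rewiring is invariant when only the
weight seed changes.

* **`cm_like_spec()`** — a layered, 8-population microcircuit analogue:
  L2/3, L4, L5, L6, each with an excitatory and an inhibitory population
  at 4:1. The reference microcircuit's probability table is not
  reproduced; instead relative strengths (same population 20, same layer
  10, a weak feedforward loop 3, baseline 1) are normalised to a target
  mean in-degree. This preserves what the allocation method exploits —
  within-layer connectivity exceeding cross-layer connectivity — without
  inventing citable numbers; the real table can be supplied through
  `read_model_spec()`.
* **`multiarea_spec()`** — 32 areas, each an independent layered
  microcircuit, with a single fixed cell-to-cell probability between any
  two distinct areas, the stronger inhibitory multiplier (−15) and the
  weaker drive (0.38 mA) of the multi-area convention.

Delays are uniform on $\{1,\dots,15\} \cdot dt$ per synapse: "random
delays" with the simplest grid-consistent distribution, whose one-step
minimum forces per-step exchange. Weights are constant per rule by
default (distribution hooks exist); inhibitory populations' outgoing
weights are scaled by the multiplier (−4 microcircuit, −15 multi-area).

### Desk-scale study conditions

The cluster-scale originals (77 k neurons / 150 M synapses; 660 k / 620 M)
exceed what a single-machine R session should chew on, so the presets
preserve structure, not size — and these sizes were fixed once, as the
package's study conditions:

* CM-like: 20 000 neurons (40 000 for the partitioner balance study),
  mean in-degree 50, $P = 96$ virtual processes, 100 ms at 0.1 ms.
* Multi-area: 32 areas × 1 000 neurons, intra-area mean in-degree 45,
  inter-area probability $10^{-4}$ (intra ≫ inter, the modularity the
  partitioner exploits), $P = 192$, 50 ms at 0.1 ms.
* Comparisons are medians over 5 seeded realisations; baselines follow
  the conventional pairings (balanced random + PEX for the microcircuit,
  round robin + PEX for the multi-area model).

What passing at this scale does and does not show: the generators
emulate the *topology class* (layered clustering, modularity) and the
traffic regime (steady tonic activity, per-step exchange), not the
original models' parameter tables, degree distributions (~2 000 inputs
per neuron there vs 50 here), or emergent dynamics. Count-based
reductions transfer qualitatively; anything measured in seconds does not
exist here at all.

## Known limitations

* Virtual processes execute sequentially; there is no real message
  passing, no overlap of computation and communication, and therefore no
  wall-clock claim of any kind.
* The abstract cost of NBX's barrier (counted as $P$ zero-byte messages)
  is a bookkeeping convention, not a performance model.
* No plasticity; allocation is static over a run.
* Single-vertex FM moves only (no pair swaps); recursive-bisection
  vs direct k-way trade-offs are not explored.
* `remote_spikes` (per firing event) saturates at realistic densities;
  use `remote_spike_messages` for allocation comparisons.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
preset, runs all allocations and both patterns, asserts raster equality
between compared cells, and writes the partitioner imbalance and the
four reduction metrics as JSON. The test suite
(`testthat::test_dir("tests/testthat")`) contains the property and
oracle checks: brute-force metric equality on 200 random hypergraphs,
exhaustive-optimum sanity for the partitioner, bit-identical rasters
across 18 strategy/pattern/P cells, exact PEX/NBX accounting over 1 000
randomised exchanges, and first-order convergence of the integrator.
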