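---
title: "Calling TADs by graph embedding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling TADs by graph embedding: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictad)
```

## The problem

Topologically associating domains (TADs) are contiguous genomic intervals in
which chromatin contacts are markedly enriched relative to their
surroundings; their boundaries coincide with CTCF/cohesin binding and
insulate enhancer–promoter communication. Given a single-chromosome Hi-C
contact matrix at a fixed bin resolution, `hictad` partitions the chromosome
into an ordered, non-overlapping set of such domains.

The method treats the contact matrix as a weighted graph — bins are nodes,
interaction frequencies edge weights — embeds the graph in a low-dimensional
Euclidean space with a closed-form matrix factorization, and density-clusters
the embedded bins. Bins whose contact profiles are alike land close together
in embedding space; maximal genomic runs of co-clustered bins become domain
calls.

## Pipeline

1. **Partition.** A chromosome of `n_bins` bins is split into
   `ns = ceiling(n_bins / t)` windows of core size `p = ceiling(n_bins / ns)`
   (default threshold `t = 5000` bins), so full-chromosome matrices need
   never be held in the quadratic-cost stages at once. Every window after
   the first is extended left/up by `q = 3` Mb of bins borrowed from its
   predecessor; a domain straddling a core boundary is therefore seen whole
   by at least one window.
2. **Smoothing.** Each extracted sub-matrix is convolved with an isotropic
   2-D Gaussian (default `sigma = 1` bin, kernel truncated at 4 sigma,
   half-sample reflect boundary). This suppresses speckle noise while
   reinforcing the diagonal block signal.
3. **Graph and embedding.** The smoothed sub-matrix becomes a weighted
   graph; the diagonal is zeroed (self-contacts carry no pairwise proximity
   and would dominate degrees and volume; a flag retains them). The NetMF
   embedding factorizes the closed-form DeepWalk matrix
   `chi = vol(G) / (b T) * (sum_{r=1}^{T} (D^-1 A)^r) D^-1`
   with context window `T` and negative-sampling constant `b`: the
   shifted-PPMI floor `max(chi, 1)` is applied, logs are taken elementwise,
   and the resulting matrix is factorized by truncated SVD; node vectors are
   `U sqrt(Sigma)`. For small windows the matrix powers are computed
   directly ("exact-small"); for large graphs or windows the normalized
   adjacency `D^-1/2 A D^-1/2` is eigen-truncated to `h` pairs and the same
   expression is assembled from the eigenbasis ("approx-large"), which is
   exact when `h` equals the number of active nodes.
4. **Clustering.** Embedding rows are clustered with HDBSCAN (Euclidean
   metric): core distances at `min_samples`, mutual reachability
   `max(core_p, core_q, d(p, q))`, minimum spanning tree, single-linkage
   hierarchy, condensed tree at `min_cluster_size`, excess-of-mass cluster
   extraction; label `-1` is noise. Zero-degree bins never enter the
   embedding and are forced to noise.
5. **Runs and size filter.** Clusters live in embedding space and need not
   be genomically contiguous, but TADs are intervals: each maximal run of
   consecutive bins sharing a non-noise label becomes one candidate, and
   candidates outside the closed 100 Kb – 5 Mb range — the typical mammalian
   TAD span — are discarded. The filter is applied per run, after
   run-splitting.
6. **Stitching.** Candidates from adjacent windows can duplicate or
   contradict each other inside the overlap (Q) region. Both sides'
   Q-intersecting candidates are scored with the TAD-quality score
   `TQ = IntraIF - InterIF` (mean contact over same-domain bin pairs minus
   mean contact over cross-domain pairs) after clipping to the Q region; the
   side with the higher TQ keeps its full intervals, ties go to the current
   window, and a side with no Q candidates concedes vacuously. Any residual
   overlap after the Q pass drops the later window's interval — the earlier
   call already survived a TQ comparison, and the rule gives a deterministic
   total order. The final set is sorted and non-overlapping.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `t` | 5000 | bins | largest sub-matrix the dense stages should see |
| `q_bp` | 3e6 | bp | overlap extension; `q_bins = ceiling(q_bp / resolution)` so the extension never falls short of 3 Mb |
| `sigma` | 1 | bins | smooths over immediate neighbors only at 5–40 Kb resolutions; 0 disables |
| `dim` (`e`) | 455 | — | embedding width; clamped to `min(e, m_active - 1, rank)` on small windows |
| `window` (`T`) | 2 | — | skip-gram context; the exact path is used up to `T = 4` |
| `neg` (`b`) | 1 | — | negative-sampling constant |
| `rank` (`h`) | 256 | — | eigenpairs kept on the approximate path |
| `min_cluster_size` | 5 | bins | lets a 100 Kb domain (10 bins at 10 Kb) survive run-splitting |
| size bounds | 100 Kb – 5 Mb | bp | typical mammalian TAD sizes; closed bounds |

The context window, negative-sampling constant and eigen rank are
declared defaults of this implementation (mirroring common NetMF practice),
not values with an external provenance; the embedding width and the
partition/overlap/size constants follow the published configuration.

## Numerical choices

* **SVD via symmetric eigendecomposition.** The log-shifted matrix is
  symmetric by construction, so its SVD is assembled from `eigen(...,
  symmetric = TRUE)` (`sigma = |lambda|`, `u = sign(lambda) v`), ordered by
  `|lambda|` with the positive eigenvalue first on magnitude ties. LAPACK's
  general SVD may return any orthogonal basis of a degenerate singular
  subspace; the eigen route is deterministic and matches hand calculations
  on small symmetric matrices. Each singular vector's sign is then fixed by
  making its largest-magnitude component positive (first index on ties).
  Reflections preserve pairwise distances, so clustering is sign-stable
  either way; the convention only pins down bit-reproducibility.
* **Zero-height merges are pass-through.** Duplicate points in embedding
  space merge at distance 0, i.e. density `1/0`; treating such merges as
  cluster splits would inject infinite stabilities. They are instead treated
  as one density peak: the cluster continues through both children. A
  consequence is that a window of identical points yields one cluster.
* **Root fallback.** Excess-of-mass selection never selects the root
  cluster; if no split ever produced two children of at least
  `min_cluster_size` points, the root is selected instead so a homogeneous
  window yields one cluster rather than all noise.
* **TQ conventions.** Pairs with a bin outside every TAD contribute to
  neither mean; an empty pair set contributes 0. Candidates are clipped to
  the Q region before scoring so the comparison stays local to the disputed
  bins (scoring full intervals would let contacts far outside the overlap
  decide it).
* **MoC floor.** The concordance statistic
  `(sum F_ij^2 / (|P_i||Q_j|) - 1) / (sqrt(N_P N_Q) - 1)` assumes complete
  partitions; for domain sets with gaps the raw value can dip marginally
  below zero, and it is floored at 0 (which already means "fully
  discordant"). Both-single-domain comparisons are defined as 1.
* **Adjusted R².** At each genomic distance the contact pairs are grouped by
  the domain containing *both* endpoints; straddling pairs and pairs outside
  every domain form one background group per distance, and the group mean is
  taken over pairs at that same distance (not pooled across distances —
  pooling would mix the distance decay into the residual). `N_t` counts
  domains at least the distance long, in bp. The statistic is reported as
  missing when total variance is zero or `N - N_t - 1 <= 0`.
* **Degenerate inputs.** All-zero windows ("empty graphs") are skipped and
  yield no candidates; matrices smaller than `min_cluster_size` bins come
  back all-noise; `NaN` cells read from dumps are zeros (unmappable bins are
  conventionally empty, and the smoothing and degree computations need
  finite values); asymmetric dense input is stored as `(M + t(M)) / 2`.

## The synthetic generator

Real benchmark matrices are large downloads; `simulate_hic()` generates the
canonical Hi-C phenotype instead, with known truth. Domains of
250–1750 Kb (the typical size range of mammalian TADs) tile the chromosome
with occasional 1–5-bin gaps (`gap_prob = 0.1`); the expected contact is
`beta * exp(-|i - j| / L)` — `beta = 10`, decay scale `L = 60` bins, i.e.
600 Kb at 10 Kb, typical of mammalian distance-decay at the TAD scale —
multiplied by `gamma = 4` when both bins share a domain; observed counts are
Poisson draws plus folded-normal noise scaled by `nu` (default 1), then
symmetrized. These defaults are fixed study conditions, chosen once as
realistic for the matrices the caller targets.

```{r simulate}
sim <- simulate_hic(n_bins = 300, seed = 4)
sim$cm
tads <- call_tads(sim$cm)
nrow(tads)
moc(tads, sim$truth)
```

What the generator does *not* emulate: loops and corner peaks, A/B
compartment plaids, nested (hierarchical) domains, unmappable-bin gaps, and
coverage biases that ICE/KR balancing corrects in real data. Passing tests
on these matrices therefore show that the pipeline recovers block-diagonal
enrichment on a decaying background under Poisson noise — not that it
handles every artifact of a real experiment.

## Problem sizes and runtime

The package is validated desk-scale: fuzzed partition plans to 20 000 bins,
embedding oracles on graphs of up to 12 nodes with windows up to 4,
clustering fixtures of ~100 points, and end-to-end synthetic runs of 600
bins (single window) and 1200 bins (whole-matrix vs. three partitioned
windows, coverage Jaccard ≥ 0.8). These sizes keep the full suite under a
minute while exercising every code path, including stitching; the same code
scales to real chromosomes because each window is bounded by `t + q_bins`
bins.

## Known limitations

* Dense in-memory storage: a 25 000-bin chromosome at 10 Kb costs ~5 GB as
  a dense double matrix. The partition bounds the *processing* cost but not
  the input storage; a sparse backend behind the same contract would be the
  natural extension.
* One chromosome per call; a wrapper can loop over chromosomes.
* No nested/hierarchical TAD output: each bin belongs to at most one call.
* HDBSCAN parameters (`min_cluster_size`, `min_samples`) interact with
  resolution; at 40 Kb a 100 Kb domain spans only 2–3 bins and cannot form
  a cluster of 5 — lower `min_cluster_size` accordingly.
* The caller is deterministic end to end; only `simulate_hic()` consumes a
  seed.
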