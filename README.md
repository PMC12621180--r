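# endoCaNet

Network analysis of agonist-evoked Ca²⁺ signaling in the vascular
endothelium. Endothelial cells imaged *en face* respond to agonists such
as acetylcholine (ACh) and bradykinin with stochastic Ca²⁺ transients;
which cells respond, how strongly neighbouring activity couples them, and
whether stimulus intensity is encoded in event **frequency** (venous
endothelium) or event **amplitude** (arterial endothelium) are questions
about the tissue as a network. endoCaNet takes per-cell F/F₀ fluorescence
traces and an integer-labelled cell mask and turns them into that network
analysis, for researchers working with endothelial (or other epithelial
sheet) Ca²⁺ imaging.

The pipeline:

* **Event detection** — Savitzky–Golay smoothing (21 point, 3rd order),
  automatic 10-s lowest-activity baseline, 5×SD threshold, and a
  least-squares exponentially modified Gaussian (EMG) fit per transient
  giving amplitude, rise time, fall time and FDHM.
* **Tissue graph** — generalized Voronoi expansion of the cell mask;
  cells whose expanded boundaries touch are neighbours; field-edge cells
  flagged by a concave hull and excluded from analysis.
* **Responder communities** — top 20% of cells by response frequency;
  communities as connected components of the responder subgraph; degree
  of clustering and clustering coefficient against a 100-fold label
  permutation null.
* **Centrality** — betweenness, eigenvector centrality, eigengap-based
  local influence (L2 norm over the leading eigenvectors); enrichment of
  multisensitive cells against permutation nulls.
* **Neighbour influence** — case–control estimate of P(event | k active
  neighbours) in a 3×median-FDHM window, split by functional cluster,
  against a temporal permutation null that preserves per-cell event
  counts.
* **Cross-correlation** — lagged, segmented, demeaned-normalized
  coefficients in [0, 1]; per-node 75th-percentile connectivity within
  and between agonist networks.
* **Dose–response** — 4-parameter logistic and log-Gaussian bell fits,
  EC50/EC25, frequency- vs amplitude-encoding classification, and linear
  regression of Ca²⁺ metrics against vessel relaxation.
* **Synthetic tissue generator** — tessellated sheets, clustered
  agonist-sensitivity maps with bridge-placed multisensitive cells, and
  neighbour-coupled stochastic transients with exported ground truth.

The hazard model behind the generator is
λᵢ(t) = base + sᵢ·r(C)·(1 + β·kᵢ(t)), with sᵢ the cell's sensitivity to
the applied agonist, r(C) the concentration drive (4PL of log C for the
venous rate; bell-shaped rate plus 4PL amplitude for arterial mode) and
kᵢ(t) the number of neighbours with an event onset in the preceding
coupling window. See the methods vignette
(`vignettes/endothelial-calcium-networks.Rmd`) for every model detail and
design decision.

## Worked example

Simulate a venous sheet, detect events, and test whether the top
responders cluster spatially:

```r
library(endoCaNet)

cfg <- simulationConfig(nCells = 120, duration = 180, rngSeed = 42)
sim <- simulateTissue(cfg, agonist = "ACh", concentration = 1e-6)
sim$graph
#> TissueGraph: 120 cells, 316 edges, 40 boundary / 80 interior
graphStats(sim$graph)
#>      statistic        mean        sem  n
#> 1    neighbors    5.962500  0.1044027 80
#> 2         area 2087.075000 35.3882569 80
#> 3 aspect_ratio    1.200438  0.0144821 80

ev <- detectEvents(sim$traces)
head(ev[, c("cell_id", "peak_time", "amplitude", "fdhm")], 3)
#>   cell_id peak_time amplitude fdhm
#> 1       2      81.8     0.880 2.49
#> 2       6      23.3     0.808 1.76
#> 3      11     109.7     1.227 2.65

interior <- interiorCells(sim$graph)
summ <- summarizeCells(ev, interior, exposure = c(20, 180))
resp <- selectTopResponders(summ, 0.2)
met <- communityMetrics(sim$graph, findCommunities(sim$graph, resp))
pn <- clusteringPermutationNull(sim$graph, resp, nPerm = 100, seed = 1)
pn$degree_of_clustering[c("observed", "nullMean", "percentile")]
#> $observed
#> [1] 3.142857
#> $nullMean
#> [1] 1.465546
#> $percentile
#> [1] 100
```

Interior cells average ~6 neighbours, as expected for a planar
tessellation. The 16 top responders form one 14-cell community plus 2
isolated cells; their degree of clustering (3.14 responder–responder
connections per community member) sits at the 100th percentile of the
100-permutation null (null mean 1.47) — the responders are spatially
clustered, not randomly scattered, because the generator grew a clustered
sensitivity map.

`runPipeline(mask, list(ACh = tracesA, BK = tracesB), runConfig(...))`
chains every stage (detection → graph → communities → centrality →
influence → cross-correlation) and writes all tables when given an
output directory.

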