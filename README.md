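# TemperatureIndices

Temperature-based topological indices for molecular graphs, with explicit
carbon-nanocone construction, benzenoid closed forms, and exponent
optimisation for structure–property correlation.

## The problem

Quantitative structure–property relationship (QSPR) modelling predicts
physicochemical properties of molecules from graph-theoretic descriptors of
their skeletal structure. One family of descriptors builds on the
*temperature* of a vertex $b$ in an $n$-vertex connected graph,

$$T_b = \frac{d_b}{\,n - d_b\,},$$

and sums a symmetric map $\psi(T_u, T_v)$ over the edges:
$\vartheta_t = \sum_{uv \in E} \psi(T_u, T_v)$. The package is for
researchers in chemical graph theory and cheminformatics who need to

* evaluate the thirteen named temperature indices (HT1, HT2, ST, PT, RPT,
  AGT, GAT, FT, TSO, mTSO, HT, RRPT, ABCT) and the parametric families
  $T^\sigma_1 = \sum (T_u+T_v)^\sigma$, $T^\sigma_2 = \sum (T_u T_v)^\sigma$
  and the general F-temperature index
  $T_\beta = \sum (T_u^\beta + T_v^\beta)$ on arbitrary graphs or edge-list
  files;
* construct carbon nanocones $CNC_k[n]$ explicitly and evaluate their
  indices through the three-class temperature edge partition (closed form);
* evaluate benzenoid systems directly from vertex/hexagon/inlet counts
  $(v, p, k)$ via $n_{22} = v-2p-k+2$, $n_{23} = 2k$, $n_{33} = 3p-k-3$;
* find the exponent $\beta$ at which $T_\beta$ is maximally
  Pearson-correlated with the total $\pi$-electron energy $E_\pi$ of the
  bundled 30 lower benzenoid hydrocarbons, with OLS fit diagnostics.

## Worked example

```r
library(TemperatureIndices)

## benzene is the 6-cycle: every temperature is 2/(6-2) = 1/2
benzene <- cycleGraph(6)
evaluateIndex(benzene, indexSpec("FT"))
#> [1] 3

## a carbon nanocone and its three-class partition
nanoconeEdgePartition(3, 1)
#> TemperatureEdgeClasses: 3 class(es), 15 edge(s)
#>   (1/5, 1/5) x 3
#>   (1/5, 1/3) x 6
#>   (1/3, 1/3) x 6
nanoconeTable(3:4, 1:2, indices = c("HT1", "ST", "FT"))
#>   k n  HT1     ST   FT
#> 1 3 1 4.85  20.31 2.48
#> 2 3 2 1.89  76.00 0.96
#> 3 4 1 3.15  32.35 1.60
#> 4 4 2 1.34 118.68 0.68

## the exponent scan over the 30 lower benzenoids
bh <- lowerBenzenoids()
scan <- rhoCurve(bh, "F_GENERAL", scanConfig(-1, 1, 1e-4))
scan
#> ScanResult: F_GENERAL (as_printed mode), 20000 grid points
#>   beta* = -0.0918, rho* = 0.997167737
```

The partition counts say that $CNC_3[1]$ has 3 edges between boundary
degree-2 vertices, 6 boundary–interior edges and 6 interior edges; the
table rows are the two-decimal index values for each $(k, n)$. The scan
output is the exponent at which the F-temperature index correlates most
strongly with $E_\pi$ over the dataset (correlation 0.9972 — note that the
curve is very flat near the optimum; see the vignette for what does and
does not reproduce the published statistics for this dataset, and for the
dataset's transcription audit).

A thin command-line interface over the same functions is installed at
`inst/cli/tempindices.R` (`index`, `nanocone`, `nanocone-table`,
`benzenoid-table`, `scan`, `fit`, `export-nanocone`).

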