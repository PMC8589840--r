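# rtgloh

Sterile yeast hybrids cannot complete meiosis, but a cell that initiates
meiosis and is then returned to rich medium — *return-to-growth* (RTG) —
repairs its Spo11-induced double-strand breaks (DSBs), buds mitotically, and
segregates its recombined chromatids without a second round of replication.
The result is a mother/daughter pair of diploids whose genomes carry
regions of **loss of heterozygosity (LOH)**: terminal blocks from single
crossovers (CO) and interstitial tracts from gene conversions (NCO) or
double crossovers. RTG thereby shuffles hybrid genomes that sexual
reproduction cannot.

`rtgloh` is an R package for simulating and analysing this process. It is
aimed at yeast geneticists and genome-evolution researchers who want to

* **simulate** RTG mother/daughter genotype pairs with full ground truth —
  hotspot-weighted Poisson DSBs, mismatch-repair anti-recombination
  (per-mismatch rejection probability `rho`, switched off by an `msh2_null`
  flag), CO/NCO resolution, and mitotic-like 2+2 chromatid segregation;
* **call LOH segments** from per-marker genotype tables
  (`HET`/`HOM_P1`/`HOM_P2`/`MISSING`), with single-marker events kept,
  subtelomeric masking, interstitial/terminal classification, and the two
  coordinate systems used in the field (`first/last` = outer segment
  markers; `start/end` = midpoints to the adjacent heterozygous markers);
* **test breakpoint–hotspot association** with a permutation framework
  (observed = number of breakpoint regions hitting ≥ 1 hotspot; null =
  per-chromosome uniform re-placement; `p = (1 + #{null ≥ obs})/(1 +
  ntimes)`), a local Z profile over shifts spanning `W = 10·S_m` in steps of
  `T = S_m/2`, and relative hotspot intensities `RI = H / max(H)` compared
  between overlapping and non-overlapping hotspots at several paddings;
* **quantify LOH rates** from the URA3-loss assay:
  `R_T = 100·CFU_5-FOA / CFU_YPD`, the LOH ratio `R_T6/R_T0`, the LOH
  difference `R_T6 − R_T0`, and their correlation with meiotic progression;
* **map QTLs** from LOH genotypes: single-marker regression LOD scores
  `LOD = (n/2)·log10(RSS0/RSS1)`, genome-wide thresholds from 1000
  phenotype permutations (95th percentile of null maxima), LOD-drop support
  intervals, growth classification of normalised doubling times
  `D_r = log2(D) − log2(D_control)`, and best-/worse-parent heterosis
  calls.

Everything is tibble-first: functions accept and return data frames, chain
with the pipe, and fitted objects have `tidy()`/`glance()` methods and
`autoplot()`s.

## Worked example

Simulate one RTG pair on a 4-chromosome toy genome and call its LOH:

```r
library(rtgloh)

layout <- toy_layout(4, 500000)                       # 2 Mb, 4 centromeres
map    <- simulate_marker_map(layout, 0.001, seed = 1) # ~2,000 markers
hs     <- simulate_hotspots(layout, seed = 2)
pair   <- simulate_rtg_pair(map, layout, hs, sim_config(), seed = 3)

segs <- call_loh(dplyr::bind_rows(pair$mother, pair$daughter), map, layout)
segs
#> # A tibble: 5 × 9
#>   clone          chrom parent  first   last   start     end n_markers class
#>   <chr>          <chr> <chr>   <dbl>  <dbl>   <dbl>   <dbl>     <dbl> <chr>
#> 1 pair1_daughter chr02 P2     323305 429863 323060. 431532.       105 interstit…
#> 2 pair1_daughter chr03 P1     206436 206436 205308  206775          1 interstit…
#> 3 pair1_daughter chr04 P2      62259  62259  60307   63132.         1 interstit…
#> 4 pair1_mother   chr02 P1     323305 411861 323060. 412766.        92 interstit…
#> 5 pair1_mother   chr02 P1     415253 429863 414874. 431532.         9 interstit…
```

The daughter's 105-marker tract on chr02 mirrors the mother's two P1
segments across the same interval — the reciprocal footprint of a double
crossover — while the two single-marker events are gene conversions (kept
deliberately: no minimum-marker filter is applied). Six markers in this
pair deviate from the 2:2 parental dosage
(`nrow(reciprocity(pair$mother, pair$daughter))`), exactly the conversion
footprint recorded in `pair$nonreciprocal`.

```r
summarize_loh(segs, map, layout)
#> # A tibble: 2 × 8
#>   clone    n_interstitial n_terminal n_whole_chromosome frac_markers_loh ...
#> 1 pair1_d…              3          0                  0           0.0583
#> 2 pair1_m…              2          0                  0           0.0550
```

Downstream, `breakpoint_regions()` + `permutation_overlap_test()` test
whether those breakpoints sit in DSB hotspots, `loh_rate()` +
`loh_metrics()` process CFU count tables, and `encode_genotypes()` +
`map_qtl()` scan growth phenotypes for linked loci (see the vignette in
`vignettes/` for the full tour and the modelling details).

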