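# ctcscope

Image-cytometry enumeration and morphological characterization of
circulating tumor cells (CTCs) and large tumor-derived extracellular
vesicles (tdEVs) in CellSearch-style fluorescence cartridge images, for
researchers analyzing EpCAM-enriched blood fractions in metastatic
prostate cancer and similar settings.

A cartridge is scanned as frames of four co-registered fluorescence
channels — DAPI (DNA), PE (cytokeratin, CK), APC (CD45), FITC. The
pipeline follows the "full detection" paradigm:

1. **Segment** every fluorescent object per channel (triangle threshold
   with a background + 3σ floor, minimum area 4 px) and **merge** channel
   components into events (transitive overlap within a 1-px dilation;
   CD45/FITC never seed events).
2. **Measure** each event: mean/max intensity, area, eccentricity,
   perimeter (boundary-pixel count), perimeter-to-area and size per
   channel, plus the CK–DAPI overlay fraction |CK ∩ DAPI| / |CK|.
3. **Gate** with linear threshold conjunctions. An event is a **CTC** when

   mean CD45 ≤ 5 AU, mean DAPI > 45 AU, mean CK > 60 AU,
   16 < CK size ≤ 400 µm², CK overlay with DAPI > 0.2,
   mean marker 1 ≤ 5 AU, mean marker 2 ≤ 5 AU

   and a **tdEV** when

   mean CD45 ≤ 5, mean DAPI ≤ 5, mean CK > 60, max CK > 90 AU,
   CK area ≤ 150 µm², eccentricity ≤ 0.8, perimeter > 5 px,
   perimeter/area ≤ 1, CK size ≤ 150 µm², markers ≤ 5 AU.

   `>` is strict, `≤` inclusive, exactly as printed in the shipped gate
   file (`inst/extdata/gates/table1.yaml`). Review annotations exclude
   artifacts from the corrected CTC count.
4. **Subclassify** confirmed CTCs into six morphological classes
   (clusters, pretty, heterogeneous CK, cleaved CK, fragmented DNA/CK,
   cleaved CK + fragmented DNA) by a first-match cascade over measurable
   evidence: intact-nuclei count, CK coefficient of variation, shape
   irregularity (1 − solidity), CK speckling and DNA fragment count.
5. **Compare cohorts**: Mann–Whitney U with mean ranks (tie-corrected
   normal approximation, exact enumeration for groups ≤ 8), Spearman rank
   correlation, Pearson chi-square on 2×2 tables (no continuity
   correction), paired t tests, and the standard reporting bins
   (CTC 0 / 1–4 / ≥ 5; tdEV ≤ 50 / > 50).

Because the underlying patient images are not publicly deposited, the
package ships a synthetic-cartridge generator that renders all object
archetypes with planted, gate-derived ground truth, and a shared-latent
zero-inflated log-normal cohort simulator calibrated to the published
stage-level summaries (median CTC 1 vs 3.5, median tdEV 11 vs 49.5,
Spearman ρ ≈ 0.84–0.92). See the methods vignette
(`vignettes/ctc-tdev-enumeration.Rmd`) for the models and every numeric
choice.

## Worked example

```r
library(ctcscope)

gen <- generateCartridge(cartridgeConfig(
  frames = 2, dim = c(220, 220),
  objectMix = c(CTC_PRETTY = 2, CTC_CLUSTER = 1, CTC_CLEAVED = 1,
                TDEV = 10, LEUKOCYTE = 15, DEBRIS = 2)), seed = 7)
table(gen$groundTruth$expected_gate)
#>     CTC NEITHER    TDEV
#>       4      17      10

res <- runPipeline(gen$stack, verbose = FALSE)
res$counts
#>           ctc_accept          tdev_accept ctc_accept_corrected
#>                    4                   10                    4
table(res$classified$subclass)
#> CLEAVED_CK    CLUSTER     PRETTY
#>          1          1          2
```

The four planted CTCs (two intact, one cluster, one apoptotic
speckled-CK cell) and all ten tdEVs are recovered and labeled exactly;
the 15 leukocytes and 2 debris flecks fall outside both gates. On the
cohort side:

```r
d <- simulateCohort(nPerStage = 200, seed = 1)
aggregate(cbind(ctc, tdev) ~ stage, d, median)
#>   stage ctc tdev
#> 1  CNPC   1 11.5
#> 2  CRPC   3 50.5

rep <- cohortReport(d)
subset(rep$tests, test == "mann_whitney" & marker == "ctc")
#>           test marker statistic            p                               detail
#> 3 mann_whitney    ctc     12920 3.639622e-10 mean ranks 165.10 vs 235.90 (normal)
```

Castration-resistant patients carry higher CTC and tdEV loads than
castration-naive ones; at n = 200 per stage the Mann–Whitney test resolves
the difference far below p = 0.05 (the published cohorts, at 104 vs 66
patients, sit near p ≈ 0.01).

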