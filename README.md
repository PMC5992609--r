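# pdxresist

Identification and classification of chemoresistance-linked somatic
mutations in serially treated patient-derived xenografts (PDXs), from
per-sample allele counts.

When a PDX is cycled through repeated rounds of one chemotherapy until it
relapses faster, the adapted tumor is operationally resistant. Comparing
read-count evidence between the patient's germline sample, the parental PDX
and each treatment-adapted PDX reveals mutations that appeared, disappeared
or shifted in allele frequency under treatment — candidate drivers of
adaptation. `pdxresist` is aimed at analysts working with matched
tumor-lineage sequencing who need those calls to be reproducible and
statistically explicit.

## The method

For a variant with `alt` mutant reads out of `total`, AF = `alt/total`.
Calling requires `total >= 20` and `alt >= 2` (frameshifts: `alt >= 2` at
any depth); absence is certified only by `alt = 0` at `total >= 20`. After
removing dbSNP-common variants (MAF > 1%), non-impactful consequences and
anything with germline support, each (somatic variant, adapted arm) pair
gets exactly one status:

- **de novo** — called in the adapted PDX, certified absent from the parental;
- **completely depleted** — the mirror image;
- **in common** — ≥ 1 mutant read at ≥ 20× in both; a two-sided Fisher exact
  test on the 2×2 mutant/reference table, BH-adjusted within the arm, calls
  the mutation **enriched** (q < 0.05, ΔAF ≥ +0.10), **partially depleted**
  (q < 0.05, ΔAF ≤ −0.10) or **unchanged**;
- **undetermined** — insufficient evidence either way.

Downstream stages: consensus deleteriousness (frameshift/nonsense/splice, or
missense damaging by both SIFT and PolyPhen-2), a pooled two-proportion
z-test contrasting deleterious fractions between categories, one-sided
Fisher pathway over-representation with FDR control, a 1000-random-gene-set
Mann–Whitney null for negative expression–IC50 correlations across cell-line
panels, and a deep-amplicon per-base error model
(rate = pooled non-reference fraction at unaffected positions) defining the
detection limit for low-frequency verification. Seeded generators with
planted ground truth (`simulate_variant_cohort`, `simulate_expression_drug`,
`simulate_amplicon_pileup`) make every stage testable without external data.
See the vignette in `vignettes/` for the model, parameter defaults and
design rationale.

## Worked example

```r
library(pdxresist)

cfg <- simulation_config(seed = 42)          # 80x exome cohort, 4 arms
sim <- simulate_variant_cohort(cfg)

somatic <- apply_exclusion_filters(sim$table)
somatic
#> variant_table: 187 variants, 1122 observations, 4 adapted arms

records <- classify_cohort(somatic)          # Fisher + BH + >=10% rule
summarize_overlap(records)
#> cross-arm summary over 4 arms
#>   arm   common_unchanged completely_depleted de_novo enriched partially_depleted
#> 1 cisp…               39                  44      65       22                 17
#> 2 fluo…               39                  43      65       21                 18
#> 3 lurb…               40                  46      64       20                 16
#> 4 olap…               40                  44      65       20                 18

imp <- deleterious_by_category(records, sim$predictions)
imp$fractions
#>   status              n_variants n_deleterious fraction
#> 1 common_unchanged            43            15    0.349
#> 2 completely_depleted         48            24    0.5
#> 3 de_novo                     65            39    0.6
#> 4 enriched                    22            15    0.682
#> 5 partially_depleted          19             6    0.316
#> 6 undetermined                 2             0    0
sprintf("enriched vs partially depleted: z = %.2f, p = %.3f",
        imp$test$z, imp$test$p)
#> "enriched vs partially depleted: z = 2.34, p = 0.019"
```

The cohort was simulated with 64/43/22/19 planted de novo / completely
depleted / enriched / partially depleted mutations per arm: at 80× coverage
the classifier recovers nearly all of them, with the stochastic shortfall
landing in `undetermined` or `common_unchanged`, and the deleterious
fraction is highest among enriched mutations, as planted. The full pipeline
(filters → classification → impact → overlap → pathways → drug
correlations), driven by one config list or YAML file, is `run_pipeline()`;
it writes per-stage TSVs and a JSON summary.

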