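# hemiasym

Hemispheric asymmetry analysis of weighted structural brain networks.

Diffusion-tensor tractography turns a brain into a weighted graph:
parcellation regions are nodes, white-matter connections are edges, and
the fractional anisotropy (FA) of each connection is its weight. This
package quantifies how the *topology* of that graph differs between the
left and right hemispheres — and how that lateralization differs between
a patient group and controls. It is aimed at researchers analyzing
two-group DTI connectome studies (the motivating use case is bipolar
disorder versus controls) and at methodologists who want a fully
testable, simulation-backed reference implementation of this analysis.

## What it computes

For each subject, from whole-brain fiber-number (FN) and FA matrices:

1. **Hemispheric networks** — keep edges with FN strictly greater than 3
   (tractography-noise filter), drop all inter-hemispheric connections,
   yielding two weighted 45 × 45 networks under the packaged AAL-90
   parcellation (any parcellation with equal hemispheres works).
2. **Graph metrics** — weighted clustering coefficient Cp (Onnela form),
   characteristic path length Lp, global efficiency Eg, local efficiency
   Eloc, and nodal efficiency Enodal(i), with distance = 1/FA.
3. **Small-world normalization** — γ = Cp/C_rand, λ = Lp/L_rand,
   σ = γ/λ against 100 degree- and weight-matched rewired null networks.
4. **Asymmetry score** — for any property X,

   AS(X) = 100 · [X(R) − X(L)] / [X(R) + X(L)]

   positive = rightward, negative = leftward lateralization.
5. **Statistics** — repeated-measures GLM (hemisphere within subject,
   group between subjects, group × hemisphere interaction; age, gender,
   age × gender covariates), one-sample t and ANCOVA on asymmetry
   scores, Bonferroni correction across the 45 regional tests, and
   partial Pearson/Spearman correlations between regional asymmetry and
   clinical scores (YMRS, HAMD) in patients.

A synthetic cohort generator (`synthetic_spec()` / `generate_cohort()`)
emulates the whole statistical structure of such a study — mirror-
symmetric small-world templates, injectable hemispheric/group/nodal
effects, spurious low-fiber-count edges, clinical scores linked to
regional asymmetry — so every stage is validated against known ground
truth.

## A worked example

```r
library(hemiasym)

# a cohort of 49 patients and 61 controls in which controls (only)
# carry a 15% rightward FA offset
spec   <- synthetic_spec(delta_right_control = 0.15, seed = 7)
cohort <- generate_cohort(spec)

metrics <- cohort_metrics(cohort$connectomes, cohort$parcellation,
                          threshold = 3, n_nulls = 0)
asym    <- cohort_asymmetry(metrics)
stats   <- run_statistics(metrics, asym, cohort$metadata, alpha = 0.05)

stats$glm_global[stats$glm_global$effect == "group_x_hemisphere",
                 c("metric", "value", "df1", "df2", "p")]
#>    metric     value df1 df2          p
#> 3      Eg 26903.176   1 105 2.239e-128
#> 6    Eloc 23864.739   1 105 1.179e-125
#> 9      Cp     9.351   1 105  2.828e-03
#> 12     Lp 22582.977   1 105 2.111e-124
```

The injected rightward control asymmetry produces a very large
group × hemisphere interaction F for the efficiency-type metrics (the
per-edge noise is small relative to a 15% hemispheric offset). The
asymmetry scores show where it comes from:

```r
as_eg <- asym[asym$metric == "Eg", ]
nc <- cohort$metadata$subject_id[cohort$metadata$group == "NC"]
mean(as_eg$AS[as_eg$subject_id %in% nc])    # controls:  6.93 (rightward)
mean(as_eg$AS[!as_eg$subject_id %in% nc])   # patients: -0.01 (no asymmetry)
```

Controls sit near the theoretical value 100 × 0.15 / 2.15 ≈ 6.98 while
patients are symmetric, and the one-sample t on AS(Eg) is significant in
controls (t(60) = 238.4, p ≈ 5e-91) but not in patients
(t(48) = −0.41, p = 0.69).

The same run as a single reproducible command, with all report tables
written to disk:

```r
run_pipeline(run_config(out_dir = "run1", spec = spec,
                        n_nulls = 100, seed = 7))
```

A command-line front end wrapping these functions (subcommands
`simulate`, `build`, `metrics`, `asymmetry`, `stats`, `run`,
`fixtures`) is installed at `inst/cli/hemiasym.R`.

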