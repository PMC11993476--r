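# adcscreen

Nomination of antibody–drug conjugate (ADC) targets and payloads from
paired tumor / normal-adjacent-tissue (NAT) proteomics, for preclinical
oncology groups screening cell-surface antigens — plus the downstream
quantifications such a program needs: internalization kinetics, spatial
proximity statistics on multiplexed immunofluorescence (mIF) cell maps,
immune-fraction associations, and small clinical metrics.

## The method

A good ADC target is overexpressed in tumor, antibody-accessible on the
membrane, and near-absent across normal tissues. `adcscreen` runs that
screen as a funnel:

1. **Paired differential proteomics.** Per patient *i*, protein *j*:
   `FC_ij = log2((T_ij + ε) / (N_ij + ε))`. A two-sided paired t-test on
   log2 abundances per protein, Benjamini–Hochberg q-values over all
   tested proteins, summary log2FC as the across-patient median of
   `FC_ij`, and the top-*k* (default 20) upregulated proteins by
   q ascending.
2. **Surfaceome filter.** Case-insensitive intersection (with alias
   resolution) of the top DEPs with a membrane-protein catalog.
3. **Normal-tissue expression index.** Over 41 normal tissues annotated at
   ordinal levels, the sum of scores high = 3, medium = 2, low = 1,
   not detected = 0; range 0–123, lower = more tumor-restricted.
4. **Specificity ranking.** Candidates ranked by index ascending, ties by
   the median per-patient log2FC descending; win fractions against
   established reference targets (strict inequality) are reported.
5. **Payload screen.** DEPs passing the FDR threshold intersected with
   drug–target catalogs; only targets with approved or clinical-trial
   drugs qualify, ranked by q.

Downstream: internalization efficiency
`E(t) = (1 − MFI(t)/MFI(0)) × 100%` with an optional monoexponential fit
`E(t) = 100·p·(1 − exp(−k t))`; target-cell counts by half-open distance
band (0–50, 50–100, 100–150, 150–200 µm) from the nearest source cell;
median-split group tests and Pearson/Spearman correlations against
deconvolution outputs; IHC H-score, caliper tumor volume
(`0.5·w²·ℓ`), CIN classification (MSS and FGA ≥ 5%), and Fisher-exact
mutation-prevalence contingency.

Every pipeline input has a synthetic generator with planted ground truth
(differential effects, membrane membership, a best target with minimal
tissue index, spatial depletion, internalization plateau, immune
correlation), so each stage is tested for *recovery* against known truth.

## Worked example

```r
library(adcscreen)

cfg  <- sim_config(seed = 1)                       # 100 pairs x 200 proteins
sim  <- generate_paired_proteomics(cfg)
diff <- paired_differential_test(sim$mat)
rep  <- nominate_targets(diff,
                         generate_surfaceome(sim$truth),
                         generate_tissue_table(cfg, sim$mat$protein_ids,
                                               sim$truth$planted_best_target),
                         per_patient_log2fc(sim$mat), k = 20)
head(rep, 3)
#>   protein_id rank      q_value    log2fc nt_index specificity_median
#> 1   PROT0042    1 2.194181e-50 1.8713034        0          1.8713034
#> 2   PROT0002    2 5.066105e-51 2.0487951       29          2.0487951
#> 3   PROT0010    3 9.623596e-02 0.2191624       32          0.2191624
sim$truth$planted_best_target
#> [1] "PROT0042"
```

The winner is the planted best target: a differentially expressed membrane
protein with normal-tissue index 0 (undetected in all 41 tissues) and a
median per-patient log2FC near the planted +2 effect. Candidates below it
have detectable normal-tissue expression (index 29, 32, ...), making them
less safe targets regardless of their q-values.

```r
cv <- build_curve(generate_mfi_series(cfg))
cv
#> internalization_curve [synthetic]: plateau 39.1% (fit: p = 0.386, k = 0.0222/min)
round(cv$efficiency, 1)
#> [1]  0.0 21.0 26.3 35.7 39.1
```

The fitted internalizable fraction (38.6%) recovers the generator's
planted plateau of 40% from five noisy time points; the efficiency at
240 min (39.1%) is the empirical plateau.

An end-to-end run — `run_pipeline(pipeline_config(seed = 1))` — writes
every stage artifact (TSV/JSON) plus a `provenance.json` with the
configuration, seed, versions, and per-artifact MD5 checksums; reruns
with the same seed are bit-identical. A thin CLI over the same functions
lives at `inst/cli/adcscreen.R`
(`Rscript adcscreen.R run-all --seed 1 --out DIR`).

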