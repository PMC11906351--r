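# vdjlens

Estimate T cell and B cell fractions, immunoglobulin class switching,
germline IGH copy-number variants and segment-usage diversity from
whole-genome sequencing read depth over the TCRA, TCRB, TCRG and IGH loci
(GRCh38).

## The idea

V(D)J recombination physically deletes the DNA between the chosen V and J
segment in every T and B cell, on both alleles. In bulk WGS this produces a
read-depth dip across the receptor loci whose depth and shape encode the
lymphocyte content and the repertoire's segment usage. For a position *x* on
the locus' deletion axis, V usage *p* and J usage *q*, the expected copy
number is

    CN(x) = C_flank − a · f · F(x),      F(x) = PV(x) · QJ(x),   a = 2

where `f` is the lymphocyte fraction of all cells,
`PV(x) = Σ_{v upstream of x} p_v`, `QJ(x) = Σ_{j downstream of x} q_j`, and
`C_flank = ρ·n_t + (1−ρ)·n_g` adjusts for tumour purity ρ and local somatic
copy number n_t. vdjlens bins coverage, GC-corrects it against undeletable
baseline regions, transforms each bin's log2 read-depth ratio to a plug-in
estimate of `f·F(x)`, and fits the monotone step curve F by weighted
isotonic regression (pool-adjacent-violators) with a profiled plateau — a
convex, deterministic estimator whose plateau is `f̂` and whose step
increments are the usage vectors. At IGH, constant-gene depth steps are
decomposed the same way along the class-switch order (IgM/IgD, IgG3, IgG1,
IgA1, IgG2, IgG4, IgE, IgA2), after masking germline copy-number variants
called from the matched normal. Shannon and Jensen–Shannon statistics
summarise repertoire diversity. A forward simulator with known truth
(Poisson depth over the same copy-number model) backs every estimator with
ground-truth validation.

Intended users: anyone with WGS BAMs/CRAMs or pre-extracted coverage who
wants immune-cell quantification without immune sequencing — tumour
immunology, cohort genomics, or method development.

## Worked example

Simulate a blood-like sample at 30× over TCRG with a true T cell fraction of
0.15, then recover it:

```r
library(vdjlens)

locus <- load_locus_definition("TCRG")
truth <- sim_truth("TCRG", f = 0.15, depth = 30, seed = 42)
track <- simulate_coverage(truth, locus)
prof  <- ratio_profile(track, locus, gc = attr(track, "gc"))
fit   <- fit_vdj(prof, locus)
fit
#> <vdj_fit> TCRG
#>   fraction: 0.1505  (95% CI 0.1478-0.1540)
#>   bins used: 257  objective: 548

glance(fit)
#> # A tibble: 1 × 9
#>   locus fraction ci_lower ci_upper objective n_bins_used converged zero_fraction
#>   <chr>    <dbl>    <dbl>    <dbl>     <dbl>       <int> <lgl>     <lgl>
#> 1 TCRG     0.151    0.148    0.154      548.         257 TRUE      FALSE

head(tidy(fit), 4)
#> # A tibble: 4 × 5
#>   locus segment kind  usage selected
#>   <chr> <chr>   <chr> <dbl> <lgl>
#> 1 TCRG  TRGV9   V     0.125 TRUE
#> 2 TCRG  TRGV8   V     0.125 TRUE
#> 3 TCRG  TRGV5   V     0.125 TRUE
#> 4 TCRG  TRGV4   V     0.125 TRUE

shannon_diversity(fit$v_usage)
#> [1] 2.079442        # = ln 8: the simulated usage was uniform over 8 V segments
```

The fitted fraction (0.1505) recovers the simulated truth (0.15) within the
bootstrap interval, and the usage estimate is the uniform distribution the
sample was simulated with. `autoplot(prof, fit = fit, locus = locus)` draws
the RDR profile with the fitted deletion curve; `fit_class_switch()`,
`call_germline_cnv()` and `jensen_shannon_divergence()` cover the IGH
decomposition and between-sample comparisons; `run_pipeline()` orchestrates
extract → normalise → fit → report for sample sheets, and
`inst/cli/vdjlens.R` exposes the same steps as shell subcommands
(`extract-coverage`, `fit`, `fit-igh`, `cnv-germline`, `diversity`,
`simulate`, `run`).

Real alignments enter through `extract_coverage("sample.bam", locus)`
(CRAM needs `reference=`), or bring your own `samtools depth`-style TSV via
`read_coverage_table()`. The packaged segment annotation is a representative
reconstruction of the GRCh38 locus architecture; supply an IMGT-derived
table through `load_locus_definition(locus, annotation_path)` for production
use.

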