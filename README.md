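# dxlink — probabilistic record linkage of de-identified patient data using diagnosis codes

De-identified research datasets have no names, no dates of birth, no
identifiers — yet two such datasets often cover overlapping patients whose
records would be far more valuable joined. `dxlink` links patient records
across two datasets using **only binarized diagnosis codes** (ever-recorded
/ never-recorded per patient), tolerating the discrepancies that real code
data always carry: a code billed at one site and not the other, different
extraction windows, administrative noise.

## Who this is for

Biostatisticians and informaticians who hold two patient-by-code binary
matrices (registry + EHR extract, EHR + claims, two study freezes) and need
a calibrated posterior probability that record *i* in one equals record *j*
in the other — plus the tooling to benchmark that linkage: a classical
Fellegi–Sunter comparator, a ground-truthed simulator, and TPR/PPV scoring.

## The model

For aligned codes $k = 1,\dots,K$ with prevalence $\pi_{Bk}$ in dataset B
and discrepancy rates $\varepsilon_k^-$ (present in A, lost in B) and
$\varepsilon_k^+$ (absent in A, present in B), each pair accumulates the
naive-Bayes log-likelihood ratio

$$\mathcal{L}(ij)=\sum_k \mathcal{L}_k(A_k(i),B_k(j)),\qquad
\mathcal{L}_k(1,1)=\log\tfrac{1-\varepsilon_k^-}{\pi_{Bk}},\;
\mathcal{L}_k(0,0)=\log\tfrac{1-\varepsilon_k^+}{1-\pi_{Bk}},\;
\mathcal{L}_k(1,0)=\log\tfrac{\varepsilon_k^-}{1-\pi_{Bk}},\;
\mathcal{L}_k(0,1)=\log\tfrac{\varepsilon_k^+}{\pi_{Bk}},$$

so agreement on a *rare* code counts for a lot and agreement on absence for
almost nothing — the property that makes sparse diagnosis profiles
linkable. Each record is then softmax-normalized against all candidates
plus an explicit **no-match** category with prior $\pi_0$, in both
directions, and the averaged posterior
$\hat\pi_{ij}=\{\pi_{ij}(A\to B)+\pi_{ij}(B\to A)\}/2$ is thresholded at
$\alpha$ (0.5 by default, 0.9 for low false-match tolerance). $\pi_{Bk}$
comes from sample fractions; $\pi_0$ can be supplied or estimated
automatically from the similarity distribution via a skew-t fit and its
rightmost inflexion point. The methods vignette
(`vignettes/diagnosis-code-linkage.Rmd`) derives everything and records the
numerical choices.

## Worked example

Simulate a claims-like cohort (400 patients, 600 mostly-rare codes, ~5
codes/patient), perturb it with correlated Gaussian noise at $\rho=0.5$,
keep partially overlapping subsets (250 vs 150 patients, 75 true pairs),
and link:

```r
library(dxlink)

sim <- simulate_linked_pair(n_patients = 400, K = 600, n_a = 250, n_b = 150,
                            n_overlap = 75, rho = 0.5, mean_codes = 5,
                            seed = 2024)
run <- match_pipeline(sim$A, sim$B, eps_minus = 0.01, eps_plus = 0.01,
                      pi0 = "auto", alpha = 0.5)
run
#> <dxlink_run> 250 x 150 patients over 600 codes; pi0 = 0.0215 (auto); 65 matches at alpha = 0.50 (37.3 s)
head(run$matches, 3)
#>      id_a    id_b posterior
#> 1 A000137 B001457         1
#> 2 A000530 B002731         1
#> 3 A000555 B001238         1
evaluate_matches(run$matches, sim$truth)
#> <evaluation> declared 65, truth 75, TP 62 | TPR 0.827, PPV 0.954
```

Reading the output: the automatic prior ($\hat\pi_0 = 0.0215$) is a rough
order-of-magnitude device (true overlap is 75/37,500 pairs — matching is
insensitive to the gap, see the vignette); 65 pairs clear the 0.5
posterior cutoff, 62 of them correct, recovering 83% of the true pairs at
95% precision despite ~8% of each patient's codes having been dropped by
the perturbation. The Fellegi–Sunter comparator on the same data
(`fs_em()`, `fs_scores()`, `fs_match_best()`) lands below 20% precision —
the reason this Bayesian weighting exists.

Real data enter the same way via `read_binary_records()` (dense CSV/TSV
with a patient-id column, or MatrixMarket + id sidecars); a thin CLI over
the same functions lives at `inst/cli/dxlink.R` (`match`, `fs`,
`simulate`, `evaluate`, `grid` subcommands). The anonymized RA benchmark
shipped inside the CRAN `ludic` package can be exported to this format
with `export_ludic_benchmark()`.

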