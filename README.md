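# vustruct

Desk-scale structural analysis of missense variants of unknown significance
(VUS), for computational geneticists and structural bioinformaticians who
want the bespoke computational core of a variant-to-structure pipeline as a
fully testable R library: no external databases, web services, schedulers
or licensed calculators are required — every input the pipeline consumes
can be generated by the package's own fixture module, deterministically
from a seed.

The pipeline runs in five phases over a case (a patient's set of candidate
variants):

1. **Variant intake** — parse a VCF or a pipeline-ready "VUStruct CSV"
   (`gene,transcript,unp,mutation,inheritance`), call protein-level
   consequences of each SNV against a flat-file transcript catalog with a
   strand-aware codon caller, retain missense variants, restrict to
   Swiss-Prot-curated transcripts, and expand each variant across a gene's
   curated "-N" splice isoforms.
2. **Cross-reference reconciliation** — classify each transcript's
   ENSEMBL-style/UniProt-style sequence pair into `PERFECT`,
   `SEQ_MISMATCH_SAME_LEN`, `LEN_MISMATCH` or `MISSING_XREF`; any
   discrepancy HALTs the case with a machine-readable report (a `--force`
   override runs the clean subset, mirroring a manual patch workflow).
3. **Structure selection** — map transcript positions onto candidate PDB /
   SwissModel / ModBase / AlphaFold structures (exact-substring offset or
   global alignment: match +1, mismatch −1, gap −2, identity floor 40%),
   score candidates linearly and select greedily:

   ```
   score = w_cov · coverage + w_var · [variant covered] + w_qual · q
         + w_conf · pLDDT/100 + w_multi · [multimer] + w_exp · [experimental],
   q = clamp((4 Å − resolution)/4 Å, 0, 1),  w = (1, 4, 1, 1, 1, 1)
   ```

   skipping any candidate whose covered-set Jaccard similarity with an
   accepted same-method candidate exceeds 0.9; an AlphaFold model is always
   included for canonical transcripts.
4. **Work planning and execution** — a GUID-suffixed case tree
   (`VUStruct/<case>_<guid>/<transcript>/<structure>/<calc>/work` with a
   sibling `status/` directory per job), a round-tripping `workplan.csv`, a
   content-hash ΔΔG relax cache, and a pluggable calculator contract.
   Licensed external calculators (Rosetta ΔΔG, PPI disruption, PTM
   proximity, digenic predictors) are represented by deterministic
   hash-based stubs; the spatial pathogenicity calculation is real.
5. **Reporting** — per-variant metric ranges across structures and
   isoforms, precomputed-score merging (AlphaMissense-/ConSurf-/COSMIS-like
   tables, exact-key lookup only), digenic pair enumeration, and
   deterministic HTML + CSV case reports.

At the scientific core is the spatial-proximity pathogenicity score
(PathProx-style): with labeled pathogenic sites *P* and benign sites *B*
on a structure and a query residue *q*,

```
score(q) = (1/|P|) Σ_{p∈P} K(d(q,p)) − (1/|B|) Σ_{b∈B} K(d(q,b)),
K(d) = 1/(1+d)  (Gaussian and hard-shell kernels available)
```

with significance from a label-permutation null
(`p = (1 + #{null ≥ observed}) / (n_perm + 1)`) and a Ripley-style
close-pair diagnostic with a permutation envelope to detect spatial
clustering of the labeled sites.

## Worked example

```r
library(vustruct)
bundle <- make_case(fixture_config(seed = 5, n_genes = 6), tempfile("bundle"))
res <- run_case(bundle$dir, tempfile("case"), user_case_id = "demo",
                force = TRUE, n_perm = 199, seed = 1)
print(res$reconciliation)
#> <xref reconciliation> 3 runnable, 1 discrepant
#>   transcript_id   gene mutation                status                          detail
#> 1        TX0040 GENE04      M1L SEQ_MISMATCH_SAME_LEN first difference at position 38
print(res$status)
#> <case status> complete: 11
#>   variants complete: 3 / 3
res$summary[, c("variant", "ddg_reu_min", "ddg_reu_max", "pathprox_pvalue_min", "consurf_like")]
#>       variant ddg_reu_min ddg_reu_max pathprox_pvalue_min consurf_like
#> 1  GENE01:N8K      -2.276      -1.598               0.655        0.644
#> 2 GENE02:A51V      -2.010      -2.010               0.070        0.433
#> 3 GENE03:F14L       6.554       8.275               0.555        0.210
```

The toy case planted four missense variants; one sits on a transcript whose
curated protein sequence disagrees with the transcript record
(`SEQ_MISMATCH_SAME_LEN` at residue 38), so that variant is reported and
excluded while `force = TRUE` lets the three clean variants run. Eleven
jobs (ΔΔG and spatial-proximity per selected structure, plus one digenic
job) all complete. In the summary, ΔΔG ranges arise because two structures
were analysed per transcript (`min = max` when only one structure
contributed); `ddg_reu` values are the deterministic stub's stand-ins for
Rosetta energies, while `pathprox_pvalue` is a real permutation p-value —
GENE02's variant sits near its planted pathogenic cluster (p = 0.07),
the others do not. `consurf_like` is an exact-key lookup from the bundled
per-site conservation table, and `res$digenic` lists the gene pairs the
deterministic stub predictor scores above threshold.

A thin CLI wraps the same functions
(`Rscript $(Rscript -e 'cat(system.file("cli","vustruct.R",package="vustruct"))') run-case --bundle <dir> --out <dir> --force`);
subcommands: `preprocess`, `reconcile`, `plan-structures`, `pathprox`,
`status`, `report`, `make-case`, `run-case`.

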