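# svradiate

Analysis of radiation-induced genomic structural variations (SVs) from
long-read sequencing call sets, built for studies of DNA double-strand
break repair in plant genomes (the reference organism is *Arabidopsis
thaliana*).

Somatic cells exposed to genotoxic agents (UV-B, UV-C, ionizing
radiation) accumulate deletions, insertions, duplications, inversions
and inversion-duplications. Separating the *induced* SVs from the
variation a seed stock already carries, and reading the repair-pathway
signature out of each deletion junction, takes a chain of careful
call-set arithmetic that this package implements end to end:

1. **Ingestion and filtering** — Sniffles-style SV VCFs are parsed into
   typed call sets and filtered with the study-grade thresholds
   (SV length 1 bp – 1,000,000 bp, supporting reads ≥ 1000 bp,
   mapping quality ≥ 20; all inclusive).
2. **Tolerant call-set algebra** — two calls are identical when they are
   the same SV type on the same chromosome with both breakpoints within
   ±50 bp. On top of this rule the package builds one-to-one pairing
   (greedy nearest, oracle-checkable), pooling by concatenation (the
   pedigree reference: three untreated replicates of 248 + 339 + 291
   calls pool to 878), control subtraction with an audit trail, and a
   three-replicate Venn partition via connected components of the match
   graph (the identity rule is not transitive, so components — not
   chained pairwise matches — define the regions).
3. **Annotation** — every SV is assigned to a protein-coding gene (PCG),
   transposable element (TE, with superfamily) or intergenic region (IR)
   by maximal base-pair overlap (ties favor TE), plus chromatin state
   (CS1–CS9, with CS8/9 grouped as constitutive heterochromatin),
   centromeric context (interval midpoint) and rearrangement-hotspot
   (HOT) overlap.
4. **Repair classification** — for each deletion `[s, e)` on reference
   `R`, the junction microhomology is the sum of the largest `k` with
   `R[s..s+k) = R[e..e+k)` and the largest `j` with
   `R[s−j..s) = R[e−j..e)`. Total microhomology ≤ 1 bp is scored NHEJ,
   2–19 bp MMEJ, ≥ 20 bp an SSA candidate; flanks truncated at a
   chromosome end or containing N are undetermined. The measure is
   invariant under shifting the reported breakpoints along the homology
   tract.
5. **Insertion-origin tracing** — inserted sequences are located in the
   reference by exact k-mer seeding plus local affine-gap extension
   (match +1, mismatch −2, gap open 4, gap extend 1) on both strands,
   with self-locus exclusion, identity/coverage floors, and a strict
   best-vs-runner-up rule separating resolved from ambiguous origins;
   resolved donors are classified (element class, truncated-TE
   detection, intra- vs interchromosomal).
6. **Statistics and reporting** — the chi-squared goodness-of-fit and
   homogeneity tests and the Mann-Whitney-Wilcoxon rank-sum test used
   in the study's figure panels, and a deterministic JSON/TSV report
   bundle.
7. **Synthetic truth generator** — a seeded toy genome (tandem-repeat
   centromeres, TE/PCG layers, chromatin states, HOT regions) with
   implanted SVs whose ground truth is exact by construction:
   mismatch-guarded deletion junctions carry a planned microhomology,
   insertions are copied from recorded donor loci, replicates share a
   controlled pedigree core. Every stage of the pipeline is tested by
   parameter recovery against these manifests.

## Worked example

```r
library(svradiate)

# a full synthetic study: 3 untreated replicates + 1 UV-B-treated sample
sc <- simulate_scenario(scenario_spec(seed = 42))
sc$callsets$rep1
#> <sv_callset> WT_untreated_rep1 (genotype WT, treatment none, replicate 1): 41 records
#>    DEL=23 INS=12 DUP=3 INV=2 INVDUP=1

# radiation-induced SVs = treated minus the pooled pedigree replicates
ind <- induced_sv_workflow(sc$callsets$treated, sc$callsets[1:3])
n_records(ind)
#> [1] 40
setequal(ind$records$id, sc$truth$truth_id[sc$truth$cohort == "induced"])
#> [1] TRUE

# replicate concordance under the ±50 bp identity rule
venn_partition(sc$callsets$rep1, sc$callsets$rep2, sc$callsets$rep3)
#> <sv_venn> components: 60 (inconsistent: 0 )
#>   A   B   C  AB  AC  BC ABC
#>   8   4  12   1   2   3  30

# repair signature of the induced deletions
repair_summary(ind, sc$seqs)$counts
#>          NHEJ          MMEJ SSA_CANDIDATE  UNDETERMINED
#>            14             3             0             0
```

The Venn's `ABC = 30` is the pedigree core (the scenario plants 30 of
60 pedigree SVs in all three replicates), and the recovered induced set
matches the implanted truth exactly because emission jitter (±25 bp) is
capped at half the matching tolerance.

## Command line

A thin CLI over the package functions lives at `inst/cli/svradiate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/svradiate.R", package="svradiate"))')" \
    simulate --seed 42 --out scenario/
```

with subcommands `simulate`, `run-all --config run.yaml`,
`subtract --target t.vcf --control c.vcf --tol 50` and
`venn a.vcf b.vcf c.vcf`.
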