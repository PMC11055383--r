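# demuxrescue

Joint donor deconvolution for pooled single-cell experiments that carry
both **cell hashing** (HTO) and **genetic** (SNP-based) demultiplexing
information.

In a multiplexed experiment each droplet is classified by a hashing
demultiplexer (singlet of a hashtag, doublet, or negative) and — when the
donors are genetically distinct — by a genotype-free genetic
demultiplexer, which yields singlets of *anonymous* donor clusters.
Hashing libraries fail often (unstained nuclei, antibody background), so
many droplets with good RNA are hashing-negative. `demuxrescue`:

1. **Matches** anonymous donors to hashtags: both call sets are binarized
   into barcodes × labels 0/1 matrices, and each (donor, hashtag) pair is
   scored with the Pearson correlation of its indicator columns — on
   binary data, the phi coefficient
   `φ = (n11·n00 − n10·n01) / √(n1+·n0+·n+1·n+0)`. Donors and hashtags
   are paired by highest *mutual* correlation, and a method pair is
   summarized by the **Phi score**: the sum of the matched non-negative
   correlations divided by the expected donor count K (so Phi ∈ [0, 1]).
   `select_best_pair()` ranks all method combinations by this score.
2. **Rescues** hashing negatives: a cell that is a confident genetic
   singlet of a matched donor adopts that donor's hashtag; agreements are
   `confirmed`, contradictions flagged as `conflict`, and genetic
   doublets/negatives are never rescued.
3. **Reconstructs minimal donor genotypes** from cellSNP-style AD/DP
   allele counts: per donor, pooled counts over consistently assigned
   cells call an overrepresented allele (aggregated depth > 10 reads,
   frequency > 90%, both configurable), inconsistently assigned cells
   must not contradict the call, and only donor-specific calls are kept.
   The result is a GT-only VCF with samples named by hashtag.
4. **Re-demultiplexes** all cells against the reconstructed genotypes
   with a binomial-likelihood assigner (singlet and doublet models,
   margin rule) and reports the concordance with the rescued assignment
   as a sanity check.
5. **Simulates** complete experiments — diploid donor genotypes with
   planted private variants, sparse AD/DP counts, negative-binomial HTO
   counts with staining failure, and noisy method output tables with a
   hidden donor-label permutation — for end-to-end validation.

## Worked example

```r
library(demuxrescue)

cfg <- sim_config(seed = 1)   # 6 donors, 5000 droplets, 30% staining failure
res <- run_pipeline(cfg)

res$match
#> donor_match sim_genetic ~ sim_hashing: phi score 0.7426, 6 pair(s),
#>   all donors matched: TRUE (5000 common barcodes)
#>   donor hashtag correlation
#>  donor0   Hash6   0.7615844
#>  donor1   Hash2   0.7329311
#>  donor2   Hash4   0.7254109
#>  ...

res$rates$rescued_fraction
#> [1] 0.9518922          # 95.2% of the 1559 hashing negatives rescued

res$genotypes
#> donor_genotype_set: 6 donor(s), 491 variant call(s) total
#>  donor n_informative n_specific
#>  Hash1           619         80
#>  Hash2           624         83
#>  ...

res$concordance$concordance
#> [1] 0.9832342          # rescued vs refined assignment, 3698 cells
```

Reading: under 2%/5% method noise the six anonymous donors are matched
to their hashtags with a Phi score of 0.74 (1.0 would be noise-free
agreement); 95% of the hashing-negative droplets receive a donor
identity from their genetics; 491 donor-specific variants (of 800
simulated) reconstruct the pool's genotypes; and re-demultiplexing
against those genotypes reproduces 98.3% of the rescued identities.

The same stages run from files — assignment CSVs
(`Barcode,Assignment`), MTX allele counts, VCF variant lists — via
`run_stage()` or the CLI wrapper:

```sh
Rscript inst/scripts/demuxrescue.R pipeline --out-dir out/ --seed 3
Rscript inst/scripts/demuxrescue.R refine --out-dir out/refine \
    --joint-csv out/joint_assignment.csv --ad-mtx out/AD.mtx \
    --dp-mtx out/DP.mtx --variants out/variants.vcf --barcodes out/barcodes.tsv
```

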