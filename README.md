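# dmsc — dynamic multi-seeds clustering of 16S rRNA amplicons into OTUs

`dmsc` bins 16S rRNA amplicon reads into operational taxonomic units
(OTUs) with a greedy heuristic clusterer whose clusters are represented by
**multi-core sequences (MCS)** instead of a single seed. It is aimed at
microbiome researchers doing de novo OTU picking who want the speed of
CD-HIT/UCLUST-style streaming clustering with less OTU over-estimation and
less sensitivity to sequencing errors.

## The method

Reads are dereplicated and streamed in abundance-descending order; each
record joins a qualifying cluster or founds a new one at distance
threshold θ (0.03 ≈ the 97% identity convention). Once a cluster reaches
η members (default 25), its MCS is selected: a greedy clique of ≥ 3
members whose pairwise alignment distances are all strictly below θ. A
candidate sequence *s* then qualifies for cluster *i* when

    d(s, Mᵢ) ≤ θ    or    |d(s, Mᵢ) − d̄(Mᵢ)| ≤ μ·σᵢ        (μ = 3)

where d(s, Mᵢ) is the mean distance of *s* to the core members, d̄(Mᵢ)
the mean and σᵢ the standard deviation of all within-core pairwise
distances (deviation sum over pairs, divisor |Mᵢ| − 1). The MCS is
updated after every merge, and isolated reads (clusters holding a single
raw read) are finally rescued into their nearest cluster. Distances are
exact global unit-cost alignment distances: difference columns divided by
alignment length.

The package also provides the evaluation metrics used for OTU
benchmarking — NMI against ground-truth labels and reference-free
pair-based MCC at a distance threshold — and a labelled amplicon
community simulator so everything is testable offline.

## Worked example

```r
library(dmsc)

spec  <- dmsc_preset("eleven_taxa", scale = 0.05, rng_seed = 42)
reads <- make_reads(spec)       # 1,100 labelled 500 bp reads, 11 taxa
fit   <- dmsc(reads, theta = 0.03)
fit
#> Dynamic multi-seeds clustering (DMSC)
#> Call: dmsc(x = reads, theta = 0.03)
#>   1100 reads, 836 dereplicated records, theta = 0.03
#>   OTUs: 9   (MCS-represented: 9, single-seed: 0)
#>   alignment calls: 53340
```

Nine OTUs from eleven taxa is the expected answer: the design places
three taxa within 1% of each other, below the 3% clustering threshold, so
they merge into one OTU. Evaluating against the simulator's truth labels:

```r
truth <- parse_taxon_labels(reads$id)
m     <- otu_map(fit)                      # one row per input read
pred  <- setNames(m$otu_id, m$read_id)
nmi(truth, pred[names(truth)])
#> [1] 0.9353854   # < 1 only because the merged trio cannot be separated

rec <- dereplicate(reads)
pair_confusion(rec, fit, theta = 0.03)
#> pair confusion: TP=46699 TN=302331 FP=0 FN=0 (MCC = 1.0000)
```

An MCC of 1 says the partition is exactly the θ-transitive structure of
the data: no pair within 3% was split and no pair beyond 3% was merged.
`write_otu_map(fit, "run.otus.tsv")` writes the read→OTU table plus a
representatives FASTA, and `predict(fit, newseqs)` places new sequences
onto the fitted OTUs. A command-line front end is available as
`exec/dmsc` with `simulate`, `cluster` and `eval` subcommands.

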