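# duphist

Detecting the footprints of ancient gene duplication in multigene
families that are being eroded by concerted evolution.

## The problem

In families like the MHC class IIB genes, an ancient duplication can
leave two gene lineages that persist across an entire species
radiation. Their footprint is a set of *diagnostic sites*: alignment
columns where the two lineages carry fixed alternative variants in
essentially every species. Intergenic gene conversion works against
this signal — it copies tracts between a species' paralogs,
homogenizing them (*concerted evolution*) until the copies resemble
each other more than their true orthologs. Deciding whether a family
retains duplication history, and at which sites, therefore requires
separating alignment columns that still trace the duplication from
columns already homogenized.

`duphist` is for molecular evolutionists who have a multiple alignment
of gene-family members from many species (plus a table mapping
sequences to species and higher groups) and want to:

* screen sequences against a lineage signature (diagnostic columns with
  their two lineage-specific variants), call each sequence's lineage,
  and quantify per-group *signature retention* — at how many signature
  columns the most lineage-A-like and most lineage-B-like members still
  differ (`signatureMatches`, `callLineage`, `signatureRetention`,
  `interminglingReport`);
* partition alignment columns into local phylogenetic classes
  ("cacti"), each summarized by a mean pairwise-difference matrix
  (`fitPartition`);
* score each cactus with the within-species statistic that
  discriminates duplication history from concerted evolution: the mean,
  across species, of the distance between each species' two most
  distant sequences, normalized across cacti by the maximum
  (`discriminationScores`, `classifyCacti`, `diagnosticSites`);
* check tree-shape predictions with uncorrected p-distances and
  neighbor joining — reciprocal monophyly of the two lineages
  (duplication topology) versus clustering of conspecific copies
  (concerted topology) (`pDistanceMatrix`, `neighborJoining`,
  `isMonophyletic`);
* simulate gene families with known duplication history and tunable
  gene conversion to calibrate all of the above (`simulateFamily`,
  `runRecoveryExperiment`).

The central statistic: for cactus $c$ with distance matrix $D_c$ and
species $s$ with sequence set $S_s$,

$$ r_c \;=\; \frac{1}{|S^{2+}|}\sum_{s \in S^{2+}}
   \max_{i,j \in S_s} D_c(i,j), \qquad
   \tilde r_c \;=\; \frac{r_c}{\max_{c'} r_{c'}}, $$

where $S^{2+}$ are the species with at least two sequences. Cacti with
$\tilde r_c \ge 0.5$ (default) are labeled duplication-history and
their columns reported as diagnostic sites.

## Worked example

Simulate a 20-species family whose two lineages were born at the root
(16 diagnostic sites among 300 columns, ~10% inter-lineage divergence,
no conversion), then recover the sites blind:

```r
library(duphist)

fam <- simulateFamily(simConfig(seed = 42))
fam$alignment
#> FamilyAlignment: 40 sequences x 300 columns
#>   sp01_A          ACAATTAGGATATTCCTCCCTACCCTGTATATGCCGAACG...
#>   sp01_B          ACCATTAGGTAATTCATCCCTACATTGTATATGCCGGACG...
#>   ...

rep <- interminglingReport(fam$alignment, fam$groups, fam$signature,
                           groupBy = "species")
head(rep[, c("group", "id", "nA", "nB", "label", "retention")], 4)
#>   group     id nA nB label retention
#> 1  sp01 sp01_A 16  0     A        16
#> 2  sp01 sp01_B  0 16     B        16
#> 3  sp02 sp02_A 16  0     A        16
#> 4  sp02 sp02_B  0 16     B        16

disc <- discoverDiagnosticSites(fam$alignment, fam$groups)
disc$scores
#>   cactus nColumns       raw normalized nSpeciesUsed       label
#> 1      1       98 0.1270408  0.1270408           20   concerted
#> 2      2       16 1.0000000  1.0000000           20 duplication
disc$sites
#>  [1]  10  37  46  88  89 121 163 181 194 203 225 244 268 280 283 287
sigColumns(fam$truth@diagnosticColumns)   # the simulated truth
#>  [1]  10  37  46  88  89 121 163 181 194 203 225 244 268 280 283 287
```

Every sequence gets a clean lineage call (`nA`/`nB` count matches to
the two lineage signatures), each species retains all 16 signature
differences, and the segmentation isolates exactly the 16 true
diagnostic columns into the top-scoring cactus (normalized score 1.0
versus 0.13 for the background), so precision and recall are both 1.

Turning on gene conversion erodes this footprint:

```r
res <- runRecoveryExperiment(baseConfig = simConfig(),
                             convRates = c(0, 0.2, 1, 5),
                             nReps = 10, seed = 1)
res$summary[, c("convRate", "medianRetention", "medianRecall",
                "medianPrecision", "monophylyRate")]
#>   convRate medianRetention medianRecall medianPrecision monophylyRate
#> 1      0.0              16      1.00000       1.0000000           1.0
#> 2      0.2              16      0.71875       1.0000000           0.9
#> 3      1.0              13      0.84375       0.1870629           0.6
#> 4      5.0               3      0.65625       0.1588050           0.0
```

Retention of the 16-site signature collapses from 16 to 3 as the
conversion rate rises, reciprocal lineage monophyly on neighbor-joining
trees disappears, and site discovery degrades — the quantitative form
of concerted evolution erasing duplication history.

Command-line wrappers over the same functions live in
`inst/scripts/duphist` (subcommands `simulate`, `screen`, `partition`,
`discover`, `experiment`), reading FASTA/TSV/YAML and writing TSV/JSON
reports.

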