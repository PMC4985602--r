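# resistseq

Locating the genetic target of an antibacterial peptide by resequencing
resistant mutants — as a fully simulatable, tested R pipeline.

## The problem

Two-peptide bacteriocins (here the plantaricin JK scenario: peptides PlnJ +
PlnK in a 1:1 ratio) kill closely related lactic-acid bacteria by engaging
a membrane protein receptor. When the sensitive strain has no reference
genome, the receptor gene can still be found genetically:

1. select spontaneous resistant mutants and quantify resistance as the
   fold increase of the MIC (the concentration inhibiting growth by 50%
   in a two-fold microdilution series);
2. sequence the wild type and the resistant mutants, assemble the
   wild-type reads into a *crude* draft, and call differences between each
   mutant read set and that draft;
3. clean the calls: differences also present in the **wild-type**
   self-comparison are assembly errors; differences shared by several
   mutants in **low-coverage** (1–5×) assembly regions are unreliable
   consensus; survivors must verify (depth, alternate fraction ≥ 0.9,
   strand balance);
4. rank genes by recurrent independent mutations, annotate each hit at
   codon level (silent / missense / nonsense / frameshift with truncation
   length), and place it on the protein's predicted transmembrane
   topology.

A gene hit independently in every resistant isolate — nonsense and
frameshift truncations plus clustered substitutions in a
12-transmembrane-helix APC-superfamily transporter — is the putative
receptor. `resistseq` implements the complete procedure, plus a
synthetic-data module that generates genomes, mutant strains, paired-end
reads, crude-assembly emulations, difference-report fixtures and
dose–response plates with known ground truth, so every stage is tested as
a recovery property.

The codon arithmetic at the core is deliberately plain: for a gene on
`[start, end]` (1-based, inclusive, forward strand) the codon index of
position *p* is `floor((p − start)/3) + 1`, and a gene of `3n` nt encodes
`n − 1` residues; truncation lengths come from translating the mutated
coding sequence to its first stop.

## Worked example

Replay the packaged 58-record difference report through the exclusion and
verification pipeline:

```r
library(resistseq)
rp <- replay_fixture()
print(rp)
#> Difference filtering: 58 in -> 36 retained ( 11 wild-type-shared,
#>   11 low-coverage shared, 0 failed verification )
#> Top gene: APC family amino acid-polyamine-organocation transporter
#>   with 7 distinct sites in 10 strains
```

58 raw differences reduce to 36 trusted ones (11 excluded as wild-type
shared, 11 as low-coverage shared), and the candidate ranking finds one
gene mutated at 7 distinct sites across all 10 resistant strains. Its
codon-level consequences, regenerated from sequence:

```r
foc <- rp$annotated[rp$annotated$gene %in% fixture_gene_models()$name, ]
foc[order(foc$codon_index),
    c("printed_position", "codon_index", "class", "truncation_after")]
#>  printed_position codon_index      class truncation_after
#>              2518         104   nonsense              103
#>              2739         177 frameshift              190
#>              3337         377   missense               NA
#>              3367         387   missense               NA
#>              3393         395   nonsense              394
#>              3482         425   missense               NA
#>              3491         428   missense               NA
```

Three mutations truncate the protein (after residues 103, 190 and 394);
localizing a truncation against the 12-helix topology:

```r
topo <- topology_model(tm_architecture())
localize(103, topo, truncation = TRUE)
#> between TM helix 2 and 3 | removes 10 helices
```

Resistance quantification from simulated dose–response plates (wild type
at 0.5 nmol/L, a mutant 600× more resistant):

```r
wt  <- estimate_mic(make_dose_response(0.5, 12, top_concentration = 2,
                                       noise_sd = 0.02, seed = 41))
mut <- estimate_mic(make_dose_response(300, 12, top_concentration = 1200,
                                       noise_sd = 0.02, seed = 42))
fold_increase(mut, wt)
#> Fold increase: 590
```

The full synthetic study — genome, mutants, reads, crude assembly,
mapping, calling, filtering, annotation, scoring against the truth
manifest — runs in about a minute at the default 50-kb scale:

```r
report <- run_simulated_study(study_config(seed = 1))
report$scorecard$sensitivity  # 1: every injected mutation retained
report$scorecard$precision    # 1: every assembly artifact excluded
```

A thin command-line wrapper lives in `inst/scripts/resistseq-cli.R`
(subcommands `run-all`, `replay-fixture`, `simulate`).

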