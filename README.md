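# trapvote

Plurality consensus for citizen-science camera-trap classifications.

Large camera-trap surveys crowd-source image labelling: every capture event
(one camera trigger, a burst of 1–3 photographs) is shown to many untrained
volunteers, who each report the species present, a group size on the ordinal
scale 1, 2, …, 10, 11–50, 51+, behaviour flags, and presence of young — or
press "nothing here". `trapvote` turns those raw per-volunteer ballots into
one reliable record per capture event, the way the big Serengeti-style
surveys do it:

* **Retirement engine** — a streaming decision, after every incoming
  classification, of whether an image set leaves circulation: *Blank*
  (first 5 answers blank), *Blank_Consensus* (10 blanks total), *Consensus*
  (10 identical species sets), or *Complete* (25 classifications).
* **Plurality consensus** — species richness `S*` is the median number of
  species named per ballot (half-integers round down); the `S*` top-voted
  species win; counts are ordinal medians; behaviours are per-species
  proportions. Certainty comes from Pielou evenness over vote shares
  `E = −(Σᵢ pᵢ ln pᵢ)/ln S` (0 = unanimous, 1 = maximally split; 0 by
  definition when `S = 1`), percent support `NumVotes/NumClassifications`,
  and the blank count.
* **Gold-standard validation** — mismatch taxonomy (correct / impossible /
  missed species / extra species / wrong species), per-species accuracy,
  count-bin agreement (exact and within ±1 ordinal bin), and the evenness
  separation between correct and incorrect answers.
* **Volunteer simulator** — seeded ground-truth scenes and volunteers with
  lookalike-structured species confusion, difficulty-scaled
  blank-when-unsure behaviour, ordinal count noise, and a matching expert
  gold table, so the full pipeline is testable without the public
  multi-gigabyte download.
* **Capture histories** — trap-day search effort and species detection
  histories (presence or counts) over sites × time bins, plus a relative
  abundance index, for downstream occupancy and abundance modelling.

File I/O mirrors the five published table schemas (`raw_data.csv`,
`consensus_data.csv`, `gold_standard_data.csv`, `search_effort.csv`,
`all_images.csv`) column for column.

## Worked example

The package ships the published sample classification streams for three
image sets (volunteer IDs are synthetic; the classifications are the
published ones). Retirement first:

```r
library(trapvote)
raw  <- read_raw_classifications(
  system.file("extdata", "worked_example_raw.csv", package = "trapvote"))
run_retirement(raw)
#> # A tibble: 3 × 5
#>   capture_event_id status    n_consumed n_post_retirement winning_set
#>   <chr>            <chr>          <int>             <int> <chr>
#> 1 ASG0010cz5       Consensus         10                 0 giraffe
#> 2 ASG0000009       Consensus         14                 0 spotted hyena
#> 3 ASG000xzxd       Complete          25                 0 <NA>
```

The giraffe stream retires the moment its 10th identical classification
arrives; the spotted-hyena stream needs 14 ballots before any species
reaches 10 votes; the third stream never reaches consensus and retires at
25 classifications. Aggregation:

```r
meta <- read_capture_metadata(
  system.file("extdata", "worked_example_metadata.csv", package = "trapvote"))
cons <- aggregate_classifications(raw, meta)
cons[, c("capture_event_id", "species", "count", "evenness",
         "num_votes", "num_blanks", "tie")]
#> # A tibble: 3 × 7
#>   capture_event_id species       count evenness num_votes num_blanks tie
#>   <chr>            <chr>         <ord>    <dbl>     <int>      <int> <lgl>
#> 1 ASG0010cz5       giraffe       1        0            10          0 FALSE
#> 2 ASG0000009       spotted hyena 1        0.646        10          0 FALSE
#> 3 ASG000xzxd       dik dik       1        0.945         5          3 TRUE
```

Unanimity gives evenness 0 (high certainty); the hyena image's dissenting
votes (two warthog, one jackal, one wildcat among 14) push evenness to
0.646; and the third image's published 25-ballot sample is an exact
three-way tie (impala / Grant's gazelle / dik dik, 5 votes each) — the
record is emitted under the deterministic tie-break but flagged `tie` so
analysts can exclude it.

A shell wrapper exposes the same pipeline as subcommands
(`aggregate`, `retire`, `validate`, `simulate`, `history`):

```sh
cli=$(Rscript -e 'cat(system.file("cli", "trapvote", package = "trapvote"))')
"$cli" simulate  --out simdir --n-scenes 1000 --seed 7
"$cli" aggregate --raw simdir/raw_data.csv \
                 --metadata simdir/capture_metadata.csv \
                 --out simdir/consensus_data.csv
"$cli" validate  --consensus simdir/consensus_data.csv \
                 --gold simdir/gold_standard_data.csv --out simdir/report
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance targets from
scratch against the installed package — it replays the shipped
single-species worked-example stream through the retirement engine and the
full plurality aggregation, and writes the measured quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/camera-trap-consensus.Rmd`) documents the
vote model and its assumptions, the retirement-rule reading, the
simulator's stated world and its limits, and the numerical conventions
(ordinal medians, tie-breaks, degenerate inputs).
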