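---
title: "Plurality consensus for camera-trap citizen science: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plurality consensus for camera-trap citizen science: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapvote)
```

## The problem

Large camera-trap surveys produce far more images than any research team can
label. A proven answer is crowd-sourcing: circulate every capture event (one
camera trigger and its burst of 1–3 photographs) to many untrained
volunteers, then aggregate their answers into a single, reliable record. The
Serengeti survey that motivates this package ran 225 cameras over three
years, collected 1.2 million capture events, and gathered 10.8 million
volunteer classifications; a simple plurality vote over those
classifications agreed with expert labels on 96.6% of a 4,149-image
gold-standard sample.

`trapvote` re-implements that pipeline as a reusable toolkit:

1. **Retirement** — decide, classification by classification, when an image
   set has been seen enough and leaves circulation.
2. **Consensus** — aggregate volunteer answers into one record per capture
   event and species, with certainty metrics.
3. **Validation** — score consensus output against expert gold-standard
   labels, with a mismatch taxonomy and count agreement.
4. **Simulation** — generate realistic synthetic volunteers and scenes so
   every stage is testable without the multi-gigabyte public download.
5. **Capture histories** — export search effort and detection histories for
   occupancy and relative-abundance analyses.

## The vote model

Volunteers choose from a controlled vocabulary of 48 species and
species-group options (`species_vocabulary()`), report a group size on the
12-level ordinal scale 1, 2, …, 10, 11–50, 51+, set five behaviour flags
plus a young-present flag, or press "nothing here" (a *blank*). There is
deliberately no "I don't know" option: pilot testing for the original
platform showed it gets over-used, and difficulty is instead inferred from
the spread of answers.

### Normalization

A volunteer who sees one zebra standing and one zebra moving sometimes
enters the species twice ("1 zebra, standing" + "1 zebra, moving").
`merge_duplicate_species()` combines such rows within a single
classification into "2 zebras, standing and moving": behaviour flags are
OR-ed, and counts combine on the ordinal scale by **lower-bound arithmetic
with saturation** (`combine_counts()`): exact bins 1–10 add numerically, a
sum past 10 lands in 11–50, and 51+ absorbs everything. The only worked
combination the source material gives is 1 + 1 = 2; saturation is the unique
order-preserving extension to the bins, because summing bin lower bounds can
never prove a total above 50. Merging never crosses classification
boundaries — each volunteer's answer stays one ballot.

### Retirement rules

`run_retirement()` replays each capture event's classification stream and
retires it at the first rule satisfied, checking in listed order after every
classification:

| rule | default | meaning |
|------|---------|---------|
| Blank | 5 | the first five classifications are all blank |
| Blank_Consensus | 10 | ten blank classifications in total |
| Consensus | 10 | ten classifications with the identical species *set* |
| Complete | 25 | twenty-five classifications in total |

"Matching" for Consensus means identical species sets: ten "lion-zebra"
answers retire an image, but a "lion-zebra" ballot does not advance the
"lion"-only tally. Retirement is absorbing; later classifications are kept
and still flow into consensus (the deployed system re-circulated images, so
real streams run to 11–57 classifications).

**A deliberate reading.** The survey's rule list describes Complete as 25
*non-blank* classifications, but its own published example stream retired as
Complete after 25 total classifications of which only 22 were non-blank
("having been viewed by 25 people"). We follow the worked example — the
default counts every classification — and expose
`retire_config(complete_counts_blanks = FALSE)` for the literal rule-text
reading. Only streams mixing blanks with a non-consensus crowd are affected.

### The plurality algorithm

For one capture event, with blanks excluded from voting:

* **Richness** `S*` is the median over classifications of the number of
  distinct species each names; half-integer medians round *down* (never
  below 1). The choice is conservative on purpose: in the original
  validation, missing a second species was an order of magnitude more
  common than inventing one.
* The `S*` species with the most votes win. Ties at the cut are broken
  deterministically (more votes, then case-folded alphabetical label) and
  **flagged** — the published sample for one image set tallies to an exact
  three-way tie, so a tie rule must exist, but none was published; flagged
  records let analysts drop ties rather than trust our tie-break.
* Each winning species gets the **ordinal median** of the counts reported
  for it (even-length medians take the lower middle bin — the schema stores
  a bin, not a fraction) and, for each behaviour flag, the proportion of
  classifications *naming that species* which set the flag.

### Certainty metrics

With `S` distinct species voted and `p_i` the vote share of species `i`,
the **Pielou evenness** of the event is

$$E = -\frac{\sum_{i=1}^{S} p_i \ln p_i}{\ln S},$$

defined as 0 when all classifications agree (`S = 1`). 0 means unanimity
(high confidence), 1 a maximally split vote. Evenness is computed from all
non-blank classifications and shared across the event's records; it is not
a useful certainty gauge for genuinely multi-species images, which are
expected to split. **Percent support** is `NumVotes / NumClassifications`
(blanks count in the denominator), and **NumBlanks** matters because unsure
volunteers press "nothing here" instead of guessing, so blanks accumulate
on difficult images. Analysts threshold any of the three.

```{r worked-example}
raw <- read_raw_classifications(
  system.file("extdata", "worked_example_raw.csv", package = "trapvote"))
meta <- read_capture_metadata(
  system.file("extdata", "worked_example_metadata.csv", package = "trapvote"))
run_retirement(raw)[, 1:3]
cons <- aggregate_classifications(raw, meta)
cons[, c("capture_event_id", "species", "count", "evenness",
         "num_votes", "num_blanks", "tie")]
```

## Validation against gold standards

`validate_consensus()` compares the consensus species set of every
gold-covered event with the expert set and classifies the outcome:
`correct` (sets equal), `impossible` (the expert panel could not identify
the image — always counted incorrect, since volunteers cannot answer
"impossible"), `missed_species` (consensus is a proper subset, including an
empty consensus), `extra_species` (proper superset), or `wrong_species`.
Count agreement is computed over events where the algorithm captured all or
a subset of the species present, pairing counts per species; "within ±1
bin" is ordinal adjacency, so 10 and 11–50 are adjacent. The evenness
separation (mean ± s.e. by correctness) reproduces the qualitative
published pattern: incorrect answers ride on visibly higher evenness.

When a supplied gold file contains multiple expert opinions, the file is
taken as authoritative; re-adjudication happened before release of the
original dataset and is out of scope here.

## The simulator's stated world

`generate_scenes()`, `volunteer_profiles()`, `generate_classifications()`
and `generate_gold()` form a seeded, deterministic generator. Where the
source survey states a quantity, the default *is* that value:

* `blank_fraction = 0.73` — roughly 73% of the 1.2 million capture events
  were misfires without animals;
* species prevalence proportional to the published per-species capture
  totals (`species_event_totals()`), so wildebeest and zebra dominate and
  zorilla is vanishingly rare;
* `impossible_fraction = 0.002` — the expert panel marked 0.2% of images
  impossible;
* a 225-site grid and the 2010–2013 study window, timestamps in UTC+3
  (Tanzania observes no daylight saving).

Where nothing is stated, we chose once, for realism, and do not tune:

* **Difficulty** is Beta(2, 5) per scene (mean 0.29): most camera-trap
  images are easy, a thin tail is genuinely hard.
* **Blank-when-unsure**: a volunteer blanks an animal scene with
  probability `blank_propensity × difficulty` (default propensity 0.5),
  encoding the observed behaviour that unsure volunteers press "nothing
  here" rather than guess.
* **Misidentification** concentrates on morphological lookalikes: 70% of
  error mass goes to a dominant confusion target (Thomson's ↔ Grant's
  gazelle, the bird categories, the two hyenas…), 15% to remaining
  lookalikes, 15% diffusely. Volunteer error scales with the *squared*
  scene difficulty, normalized so the pool-wide marginal accuracy equals
  the configured `accuracy` (default 0.85) exactly. This is a deliberate
  deviation from a difficulty-independent confusion matrix: with 20
  independent voters and difficulty-blind errors, a plurality vote is
  essentially never wrong, and the published phenomenon this generator
  must reproduce — errors and high evenness concentrating on difficult
  images — cannot occur at any realistic noise level.
* **Count noise** displaces the reported bin by `1 + Geometric(0.6)`
  ordinal steps with probability 0.25, truncated at the scale ends; group
  sizes are hardest to judge mid-scale, matching the published accuracy
  dip for 5–10 individuals.
* **Two-species scenes** occur at 5%; scenes carry true behaviour flags
  flipped with probability 0.05 per volunteer.

What a green simulation test does *not* establish: real volunteers are
heterogeneous and correlated in ways this generator is not (shared image
artefacts, learning over time, anchoring on earlier answers shown in
discussion threads), and the generator never models image pixels. Synthetic
recovery therefore validates the *pipeline arithmetic and its qualitative
behaviour*, not the field accuracy of any deployment.

## Capture histories

`build_effort()` turns per-SD-card operation intervals into trap-days per
site and half-open calendar bin; overlapping intervals count each day once,
and effort is invariant under splitting an interval into contiguous pieces.
Days not covered by any card are treated as zero effort — the conservative
reading when consecutive cards leave a gap. `build_history()` lays consensus
records of one species onto the same grid (presence or event counts);
detections landing on zero-effort cells are flagged, never silently
dropped, because they usually indicate a metadata problem worth seeing.
`relative_abundance()` reports events per 100 trap-days per site. Certainty
filtering (percent support, evenness, NumBlanks thresholds) is an optional
pre-filter, off by default, because the thresholds are analyst choices, not
properties of the data.

## Numerical and engineering choices

* Ordinal medians use the lower-middle (inverse-CDF) convention throughout,
  keeping every statistic on the published scales.
* The species tie-break sorts case-folded labels with radix order, so
  results do not depend on the session locale.
* The vectorized aggregator in `aggregate_classifications()` is tested for
  exact equality against the readable per-event reference
  `aggregate_capture_event()` on randomized tables.
* All randomness flows from explicit integer seeds through R's RNG; no
  global state is consulted, and identical inputs + seed give
  byte-identical output files (the provenance header records the tool
  version, command and config hash, never a timestamp).
* Blank rows carrying stray counts or behaviours are ignored with a
  warning; unknown species labels are a hard parse error naming the row.
  Both 0/1 and Y/N encodings of the behaviour flags are accepted on input
  because published excerpts print Y/N while the field descriptions say
  "binary indicator"; output always writes 0/1.

## Known limitations

* The headline validation figures of the original survey (96.6% species
  accuracy, 76.4%/92.98% count agreement, evenness 0.451 vs 0.725) require
  the full public download; desk-scale tests reproduce their structure and
  direction, not their values. When the raw and gold files are placed under
  `tests/testthat/fulldata/`, the acceptance suite compares against the
  published numbers directly.
* User-weighted or Bayesian aggregation (which lifted accuracy to ~98% in
  follow-up work) is explicitly out of scope; the raw tables this package
  reads and writes are the right substrate for such methods.
* The simulator does not model volunteer learning, session effects, or
  image content.
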