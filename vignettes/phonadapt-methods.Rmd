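---
title: "Methods: complexity scoring, vowel space estimation and the synthetic study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity scoring, vowel space estimation and the synthetic study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonadapt)
```

phonadapt implements a two-arm analysis of parent–infant interaction data.
One arm quantifies how much a parent *hyperarticulates* when speaking to
their infant: the vowel space area (VSA) spanned by the point vowels /i/,
/ɑ/, /u/ in F1–F2 space is estimated separately for infant-directed speech
(IDS) and adult-directed speech (ADS), and the signed difference
VSA~IDS~ − VSA~ADS~ is the speaker's articulatory adaptation. The other arm
quantifies the *phonetic complexity* of the infant's own vocalizations with
the Word Complexity Measure for Swedish (WCM-SE). Group analysis asks
whether registers differ (paired *t*-test on areas) and whether the
parent's adaptation predicts the infant's mean complexity (ordinary least
squares). This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Transcription model

Infant vocalizations are transcribed as IPA-like strings over a Swedish
phone inventory (consonant chart plus common allophones, and the vowel
set), shipped as an editable table
(`system.file("extdata", "phone_inventory.tsv", package = "phonadapt")`).
Segments not recognizable as any inventory phone are written `C`
(consonant-like), `V` (vowel-like), or `□` (indeterminate).

Conventions accepted by `parse_transcription()`:

* `.` separates syllables; `ˈ` before a syllable marks primary stress
  (ASCII `'` is an alias). A grave or acute accent on a vowel marks that
  syllable stressed; both notations normalize to `ˈ` in the canonical
  form, so `màma` and `ˈma.ma` are the same vocalization. A word-initial
  grave accent — Swedish accent II — therefore counts as *initial* stress.
* `ː` (ASCII `:` accepted) attaches to the preceding phone; length is a
  phone property, needed for the long-front-rounded vowel class.
* If a string has no `.` boundaries, it is syllabified by vowel nuclei
  with onset maximization: all intervocalic material joins the following
  onset. This makes corpora that omit boundaries parse deterministically;
  a mid-string stress mark is kept anchored to the phone that follows it.
* At most one primary stress is allowed per vocalization; unknown symbols
  are reported with their position rather than silently skipped.

Inventory notes. The consonant chart's retroflex plosive cells are read as
ʈ/ɖ, and its two typographically identical trill cells as alveolar [r] and
uvular [ʀ] — both are members of the trill class, which lists the trill
twice. [ɕ] and [ɧ] belong to the fricative class although they are absent
from the consonant chart; both are included. The long-front-rounded vowel
class ships as {yː, øː, ʉː}; the third member is an assumption (the
Swedish front-rounded set), and the inventory table can be edited to
change it.

Inter-transcriber agreement (`transcription_agreement()`) is the
percentage of matching characters under an optimal global alignment
(equivalently, the longest common subsequence), divided by the longer
string's length. "Matching characters" admits several alignments; this is
the simplest symmetric choice, and it is exercised against an independent
edit-distance oracle in the tests.

## WCM-SE scoring

`score_vocalization()` awards points over ten parameters in three domains:

| Domain | Parameter | Points |
|---|---|---|
| Word patterns | more than 2 syllables | 1 per vocalization |
| | non-initial primary stress | 1 per vocalization |
| Syllable structures | word-final consonant | 1 per vocalization |
| | consonant cluster | 1 per occurrence |
| Sound classes | velar [k g ŋ ɧ] | 1 per occurrence |
| | liquid [l ɭ ɹ] | 1 per occurrence |
| | fricative [f v s ʐ ʁ ʂ ʝ h ɧ ɕ] | 1 per occurrence |
| | voiced fricative [v ʐ ʁ ʝ] | 1 per occurrence |
| | trill [r ʀ] | 3 per occurrence |
| | long front rounded vowel [yː øː ʉː] | 1 per occurrence |

Decisions where the measure's published description left room:

* **Cluster** = maximal run of ≥ 2 consecutive consonant-like phones
  anywhere in the vocalization, one point per run regardless of length,
  ignoring syllable boundaries. This reproduces the single "nt" cluster
  point in the /ele'fant/ → 6 worked example. A `cluster_scope =
  "syllable"` switch restricts runs to within syllables.
* **Word-final consonant** applies to the final phone of the whole
  vocalization: vocalizations are silence-bounded, so the vocalization is
  the word-like unit.
* **Class multiplicity**: a phone earns points for *every* class it
  belongs to — [v] is fricative + voiced fricative (2 points), [ɧ] velar +
  fricative (2 points). The class lists overlap by construction.
* **Cover symbols**: `C` counts for syllable structure (clusters, final
  consonant) but earns no class points; `□` counts for nothing and breaks
  a consonant run. Uncertain material is scored conservatively.
* **Non-initial stress** requires an explicit mark; segmental content
  never implies stress.

```{r}
score_vocalization(parse_transcription("e.le.ˈfant"))
score_vocalization(parse_transcription("ˈsku:"))
```

## Vowel space estimation

Tokens whose median f0 exceeds 350 Hz are excluded before any formant
averaging, because formant estimates degrade at high pitch; the bound is
strict (a token at exactly 350 Hz is kept) and every exclusion is logged.

For tokens supplied as formant tracks, `mid_window_mean()` averages the
samples whose *timestamps* fall in the closed central window
[0.3·d, 0.7·d] of the token's duration d (the "mid 40%"), which suppresses
coarticulated onsets and offsets. Timestamp inclusion, rather than index
slicing, is robust to uneven sampling; if no sample falls inside the
window the single sample nearest the midpoint is used. Tokens supplied
with pre-averaged `f1`/`f2` values (the tabular form in which such data
are typically deposited) bypass windowing, and their provenance is
recorded in a `formant_source` column.

Per speaker and register, each point vowel's token estimates are averaged
unweighted (token-level windowing first, then across tokens), and the area
of the /i/–/ɑ/–/u/ triangle is

$$\mathrm{VSA} = \frac{|iF_1(aF_2 - uF_2) + aF_1(uF_2 - iF_2) + uF_1(iF_2 - aF_2)|}{2}$$

in Hz². For the Bark re-expression, every token's Hz values are converted
*before* any averaging, with

$$z = \frac{26.81 f}{1960 + f} - 0.53,$$

plus the standard corrections `z + 0.15(2 − z)` for `z < 2` and
`z + 0.22(z − 20.1)` for `z > 20.1`. The source that the analysis cites
for the Bark transform does not print a formula; this is that source's
published transform, and `hz_to_bark()` is the single point to swap if a
different variant is preferred. Frequencies are carried as real Hz
throughout; rounding happens only in display fields.

## Group analysis

`paired_t_test()` is the classical two-tailed paired *t* on per-speaker
areas (df = n − 1); zero variance of the paired differences is an error,
not a number. `fit_regression()` is OLS of subject mean WCM-SE on the VSA
difference with an intercept, reporting the slope, model *F* on (1, n − 2)
df, R², and the two-tailed p.

Outlier handling: the study design this package follows reports excluding
one high-mean subject without stating a criterion. The default policy is
therefore explicit and conservative: a subject is excluded when its mean
score lies more than 3 leave-one-out SDs from the leave-one-out mean of
the others (so an extreme subject cannot mask itself); `absolute(cutoff)`
and `none` policies are available, and every run logs the decision with
reasons. The same subject exclusion is applied to the Hz and Bark
regressions, matching the identical error df the two re-expressions
report. `predicted_increase(beta, delta)` reports the model-implied
complexity change for a delta of, by default, 10,000 Hz² (display-rounded
to two decimals, full precision retained).

`run_study()` chains the two arms and fails with stage-labelled errors
(`"stage paired-t-hz: ..."`), collects per-row parse errors rather than
aborting on them, and returns an audit of counts (tokens kept/excluded,
vocalizations parsed/failed, subjects excluded). `write_report()` writes a
deterministic, full-precision JSON report (17 significant digits;
byte-identical for identical inputs, config and seed).

## The synthetic-data generator

`simulate_study()` exists so that every stage — parsing, screening,
windowing, averaging, areas, tests, regression — can be validated against
known ground truth without any recordings. Defaults are anchored to the
study conditions the package targets:

* **Acoustics.** ADS grand mean formants and per-vowel SDs are the
  published group descriptives (e.g. /i/ 472/1904 Hz). Total variance is
  split evenly between a between-speaker and a within-speaker component
  (`sd_split = 0.5`); `noise_scale` scales both, and `within_scale`
  additionally scales only the token-level noise, so measurement error
  can be dialled down without collapsing the between-dyad signal.
* **Register effect.** A speaker's IDS triangle is the speaker's ADS
  triangle expanded linearly about its centroid by `ids_expansion = 1.36`,
  so the true IDS area is 1.36² times the ADS area and the centroid (the
  speaker's average position in formant space) is unchanged. The factor
  is the generator's effect-size dial; note that the published group
  means imply an *area* ratio near 1.36 (linear ≈ 1.17), so the default
  synthetic register effect is larger than the empirical one — the
  generator is a test harness, not an inference about the data.
* **f0.** Median f0 exceeds the 350 Hz bound with probability
  `exceed_rate` (defaults 0.10 in IDS, 0.02 in ADS), drawn from truncated
  normals on either side of the bound, so the screening stage always has
  both kinds of token to act on.
* **Tracks.** Tokens are drawn as tracks (6.25 ms frame step, 80–250 ms
  duration) with linear coarticulation ramps occupying the outer 25% at
  each edge, heading half-way toward a schwa-like neutral (500, 1500) Hz,
  plus 10 Hz per-sample jitter — so mid-40% windowing has actual bias to
  remove. `token_form = "point"` generates pre-averaged tokens instead.
* **Token counts** default to the per-speaker order of the published
  per-vowel token tallies (IDS 27/49/12 and ADS 15/35/6 for /i/ /ɑ/ /u/).
* **Complexity arm.** Each infant's expected mean WCM-SE is
  `intercept + beta_true × (true VSA difference) + N(0, resid_sd)`, with
  defaults `beta_true = 8.07e-6` points/Hz², `intercept = 1.0` and
  `resid_sd = 0.42` (the subject-level spread implied by the reported
  R² ≈ 0.22 around a mean near 1.23), and 30 vocalizations per infant
  (the order of a 10-minute session).

Vocalizations are generated from a zero-scoring base syllable "ma" plus
independent Bernoulli complexity features, each structurally isolated so
features never interact: one appended CV syllable per sound-class feature
(`ka`, `la`, `fa`, `va`, `ra`, `møː`), two appended syllables for
trisyllabicity, one appended stressed syllable, an onset cluster (`pma`),
and a final consonant. Because the features are independent and the only
non-linear term is the >2-syllables indicator, the expected score is
available in closed form (`expected_wcm_se()`), and
`calibrate_wcm_probs()` scales the configured feature weights by a common
factor (capped at probability 1, root-found to 1e-12) until the
expectation equals the target. Targets up to 13 points are reachable under
the default weights; unreachable targets are an error, and study-level
targets that fall outside the range are clamped and flagged in the truth
table. The tests verify the closed form against exact enumeration of all
feature patterns scored by the real parser and scorer.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: formant-estimation error structure
(LPC failures correlate with f0 and vowel height; here noise is Gaussian
and independent), transcription disagreement between humans, infant
corpora whose complexity distribution is not reachable by independent
feature draws (e.g. heavy-tailed babbling runs), conversational structure
of any kind, and any causal direction between the two arms — the linear
link is imposed by construction.

## Validation scale and numerical choices

The package's own validation runs at sizes chosen to make Monte-Carlo
error small relative to the margins being checked: oracle equivalence on
1,000 random triangles (relative error < 1e-9 against a generic shoelace),
1,000 generated vocalizations against a flat regex recount, 1,000 ramped
tracks for the windowing-bias comparison; 100 replicate studies at 19
dyads for register detection and 100 replicates at 200 dyads (within-token
noise scaled to 0.1, residual SD 0.05, 8 tokens per vowel) for slope
recovery, where the replicate SD of the fitted slope is ≈ 10% of the true
value, giving a ≈ 1% standard error on its mean. Ties in nearest-midpoint
fallback resolve to the earlier sample; degenerate (collinear) triangles
have area 0 by construction; uniroot calibration uses tolerance 1e-12 on
an expectation that is exact, not simulated.

## Limitations

The pipeline consumes formant tracks or tabulated estimates; it does not
estimate formants or f0 from audio, align transcriptions to audio, or
classify vowel categories acoustically. VSA is the three-point-vowel
triangle only. The WCM-SE implementation targets vocalization-level
scoring of infant productions; it is not a phonological-development stage
assessment. The regression is a two-variable OLS by design — no
longitudinal, turn-level or causal modelling.
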