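---
title: "Neighborhood indicators from geotagged posts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood indicators from geotagged posts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tweetscape)
library(dplyr)
```

## The problem

Neighborhood context — prevailing mood, food culture, physical-activity
norms — is linked to health outcomes, but consistent small-area measures of
it are scarce. Geolocated short-text posts offer a continuously updated
signal: each post carries coordinates, a timestamp, and text from which
sentiment and health-behavior mentions can be extracted. `tweetscape`
implements the full chain from a raw post stream to area-level (census-tract-
like and zip-code-like) indicators, plus the association statistics used to
relate those indicators to area covariates.

The pipeline has six stages, each usable on its own:

1. **Ingest** — parse JSON-lines records, drop malformed ones, deduplicate by
   post id, remove job postings (`#hiring`, `#jobs`, `#job` hashtags), and
   flag users holding an outsized share of the corpus.
2. **Spatial join** — assign each post to the polygon containing its point,
   in each of two area layers.
3. **Sentiment** — score each post's probability of expressing happiness with
   a maximum-entropy classifier and dichotomize at a calibrated cutpoint.
4. **Lexicon matching** — detect food and physical-activity mentions, with
   caloric-density and exercise-intensity scoring.
5. **Aggregation** — per-area percentages and means.
6. **Association statistics** — z-standardization, an economic-disadvantage
   factor score, OLS with county-clustered standard errors, and Moran's I.

## Tokenization

Posts are lowercased and split on whitespace; leading/trailing punctuation is
stripped except that a leading `#` or `@` stays attached. Hashtags are *not*
segmented into words: `#chocolatebrownie` remains one opaque token and will
not match the `chocolate` or `brownie` lexicon entries. This reproduces a
known failure mode of token matching on hashtag-heavy text, and we keep it
deliberately so that measured matcher performance reflects what such a
system actually does in the field. The rule-based tokenizer replaces
heavyweight NLP tokenizers; on the token classes the matchers and classifier
consume (plain words, hashtags, handles) the behavior is equivalent.

## The sentiment model

Two-class maximum entropy over binary unigram features is exactly logistic
regression: for tokens $t_1,\dots,t_m$ with vocabulary feature set $V$,

$$\Pr(\text{happy}\mid x) = \operatorname{logit}^{-1}\!\Big(w_0 + \sum_{j \in V}
w_j\, \mathbf{1}[t_j \in x]\Big),$$

fit by maximizing the log-likelihood minus an L2 penalty
$\tfrac{\lambda}{2}\lVert w_{-0}\rVert^2$ (the bias $w_0$ is unpenalized).
Features are binary *presence* indicators — a token repeated in one post
counts once. Unlike naive Bayes, the model does not assume conditional
independence among features.

Numerics: Newton iterations with step halving on the penalized objective,
initialized at zero, stopping when the gradient sup-norm falls below
`tolerance` (default `1e-6`, `max_iter` 500). The objective is strictly
convex for $\lambda > 0$, so training is deterministic. At $\lambda = 0$
exactly collinear features (e.g. a token present in every document) make the
Hessian singular; the Newton step then adds a tiny ridge
($10^{-8}\max_i H_{ii}$) to stay well-defined without moving the optimum.
The default penalty is $\lambda = 1$; tests that compare against `glm()` use
$\lambda = 0$.

**Happy score and cutpoint.** The fitted posterior is the post's *happy
score* in $[0,1]$. Classification is `score >= cutpoint`, boundary
inclusive; the default operational cutpoint is **0.80**. Raising the
cutpoint trades higher agreement with human labels against a lower measured
prevalence of happy posts; `calibrate_threshold()` tabulates accuracy and
predicted prevalence over a cutpoint grid and selects the accuracy-maximizing
cutpoint, breaking ties toward the cutpoint whose predicted prevalence is
closest to the labeled prevalence. The prevalence column is non-increasing
in the cutpoint by construction.

A bag-of-words valence baseline (`baseline_valence_score()`: mean valence of
tokens found in a rating table, undefined below a minimum match count) is
provided for comparison, and `evaluate_against_labels()` computes accuracy
and F1 on the positive class from the full 2x2 confusion table.

## Food and activity matching

Lexicon entries are one- or two-token lowercase phrases. Matching scans left
to right for **two-word phrases first**, consuming both token positions of
each match, then scans the remaining positions for one-word phrases. So
`orange chicken` never additionally matches `chicken`, while `taco ... taco`
counts twice: every *occurrence* counts, but no token position is consumed
twice. Caloric density is the **sum** of kcal-per-100g over matched
occurrences — the reading consistent with summing all foods mentioned — not
the mean; a `0` for non-food posts never enters area means because density is
averaged over food posts only.

Activity matching adds three rules, applied in order:

1. **Veto**: if the post contains any of *watch, watching, watches, watched,
   attend, attending, attends, attended*, it is rejected outright — such
   posts are overwhelmingly about spectating.
2. **Exclusion idioms**: token spans matching phrases like *running late*,
   *walk away*, *walking dead* are masked before matching, so `running late
   but running anyway` still matches the second `running`.
3. **Team-sport play requirement**: matches of team-sport entries
   (basketball, soccer, ...) are kept only if *play, playing,* or *played*
   occurs somewhere in the post.

Exercise intensity converts an activity's MET value to energy for a
standardized bout:

$$\text{kcal} = \text{MET} \times 3.5 \times \frac{\text{weight}_{kg}}{200}
\times \text{minutes},$$

with defaults of 30 minutes and 155 lb (70.3 kg), the approximate average
adult weight — e.g. 129.2 kcal for walking (MET 3.5) and 295.3 kcal for
running (MET 8). A post matching several activities records their **mean**
kcal (switchable to sum). `mileage_and_duration()` reads a number
immediately preceding a mile/hour/minute unit token.

The bundled lexicons (`inst/extdata/`) are small authored subsets with
plausible kcal and MET values, sufficient for testing and demonstration;
full-scale use expects the caller's own nutrient and activity tables in the
same CSV layout. Healthy and fast-food status are per-entry flags (fried
items are simply not flagged healthy), and an entry cannot carry both flags.

## Spatial join

Layers are GeoJSON FeatureCollections (longitude first, everywhere).
Containment uses the **even-odd** ray-crossing rule with **boundary points
counted inside**; when a point sits on a shared boundary, the
lexicographically smallest area id wins and the tie is logged. These
conventions are choices made for determinism, not inferences about any
upstream toolchain. Geometry is planar — at neighborhood scale the
difference from geodesic edges is negligible. A bulk-loaded bounding-box
tree provides candidate areas; candidates are always verified with the exact
test, and the index's only contract is completeness (it may over-return,
never miss). A brute-force full scan implements the same tie-break and
serves as the test oracle: on a 10x10 grid with 1,000 points, including
points placed exactly on cell edges and corners, indexed and brute-force
assignment agree exactly.

## Aggregation

Per area: percent of posts happy / about food / about activity; among food
posts, percent healthy, percent fast food, percent happy (also within
healthy-food and fast-food posts), and mean caloric density; among activity
posts, mean intensity and percent happy. Conditional indicators with an
empty denominator are `NA`, never 0 — zero is a valid data value. Areas
with fewer than `min_posts` (default 30) posts are suppressed: no upstream
rule dictates this, but percentage indicators at tiny denominators are
dominated by noise; the threshold is configurable. The post-count-weighted
mean of area percentages equals the corpus percentage exactly
(conservation), which the tests assert to $10^{-9}$.

## Association statistics

All regression variables are z-standardized (sample SD, $n-1$). The
**economic-disadvantage score** combines percent female-headed households,
percent families in poverty, unemployment rate, percent college graduates
(reverse coded), and median family income (reverse coded): each z-scored,
then the first principal component, sign-oriented so higher = more
disadvantage, rescaled to SD 1. PCA is one defensible reading of a "factor
score"; a mean-of-z-scores variant ships behind the same interface for
sensitivity checks, and on single-factor synthetic data the two correlate
above 0.99.

**Cluster-robust OLS.** Areas in the same county share unobserved context,
so their errors correlate and classical OLS standard errors are too small.
`ols_cluster()` computes the sandwich estimator

$$\widehat{V} = c\, (X'X)^{-1} \Big(\sum_g X_g' e_g e_g' X_g\Big)
(X'X)^{-1}, \qquad c = \frac{G}{G-1}\cdot\frac{n-1}{n-k},$$

with 95% CIs from the normal approximation by default and a $t_{G-1}$ option
— the standard recommendation when the cluster count is finite. The
coverage simulation in the acceptance tests draws predictor and error each
with intra-cluster correlation 0.3 (one correlation parameter, applied
symmetrically), 50 clusters of 20 areas, 500 replicates, and evaluates
coverage with the $t_{G-1}$ reference: the clustered estimator covers the
true slope about 93–94% of the time while naive OLS covers under 90%,
which is the entire case for clustering.

**Moran's I.** With row-standardized queen-contiguity weights $w_{ij}$
(shared vertex; a rook variant requires a shared edge),

$$I = \frac{n}{S_0} \cdot \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar
x)}{\sum_i (x_i - \bar x)^2},$$

with null expectation $-1/(n-1)$ under permutation. Queen contiguity and
row standardization are documented choices; nothing upstream fixes them.

## The synthetic-data generator

`simulate_posts()` is first-class, tested code, not a fixture: it defines
the study conditions under which the pipeline's recovery properties are
demonstrated. Each area gets `n_posts` posts at points drawn uniformly
inside its polygon (rejection sampling in the bounding box); text is
composed from disjoint happy/unhappy/neutral token classes with
area-specific probabilities, and food/activity phrases are inserted
independently (team sports arrive with "played", so participation is
simulated). Ground-truth labels travel in a sidecar table, never in the
text. The default per-area probabilities — 20% happy, 5.1% food, 1.8%
activity — mirror the corpus-level prevalences reported for large national
post collections, so a full synthetic run reproduces sensible magnitudes.

What the generator deliberately does *not* emulate: real linguistic
variation (sarcasm, misspellings, segmented hashtags), user-level burstiness
and spam, class-vocabulary overlap, and boundary-dense point patterns.
Consequently, passing recovery tests show that the machinery is correct —
matching rules are applied exactly, the classifier recovers a recoverable
signal, percentages aggregate and conserve — not that real-world accuracy
will match: on real text, reported sentiment accuracies are far below the
near-perfect separation seen here, precisely because real classes are not
separable.

## Problem sizes and determinism

The test and acceptance runs use: 1,000 points on a 10x10 grid for the join
oracle; 2,000 labeled examples (1,500/500 split) for held-out accuracy;
5,000 documents over 40 tokens for weight recovery (fitted-vs-generating
correlation about 0.996); a 10x10 grid at 200 posts/area (20,000 posts) for
indicator recovery; 500 replicates of the 1,000-observation coverage
simulation; 100 random fields plus 1,000 permutations for Moran's I. These
sizes give stable statistics while keeping a full run around a minute on one
core. Every stochastic step takes an explicit seed; `run_pipeline()` is
byte-deterministic given config and seed, which the tests verify by
comparing output files across two runs.

## Known limitations

- The matchers inherit every stated matching failure mode: unsegmented
  hashtags, misspellings, and out-of-lexicon items are missed, and
  metaphor/advertising uses of food terms are false positives.
- Caloric density assumes a fixed per-100g basis; portion size is unknowable
  from text.
- The bounded lexicons ship as demonstration subsets; results at scale
  depend on the caller's lexicons.
- Geometry is planar and CRS handling is limited to asserting lon-lat
  degrees.
- The happy/not-happy dichotomy does not separate sadness from neutrality.
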