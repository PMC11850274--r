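# stylegauge

Non-invasive assessment of parenting style from microblog post histories.

A negative parenting style — low emotional warmth combined with high
rejection and overprotection — is a known risk factor for anxiety,
depression and suicidal ideation among university students. The standard
measurement instrument is the short-form Chinese EMBU questionnaire
(s-EMBU-C): 21 four-point Likert items yielding three dimension scores,
Rejection (*s<sub>r</sub>*), Emotional Warmth (*s<sub>e</sub>*) and
Overprotection (*s<sub>o</sub>*), each the mean of its items on the 1–4
scale. Questionnaires are accurate but invasive and do not scale;
`stylegauge` implements the alternative route: estimating the score triple
directly from a student's public microblog posts.

The package covers the whole workflow:

* **Questionnaire scoring and validity filtering** — item-mean scoring with
  a configurable key, an instructed-response ("polygraph") check, follower
  and activity filters, normalization *y = (s − 2.5)/1.5* onto [−1, 1],
  and rule-based style typing: *positive* when
  (s<sub>e</sub> > s<sub>r</sub>+1) & (s<sub>e</sub> > s<sub>o</sub>+1),
  *mixed* when |s<sub>e</sub>−s<sub>r</sub>| < 1 &
  |s<sub>e</sub>−s<sub>o</sub>| < 1, *negative* when
  (s<sub>e</sub>+1 < s<sub>r</sub>) & (s<sub>e</sub>+1 < s<sub>o</sub>),
  *other* when no rule holds.
* **Lexicon analytics** — per-user proportions of topic words (11
  LIWC-style categories) and emotion words (7 categories), group tables by
  style type and gender, and pooled-variance Student *t* comparisons.
* **The assessment network** — post embeddings *emb<sub>i</sub>* feed two
  stacked LSTM layers; tanh attention scores
  *Att = tanh(H W₁ + b₁)* pool the hidden sequence into
  *H′ = Attᵀ H*; the **correlation-injection layer** concatenates six
  mean-embedding representations of style-linked word sets
  (*C = H′ ‖ T″<sub>p</sub> ‖ E″<sub>p</sub> ‖ T″<sub>m</sub> ‖
  E″<sub>m</sub> ‖ T″<sub>n</sub> ‖ E″<sub>n</sub>*); a two-layer tanh head
  maps *C* to the normalized score triple. Forward and backward passes are
  compiled (RcppArmadillo) with analytic gradients, trained with Adam on
  MSE. Ablations (`no_attention`, `no_injection`) are first-class.
* **Offline encoder fallback** — a deterministic subword-hash sentence
  encoder (character n-gram hashing, fastText-style), so the entire
  pipeline runs without any model download or network access.
* **Baselines and evaluation** — TF-IDF + ridge and 18-feature
  lexicon-proportion + boosted-trees baselines, per-dimension MSE/MAE
  (normalized and raw scale), dataset splitting, and an ablation driver.
* **Synthetic corpus generator** — users with latent score triples whose
  style type drives category-specific word usage at realistic rates, plus
  noise and quotation posts, so every stage is testable offline.

## Worked example

```r
library(stylegauge)

ratings <- stats::setNames(c(1,2,1,2,1,2, rep(4,7), rep(2,8)),
                           default_scoring_key()$item)
s <- score_questionnaire(ratings)
s
#> s_r s_e s_o
#> 1.5 4.0 2.0
classify_style(s["s_r"], s["s_e"], s["s_o"])
#> [1] positive
normalize_score(s)
#>        s_r        s_e        s_o
#> -0.6666667  1.0000000 -0.3333333
```

The rejection items average 1.5 and warmth is at the ceiling, so the rules
place this respondent in the positive style type; the normalized triple is
what the assessment model is trained to predict.

```r
fx <- make_fixture("tiny", tempfile(), seed = 7)
corpus <- fx$corpus
summarize_dataset(corpus$users)
#> Parenting-style dataset summary
#>   users grouped: 12 (reported: 12)
#>   positive      8 (66.7%)
#>   mixed         4 (33.3%)
#>   negative      0 (0.0%)
#>   other         0 (0.0%)
#>   mean scores: s_r=2.00 s_e=3.37 s_o=2.11

prof <- user_profiles(corpus$posts, corpus$emotion_lexicon)
compare_groups(prof$happy[corpus$users$style == "positive"],
               prof$happy[corpus$users$style == "mixed"])
#> # A tibble: 1 × 6
#>   mean_a mean_b  diff     t     p signif
#> 1   3.82   2.98 0.844  1.02 0.334 NS
```

Positive-type users in this 12-user toy corpus use "happy" words for 3.8%
of their tokens against 3.0% for mixed-type users; at this sample size the
pooled *t* test rightly calls the difference non-significant.

For the full pipeline (embed → train → evaluate → attention case study) see
`run_assessment_pipeline()`, or the command-line wrapper
`inst/cli/stylegauge` with the subcommands `simulate`, `score`, `filter`,
`analyze-freq`, `train`, `ablate` and `assess`.

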