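# clinevent

Clinical event detection in pre-tokenized narrative text: locating mentions
of patient **problems, tests, treatments, evidentials, occurrences and
clinical departments** and typing them. Annotated clinical corpora are small
and access-restricted, and clinical vocabulary is full of terms a model will
never have seen; `clinevent` addresses both with (a) a tagger whose
character-level features read word shape, and (b) a label-preserving data
augmentation engine for sequence labeling. It is written for clinical-NLP
researchers and for anyone who needs a fully inspectable, dependency-light
BIOES tagger with a CRF.

## The model

The task is BIOES sequence labeling (`B-`/`I-`/`E-`/`S-` per type plus `O`,
25 labels for 6 types). The tagger is an encoder-decoder:

- **Character encoder**: per word, an embedding lookup over its characters,
  one relative-position attention layer, a feed-forward network, a resize
  layer, and max-pooling over the character axis → a shape-aware vector
  (width `cd`, default 30).
- **Word embedder**: a pluggable interface returning an `l × wd` matrix;
  default is a trainable lookup table with a shared UNK row (a contextual
  embedder of width 768 fits the same slot).
- **Encoder**: fused features, projected to `d_model`, through a stack of
  relative-position multi-head self-attention layers. Per head,

  ```
  A[t,j] = Q_t K_j' + Q_t R_{t-j}' + u K_j' + v R_{t-j}'
  ```

  with `Q = H W_q`, keys the *unprojected* column slice of `H`,
  `R_o` a sinusoidal embedding of the signed offset `t−j`, and no
  `1/sqrt(d_k)` scaling. Sine parity makes the scores direction-aware.
- **Decoder**: a linear-chain CRF (learned transition table, START/STOP
  boundary scores) trained by exact NLL via the forward algorithm and
  decoded with Viterbi.

Augmentation replaces only non-event (`O`-tagged) words, scanning a
per-word lexicon in the priority order *synonyms → antonyms → hypernyms →
hyponyms → related words* and taking the first candidate; one-for-one
substitution preserves the tag sequence exactly. Modes: `all`,
`all_no_ant` (antonyms excluded), `one_no_ant` (one new sentence per
replaceable position).

Evaluation reports strict span P/R/F1 (exact boundary + type), lenient span
P/R/F1 (one-to-one maximum-overlap matching, type ignored) and type
accuracy over the matched pairs.

## A worked example

The packaged fixture reproduces the augmentation walk-through: the sentence
*"She has been worked up with barium enema 09/97 ."* with "barium enema"
tagged as a `test` event, and a lexicon in which *has* has the synonym
*have*, *worked* has the hypernym *set* (hyponym *cut*, related word *put*),
and *up* has only the antonym *down*.

```r
library(clinevent)
fx <- fixture_paper_example()

aug <- augment_sentence(fx$sentence, fx$lexicon, "all")
paste(aug[[1]]$tokens, collapse = " ")
#> [1] "She have been set down with barium enema 09/97 ."

aug <- augment_sentence(fx$sentence, fx$lexicon, "all_no_ant")
paste(aug[[1]]$tokens, collapse = " ")
#> [1] "She have been set up with barium enema 09/97 ."
```

Every replaceable word was swapped for its highest-priority candidate
(*has → have* by synonym, *worked → set* by hypernym, *up → down* by
antonym); excluding antonyms leaves *up* untouched. The event tokens and the
tag sequence are identical in all outputs.

End-to-end on synthetic data:

```r
full  <- generate_corpus(synth_config(n_sentences = 700, signal = 1.0, seed = 11))
train <- full[1:500]; held_out <- full[501:700]

cfg <- ced_config(char = char_encoder_config(cd = 12, heads = 3, cd_ff = 24,
                                             layers = 1, wl = 12),
                  wd = 16, d_model = 32, layers = 1, heads = 4, d_ff = 64)
fit <- train_tagger(train, ced_model(train, cfg, seed = 21),
                    train_config(batch_size = 16, epochs = 30, lr = 0.1,
                                 warmup_fraction = 0.3, seed = 31))
evaluate_corpus(held_out, predict(fit$model, held_out))
#> strict   P 0.9602  R 0.9548  F1 0.9575
#> lenient  P 1.0000  R 0.9944  F1 0.9972
#> type accuracy 1.0000
```

Strict F1 0.96 on held-out sentences whose event words are almost all
out-of-vocabulary: the character encoder has learned the type-specific
affixes the generator plants. Lenient F1 near 1 says boundaries are found;
type accuracy 1 says the matched spans are typed correctly.

There is also a command-line interface (`exec/clinevent`, or
`ced_cli()` from R) with subcommands `synth`, `augment`, `train`,
`predict`, `evaluate` over CoNLL-style two-column files.

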