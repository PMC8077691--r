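---
title: "Translating between molecular strings and systematic names: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating between molecular strings and systematic names: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chemnmt treats the conversion between a machine-readable molecular
string and its systematic chemical name as a machine-translation
problem. This vignette is the package's own account of the models it
implements, the choices behind them, and what its desk-scale tests do
and do not demonstrate.

## The translation pipeline

Molecules enter the pipeline as SMILES strings and are curated with a
fixed filter before any learning: molecular weight strictly below 1500
Da, single-component structures only (anything containing a `.` is
treated as a salt/counter-ion and removed), elements restricted to C,
H, O, N, P, S, F, Cl, Br, I, Se and B, no deuterium or tritium, 3 to 40
heavy-atom bonds, no atom with a formal charge, and no explicitly
written hydrogens. Two of those rules need interpretation:

* "charged group" is read as *any atom with nonzero formal charge* -
  the most conservative reading, and the only one that needs no
  curated list of group patterns;
* "implicit hydrogens only" is read as *reject SMILES that spell
  hydrogens inside bracket atoms* (`[H]`, `[CH3]`, `[2H]`) unless the
  bracket is required to express a charge. Aromatic `[nH]` is exempt,
  since there is no bracket-free way to write it.

The weight bound is applied to the average molecular weight, strictly
(`< 1500`), matching the wording "fewer than 1500 Da".

Accepted structures are converted to SELFIES, a molecular string
language in which any token string decodes to a chemically valid
structure. No R implementation of SELFIES exists, so the package
carries its own dialect: atom tokens (`[C]`, `[=O]`, ...), branch
tokens carrying the attachment bond order (`[Branch1_2]`), and ring
tokens (`[Ring1]`, `[Expl=Ring1]`), with branch lengths and ring spans
encoded by the following token's position in a fixed 16-symbol index
alphabet. During decoding every bond order is capped by the remaining
valence of both partner atoms and unrealizable tokens are skipped
(a branch or ring marker with no anchor atom drops only the marker
itself), so every token string containing at least one atom token
derives a valid molecule; this is the property that makes a trained
decoder's output always convertible back to SMILES. The round trip
`decode(encode(s))` is canonically exact, which the test suite checks
on every generated corpus.

Throughout the package, "same structure" means "identical Open Babel
canonical SMILES". Canonical SMILES strings are dialect-specific, so
one canonicalizer is designated project-wide and all structure
comparisons go through it; graph identity questions (as opposed to
string questions) use InChI.

## Tokenization

SELFIES strings split trivially at closing brackets. Names are split by
two rules: each punctuation character `( ) { } [ ] - . ,` becomes a
standalone token, and each occurrence of a nomenclature morpheme (49
entries: multipliers like `di`/`tri`, group names like `methyl`,
`hydroxy`, `oxo`, parent fragments like `butan`/`butane`) *ends* the
current token, scanning left to right with longest match first.
"Longest first" resolves overlaps deterministically (`butane` beats
`butan`, so "dione" splits as `di` + `one`). Cutting *after* the
morpheme, rather than around it, is deliberate: it is the convention
under which the published worked BLEU examples reproduce exactly, and
it mirrors a delimiter procedure described as "a space character was
added after every word". The printed source of the morpheme list
contains visibly merged entries (`nonadeca`, `fluoromethane`,
`sulfinoiodo`); these are carried as their constituent morphemes
(`nona`, `deca`, `fluoro`, `methane`, `sulfino`, `iodo`), in keeping
with the list's other single-morpheme entries.

Vocabularies reserve index 0 for padding, 1 for the start marker and 2
for the end marker; content tokens are indexed by descending corpus
count with lexicographic tie-breaks, so rebuilding from the same corpus
is deterministic. A rare-token cutoff (`min_count`) drops tokens seen
fewer times than the threshold. Encoded sequences have the fixed layout
`[start, tokens..., end, pad...]`; using pad = 0 lets the loss mask be
a zero test. The configured content limits (48 SELFIES tokens, 78 name
tokens) exclude the two markers, so the padded length is `limit + 2`.

## The translator

Both directions use the same architecture; swapping the dataset sides
swaps the direction. The encoder embeds source tokens and runs a single
GRU; the decoder embeds the previous target token, concatenates it with
an attention context vector, and feeds the result to its own GRU whose
output is projected to target-vocabulary logits. Attention is additive:
`score(enc_t, dec) = v . tanh(W1 enc_t + W2 dec)`, softmax-normalized
over real (non-pad) source positions, with the decoder query being the
*previous* decoder state. The decoder starts from the encoder's final
state at each sequence's true length, so training and inference see
identical encoder summaries.

Training is teacher-forced (the decoder always receives the gold
previous token; the first input is the start marker) with
padding-masked mean sparse cross-entropy - the "modified" loss: pad
positions contribute nothing, and the mean runs over real target tokens
only. Optimization is Adam at the reference learning rate 0.0005 by
default. Backpropagation through the GRUs and the attention stack is
implemented directly with matrix algebra and is verified in development
against finite differences. All randomness - initialization and batch
shuffling - derives from the single config seed, so a rerun with the
same data and seed reproduces the loss trace bit for bit.

Unstated hyperparameters are exposed with small faithful defaults: one
recurrent layer, hidden size 512, embedding 256, no dropout, teacher
forcing throughout, greedy argmax decoding (no beam search is used
anywhere). Greedy decoding feeds the argmax back as the next input and
stops at the end marker or the target length bound, so it always
terminates.

## Evaluation protocol

Translation quality is scored with sentence BLEU implemented from the
definitions: modified n-gram precision (candidate n-gram counts clipped
at their reference counts), brevity penalty `exp(1 - r/c)` for short
candidates, and score `BP * exp(sum w_n log p_n)` with preset weight
vectors BLEU-1 (1,0,0,0), BLEU-2 (.5,.5,0,0), BLEU-3 (.3,.3,.3,0) and
BLEU-4 (.25,.25,.25,.25). There is no smoothing: any zero weighted
precision zeroes the score. The BLEU-3 preset intentionally sums to
0.9 and the exponent form is applied verbatim - that is what reproduces
its published values. Two printed worked examples do not reconcile
with their own arithmetic: the "wrong word" headline (0.87 printed vs
0.88 from its own 4-gram line; the implementation reports the computed
value and the golden test allows 0.01 on that case) and the "longer
prediction" unigram score (0.63 printed; no tokenization consistent
with the other five examples yields it; the computed 16/26 is asserted
instead and the case is excluded from hard acceptance).

Chemical agreement is scored structurally. Predicted names are parsed
back to structures by a pluggable backend - the package's own family
parser by default, so tests run without external tools; a name the
backend rejects counts as *invalid*. Valid pairs get a Tanimoto
similarity between 881-bit substructure fingerprints; corpus averages
are reported both over valid pairs and readjusted to the full test set
with invalid predictions contributing zero.

The fingerprint follows the published PubChem/CACTVS substructure
keyset layout: hierarchic element counts (115 bits), ring counts by
size and character (148), simple bonded element pairs (64), atom
nearest-neighbor keys (89), detailed neighborhoods with explicit bond
orders (44), and two banks of SMARTS patterns (253 + 168). The pattern
tables are a reconstruction from the published specification of that
keyset; the layout and the section semantics are exact, the SMARTS
banks are curated to the published families. Ring perception uses a
greedy smallest-set-of-smallest-rings over the heavy-atom graph, with
aromatic ring counting delegated to Open Babel SMARTS queries; for
fused unsaturated/aromatic edge cases the per-category ring counts are
approximations, which does not affect the acyclic family the package
generates. Matching of hydrogen-containing keys is done on a graph
with hydrogens made explicit. On the published example pair of enamine
isomers this implementation reproduces the printed similarity of 0.97,
and it also reproduces the published observation that two different
polycyclic isomers can share a fingerprint (Tanimoto 1.0) while InChI
identity says they differ.

## The synthetic ground-truth family

Full-scale corpora are built by external naming software over tens of
millions of structures; at desk scale the package instead *generates*
ground truth it can prove correct. The family is deliberately narrow:
acyclic carbon skeletons up to 12 chain carbons, substituents from
{methyl, ethyl, hydroxy, amino, chloro, bromo, fluoro, iodo, oxo},
ketones only (no terminal oxo), no stereochemistry, no charged or
multivalent exotica. Within it, substitutive nomenclature is decidable
with a short ruleset: longest-chain parent (ties resolved by lowest
principal-group locants, then lowest prefix locants at the first point
of difference, then the lexicographically smaller name), suffix
priority ketone > alcohol > amine, alphabetical prefix citation
ignoring multiplying prefixes, and locants omitted only where they are
redundant (chains of one or two carbons with a single substituent).
The generator's default conditions - chains to 8 carbons, up to 3
substituents - produce molecules whose token sequences exercise every
tokenizer rule (locants, commas, dashes, multipliers, morpheme cuts).

The namer and the name parser are exact inverses on the family, so a
generated corpus needs no external validation; the parser doubles as
the round-trip validity backend during evaluation, playing the role an
external name-to-structure tool plays at full scale. Corrupting a
single token of a generated name makes the parse fail or produce a
different structure in the overwhelming majority of cases (locant
swaps across a molecular symmetry are the benign exception), which is
what gives the evaluation module genuine invalid-name and
imperfect-Tanimoto cases.

What the family does *not* emulate: rings and aromatic systems,
stereodescriptors, multiplicative and retained trivial nomenclature,
and the long-tail token distribution of real chemical names. A model
that memorizes or generalizes inside this family demonstrates that the
architecture, losses, masking and decoding are wired correctly - not
that it would reach any particular accuracy on real nomenclature.

## Numerical and scale choices

Tests and the acceptance checks run on sizes chosen to exercise every
code path while staying comfortable on a single CPU: shared module
fixtures of 60-150 generated pairs, round-trip suites on a 2,000-pair
corpus, a 10,000-pair BLEU oracle comparison, an exhaustive
modified-precision check against a brute-force matcher over all token
sequences of length up to 6 on a 3-letter alphabet, and a learning
check that trains a 48/96-unit model (a smaller instance of the same
architecture; the 256/512 defaults are unchanged) on a 500-pair
corpus for 150 epochs at learning rate 0.005 and batch 64 - enough
optimization pressure to memorize the training set, which the check
requires at 95% exact greedy match. Numerical details worth noting:
softmax rows are max-shifted before exponentiation; predicted
probabilities are clamped at 1e-12 inside the loss; attention masks
pad positions at -Inf before normalization; the train/test splitter
re-draws with an incremented seed (bounded retries) until the test
portion's source tokens are covered by training and the two relative
token-frequency vectors reach cosine similarity 0.99.

## Known limitations

* The SELFIES dialect covers the elements and bond orders the corpus
  family needs plus rings; it does not implement charges, isotopes or
  stereochemistry (encoding such structures raises a conversion
  error, by design).
* The fingerprint's SMARTS banks are a reconstruction (see above);
  bit-for-bit agreement with server-computed fingerprints is expected
  for the simple-chemistry sections but is not guaranteed across all
  881 positions for complex ring systems.
* The nomenclature grammar is complete only over its family;
  `name_molecule()` refuses anything else rather than guessing.
* Training is single-device, full-precision, greedy-decoded; no
  distributed batching or beam search.
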