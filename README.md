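# smivis

Coordinated visualization of SMILES token attribution scores, in R.

## The problem

Explainable-AI methods for molecular property prediction attach
attribution scores to their input. For models that read SMILES strings,
those scores live on *tokens* — atoms, but also brackets, charges,
ring-closure digits and parentheses. The substring `[N+]` is one atom and
three non-atom tokens, and a SMILES-based model can put real weight on all
four; yet only atom scores can be painted onto a molecule diagram, and the
string itself is hard to read (the two digits closing a ring may sit far
apart while the ring atoms are adjacent on the diagram).

smivis is for the data scientist or computational chemist screening such
attributions. It:

* lexes a SMILES string into typed tokens, losslessly, with the atom-token
  count guaranteed to equal the molecule's heavy-atom count;
* binds score vectors of either admissible length — per atom or per token
  (per-atom vectors are spread onto atom tokens, 0.0 elsewhere);
* resolves every token to the substructure it denotes (atom, ring, bracket
  group, branch) as explicit data;
* maps scores through a clamped diverging colormap with threshold
  highlighting; and
* renders a molecule diagram over positive/negative heatmap layers,
  coordinated with a per-token bar chart and an attribute table, to
  deterministic SVG and self-contained HTML galleries with precomputed
  hover behavior.

It also generates realistic attribution data: the **token-substitution
sensitivity score** for any black-box SMILES predictor,

    s_i = f(x) − mean_{v ∈ V} f(x with token i's text replaced by v),

(strings the predictor rejects are dropped from the mean), and per-atom
**Wildman–Crippen logP contributions** as a ground-truth-style comparator.
Scores are normalized against a colormap domain `(min, 0, max)` — positive
scores by `max`, negative by `|min|`, clamped to [−1, 1] — and a threshold
fraction `t` highlights atoms with `|s| ≥ t·max`.

## Worked example

```r
library(smivis)

tokenTable(tokenizeSmiles("[N+]"))
#>   text          kind charStart charEnd atomIndex
#> 1    [  BRACKET_OPEN         1       1        NA
#> 2    N          ATOM         2       2         1
#> 3    +        CHARGE         3       3        NA
#> 4    ] BRACKET_CLOSE         4       4        NA
```

One atom token, three non-atom tokens. A per-atom score vector spreads
onto the atom tokens of `C1CC1` (the ring digits get 0.0):

```r
scores(attachScores(tokenizeSmiles("C1CC1"), c(0.1, 0.2, 0.3)))
#> [1] 0.1 0.0 0.2 0.3 0.0
```

With the colormap domain (−0.5, 0, 0.5), a threshold of 0.5 highlights
atoms from an absolute score of 0.25:

```r
thresholdCutoffs(0.5, c(-0.5, 0, 0.5))
#> [1] 0.25
```

Crippen contributions for aspirin sum to its molecule-level logP, and the
substitution method scores every token of ethanol against the bundled
logP predictor:

```r
v <- crippenScores("CC(=O)Oc1ccccc1C(=O)O")
round(v, 4)
#>  [1]  0.5131 -0.2783 -0.1526 -0.4195  0.5437  0.2811  0.2811  0.2811
#>  [9]  0.2811  0.1360 -0.2783  0.1129  0.0087
sum(v)
#> [1] 1.3101

round(scores(substitutionAttribution(logpPredictor(), "CCO")), 4)
#> [1]  0.2016 -0.3303 -0.9033
```

The oxygen pulls logP down hardest: replacing it with an average
vocabulary atom would *raise* the prediction by 0.90. Render panels and a
gallery:

```r
recs <- makeFixtures(5, seed = 7, method = "crippen")
writeLines(composePanel(recs[[1]]), "aspirin.svg")
writeLines(renderGallery(recs, panelConfig(thresholds = 0.75)), "gallery.html")
```

## Command line

```sh
exec/smivis fixtures --n 5 --seed 7 --method crippen --out fx.json
exec/smivis render fx.json --out out/ --format both --palette PuOr --thresholds 0.5 0.75
exec/smivis inspect "C1CC1"
```

`inspect` prints the token table and the resolved hover map; `render`
writes one SVG per record plus `gallery.html`. The record-file JSON schema
is documented in `inst/schema/record-schema.md`.

## Not in scope

Training predictive models (the predictor is a plug-in contract), SHAP or
fingerprint-based attribution methods, live browser event handling beyond
the precomputed hover maps, SELFIES/InChI tokenization, and per-bond
scores.
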