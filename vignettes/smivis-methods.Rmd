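---
title: "smivis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smivis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smivis)
```

## The problem

Explainable-AI methods for molecular property prediction produce
attribution scores over the input representation. When that representation
is a SMILES string, scores live on *tokens*: atoms, but also brackets,
charges, ring-closure digits and parentheses. A substring like `[N+]`
contains one atom token and three non-atom tokens, and a model that reads
SMILES may assign real influence to all four. Non-atom scores have no
position on a molecule diagram, and SMILES syntax itself is hard to read —
the two digits that close a ring can sit far apart in the string while the
ring atoms are adjacent on the diagram. smivis resolves both problems as
*data*: it renders a molecule diagram (over per-atom heatmap layers)
coordinated with a per-token bar chart, and precomputes every
token-to-substructure correspondence so that hover highlighting in the
exported HTML needs no chemistry at view time.

## Token grammar

No published convention pins down a SMILES token grammar exactly (for
instance whether `+2` is one token or two), so the package declares one
and treats it as a contract:

* Outside brackets, an ATOM token is an organic-subset symbol
  (`B C N O P S F I`, aromatic `b c n o s p`, wildcard `*`) with the
  two-character halogens `Cl` and `Br` lexed as single tokens.
* A bracket group contains exactly one ATOM token — the element or
  aromatic symbol, including explicit-hydrogen atoms as in `[2H]` —
  with isotope digits, chirality marks (`@`, `@@`), H-counts (`H`, `H3`)
  and charge groups (`+`, `-`, `+2`, `++`) as separate non-atom tokens.
* A ring closure is one token: a digit, or `%` plus two digits. A bond
  symbol before a ring digit (`=1`) stays a separate BOND token.
  Directional bonds `/` and `\` are BOND tokens; `.` is a DOT token.

Two invariants follow and are enforced by tests over a 212-string fixture
set: concatenating token texts reproduces the input exactly, and the
number of ATOM tokens equals the molecule's heavy-atom count as reported
independently by two toolkits (OpenBabel and RDKit). The second invariant
is what makes per-atom score vectors attachable: atom *k* is the *k*-th
ATOM token. Atom-class maps (`[CH4:1]`) are not lexed and raise an error;
mainstream toolkits do not emit them in canonical output. The input string
is rendered exactly as written and never re-canonicalized — scores are
bound positionally, and re-canonicalization would silently desynchronize
them.

All indices in the R API (token positions, atom indices) are 1-based, as
is idiomatic in R; the exported hover-map JSON uses the same convention
and documents it.

## Binding scores and the colormap domain

A raw score vector is admissible at exactly two lengths: the atom count
(spread onto ATOM tokens in order, 0.0 elsewhere) or the token count
(positional). Anything else is a shape error that names both admissible
lengths, because off-by-one score vectors are the most common user error
in practice.

The *colormap domain* `(min, 0, max)` is the score interval mapped onto
the palette. By default it is symmetric at the molecule's largest absolute
score, so the strongest color is always reached. Normalization divides
positive scores by `max` and negative scores by `|min|` (asymmetric
domains scale each sign against its own bound) and clamps to [-1, 1]:
values beyond the domain get full-height bars and endpoint colors, which
is also the mechanism behind the *sign-only* view — a domain of
±1e-5 sends every nonzero score to ±1. An all-zero score vector has
nothing to scale against; the fallback domain is (-1, 1) with a warning.

*Thresholds* are fractions in [0, 1] of the domain maximum. A threshold
`t` highlights atoms with `|score| >= t * max` — the comparison is
inclusive (a score exactly at the cutoff is highlighted), and zero scores
are never highlighted, so threshold 0 means "every atom with any signal".
Highlight sets are therefore nested along an ascending threshold list.
When the threshold list is empty the diagram shows no highlight and the
bar chart falls back to guide lines at fractions 0.5 and 1.

## Diverging palettes and lightness correction

Built-in palettes are 5-class colorblind-safe diverging schemes after the
Color Brewer families (`RdBu`, `PiYG`, `PuOr`, `BrBG`); the hex anchors
are recorded in the source and not claimed to match any other tool's
exact colors. Custom palettes must be odd-length with a neutral middle
(this is validated), and can be supplied inline or as a JSON color-list
file.

Mapping a normalized score to a color interpolates the corresponding half
of the palette piecewise-linearly in CIELAB, then replaces the lightness
channel with a linear ramp from the neutral middle's L\* to the
endpoint's L\*. This guarantees, by construction, that lightness decreases
strictly monotonically with |score| toward both endpoints — so magnitude
is readable from lightness alone even where hue discrimination fails.
Exact anchor colors are returned literally at 0 and ±1 (no round trip
through color-space conversion), which is what makes "scores at the
domain endpoint get the endpoint color exactly" a testable identity.

## Resolving hover semantics as data

Four substructure semantics are resolved per token:

* **atom** — an ATOM token maps to its atom, and inversely an atom maps
  to its token.
* **branch** — a parenthesis maps to the whole matched span (nesting
  resolved with a stack; verified against an independent brute-force
  character-level matcher), atoms of nested branches included.
* **group** — a bracket token, or any token inside the group, maps to the
  bracket span and its single atom.
* **ring** — a ring-closure digit maps to both partner digits and the
  atoms of the smallest perceived ring through the closure bond. The
  closure bond joins the attachment atoms preceding the two digits; the
  smallest ring is the shortest path between them after removing that
  bond from the bond graph. If several smallest rings exist, the one
  with the lowest atom-index sum is chosen — an explicit deterministic
  tie-break. Ring highlighting covers atoms only; highlighting the ring
  *bonds* as well would be a reasonable alternative the renderer does
  not currently implement.

Bond tokens resolve to the two atoms they join (tracking the attachment
atom through branches, so the `=` in `CC(C)=O` correctly joins the
second carbon and the oxygen); a dot resolves to itself with no atoms,
since it denotes a disconnection. Structural errors — unmatched
parenthesis or bracket, unpaired ring digit — are raised at resolution
time naming the token position, because the lexer itself is deliberately
lenient (a partial string still tokenizes losslessly).

`exportHoverMap()` tabulates all of this per molecule; the renderer embeds
it as a `data-hovermap` attribute and the gallery script only replays it.
Browser-side code makes no highlighting decisions, which keeps every
decision unit-testable in R.

## Rendering choices

The drawing stack is deliberately plain: panels are composed as SVG 1.1
text with fixed two-decimal coordinate formatting, so a render is
byte-reproducible for identical input, configuration and toolkit version.
Numeric choices that the underlying idea leaves open are fixed as:

* heatmap kernel: one radial gradient per scored atom, radius 0.9 x the
  median bond length of the depiction, peak alpha 0.75 x |normalized
  score|, fading to transparent at the rim; positive and negative marks
  live in separate groups, negatives first;
* drawing order: heatmap layers *beneath* the skeletal structure, so
  bond lines and atom glyphs stay crisp over the color fields;
* threshold circles: white stroke, radius `fontSize + medianBond x
  (|v| - t)` — the farther a score is past the threshold, the larger the
  circle;
* per-atom score labels (optional) formatted to 2 decimal places;
* atom glyphs element-colored by default (CPK-like hex set in the
  source), or black with `blackAtoms`.

2-D coordinates come from the toolkit's depiction of the SMILES as
written, read directly from its structure block rather than scraped from
rendered output. Atom order is the string's atom order, which both
coordinates and scores rely on.

## Substitution sensitivity scores

For a black-box predictor `f` over SMILES strings and a token vocabulary
`V`, the sensitivity score of token `i` is

```
s_i = f(x) - mean_{v in V} f(x with token i's text replaced by v)
```

a positive score meaning the prediction is expected to drop if the token
is disturbed. Design points:

* Substitution is textual, on the string as written — not a graph edit.
  Substituted strings can be syntactically invalid; the predictor marks
  them rejected (`NA`) and they are excluded from the mean. If *every*
  substitution at a position is rejected the score is 0 with a warning.
  This skip policy is a declared choice of this package.
* The original token is included in the average whenever its text is in
  the vocabulary (no self-exclusion).
* The attribution is exhaustive and order-independent: permuting the
  vocabulary cannot change any score, and a constant predictor yields
  exactly zero everywhere (both are tested identities).

The bundled toy predictor is the toolkit's molecule-level Wildman-Crippen
logP: deterministic, milliseconds per molecule, structure-symmetric.
Its default vocabulary is the uppercase organic-subset atoms
(`B C N O P S F Cl Br I`): substituting structural tokens almost always
produces invalid strings that the skip policy drops, so atom
substitutions carry the signal, and symmetric substitutions on
symmetry-equivalent atoms yield isomorphic molecules — hence *exactly*
equal scores, which the suite asserts on hexabromobenzene. Any real model
can be plugged in through `smilesPredictor()` (a vectorized
SMILES-to-number function plus a vocabulary).

## Crippen contributions as comparator

`crippenScores()` returns the per-atom additive decomposition of the
Wildman-Crippen logP model, computed with RDKit, with hydrogen
contributions folded into their heavy-atom neighbours. Folding makes the
vector sum exactly to the molecule-level Crippen logP — an additivity
contract the tests verify against an independent implementation of the
same published model (OpenBabel's), which agrees to ~1e-3 on the fixture
molecules. These contributions are the customary ground-truth-style
comparator for learned logP attributions: render them side by side with
substitution scores in one gallery and the agreement (or disagreement) of
sign and magnitude per atom is directly visible.

## The fixture generator

`makeFixtures(n, seed, method)` draws from a fixed 26-molecule list of
drug-like and feature-covering SMILES (aromatics, fused and bridged
rings, brackets, charges, isotopes, stereo bonds, both two-letter
halogens) and equips each record with per-atom Crippen contributions,
substitution scores against the toy predictor, or seeded per-token
Gaussian noise. Per-record RNG streams are derived from `(seed, index)`,
so output is deterministic and *prefix-stable*: record 3 of
`makeFixtures(10, seed)` equals record 3 of `makeFixtures(3, seed)`.

What the generator emulates is the *shape* of real XAI output — score
vectors of both admissible lengths, signed, molecule-scaled — not its
distribution: real model attributions are correlated across neighbouring
tokens and across related molecules, and nothing here imitates a trained
model's error structure. Passing tests therefore demonstrate the
mechanics (binding, normalization, resolution, rendering) on realistic
inputs; they say nothing about any particular model's explanations.

## Problem sizes and limits

The property suites run the full pipeline over 212 fixture SMILES and
render panels for molecules up to ~30 tokens; the complete suite runs in
well under a minute. Molecules beyond 999 atoms are rejected by the
structure-block reader (fixed-width format); this is far beyond the
size at which a token bar chart stops being readable anyway. Known
limitations: no per-bond scores (atoms and tokens only), no live
event handling beyond the replayed hover maps, no SELFIES/InChI
tokenization, and no 3-D depiction.
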