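# smivis record file schema (version 1.0)

A record file is UTF-8 JSON: either a bare array of record objects, or

```json
{
  "schema_version": "1.0",
  "records": [ ... ]
}
```

## Record object

| field        | type               | required | meaning                                                        |
|--------------|--------------------|----------|----------------------------------------------------------------|
| `smiles`     | string             | yes      | SMILES string, rendered exactly as written (never re-canonicalized) |
| `scores`     | array of numbers   | no       | attribution scores; length must equal the molecule's atom count (per-atom) or the SMILES token count (per-token) |
| `attributes` | object (string values) | no   | ordered key/value rows shown under the bar chart               |
| `config`     | object             | no       | per-record visual-config override; any `panelConfig()` argument: `palette`, `domain`, `thresholds`, `showScoreLabels`, `blackAtoms`, `signOnly`, `geometry` |
| `id`         | string             | no       | record identifier; defaults to the 1-based record index        |

Unknown fields are preserved on a save/load round trip.

Score-vector semantics: per-atom vectors are spread onto the ATOM tokens in
order of appearance with 0.0 assigned to every non-atom token; per-token
vectors map positionally. The order of atoms is the order of atom tokens in
the SMILES string as written. Any other vector length is rejected at load
(skipped with a warning by default; fatal with `strict = TRUE`).

## Palette files

A palette referenced by file path (`*.json`) is a JSON array of colors,
odd-length, ordered negative endpoint -> neutral middle -> positive
endpoint, e.g. `inst/extdata/palette-teal-maroon.json`.

## Hover-map sidecar

`exportHoverMap()` serializes to JSON as

```json
{
  "tokens": [ {"kind": "RING", "tokens": [2, 8], "atoms": [1, 2, 3, 4, 5, 6]}, ... ],
  "atoms":  [1, 3, 4]
}
```

with one `tokens` entry per SMILES token (the tokens and atoms highlighted
when it is hovered) and `atoms[k]` the token position bound to atom k. All
indices are 1-based. The same structure is embedded in each rendered SVG
panel's `data-hovermap` attribute.
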