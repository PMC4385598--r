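# File formats

## Dataset CSV (`generate`, `train --data`, `evaluate --data`)

Comma-separated, dot decimal, header row:

    L,a,b,A1,A4,B4,C4,D4

`L,a,b` are the CIELAB coordinates of the fired specimen; `A1..D4` are the
mass fractions of the five dentin porcelain powders (non-negative multiples
of 0.08 summing to 0.40 for specimen-style data). Headerless files are
accepted by `read_dataset(columns = ...)` with an explicit column order.

## Prediction input CSV (`predict --data`)

Any CSV with at least the columns `L,a,b` (extra columns ignored).

## Model JSON (`train --out`, `predict --model`)

One JSON object with fields:

- `config`: `n_in`, `n_hidden`, `n_out`, `activation`, `lambda`
- `weights`: `W` (list of rows, hidden x in), `V` (list of rows,
  out x hidden), `theta_hidden`, `theta_out`
- `normalizer`: per-dimension `min`, `max`, and target interval `lo`, `hi`
- `method`, `profile`, `seed`

## Training history CSV (`train --history`)

Columns `epoch,objective` — the training objective (mean squared error over
samples x outputs) after each full-batch epoch.

## Hidden-node sweep CSV (`size-hidden --out`)

Columns `h,rep,error,diverged` — one row per (candidate hidden-node count,
repetition); `error` is the aggregate test error E_MSE (printed metric).

## Comparison CSV + summary JSON (`compare --out`)

CSV columns `method,trial,mse` (method `bp` or `gabp`). The sidecar
`<out>.summary.json` records the resolved parameters and the per-arm mean
and variance.

## Sidecar JSON

Every artifact-writing subcommand writes `<out>.json` beside its artifact
with the fully resolved parameters and seed needed to regenerate it.

## Example data shipped with the package

- `extdata/specimen_examples.csv` — eleven example specimen measurements
  (CIELAB color and powder recipe) in the dataset CSV layout.
- `extdata/prediction_examples.csv` — seventeen example (actual output,
  expected output) prediction pairs; columns `actual_*` then `expected_*`
  for the five powders.
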