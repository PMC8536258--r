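# clonecensus input/output schemas

## Per-ovariole records (CSV, `read_ovariole_records()` / `simulate --out-records`)

Header row, one row per scored ovariole.

| column         | type    | meaning                                                    |
|----------------|---------|------------------------------------------------------------|
| `ovariole_id`  | any     | identifier, kept verbatim                                  |
| `n_r1_ec`      | integer | marked region-1 escort cells                               |
| `n_r2a_ec`     | integer | marked region-2a escort cells                              |
| `n_fsc`        | integer | marked follicle stem cells                                 |
| `fc_locations` | string  | semicolon-joined FC location codes from `I,G,E1,E2,E3,E4`; empty = no marked FCs |
| `basal_stalk`  | string  | `yes` / `no` / `not_imaged` (optional, default `not_imaged`) |
| `scoring_age`  | string  | `eclosion_day0` / `adult_day2` (optional, default `eclosion_day0`) |

Location codes follow the anterior-to-posterior scheme: `I` immediately
posterior to the Fas3 border (region 2b), `G` germarial (region 3), `E1`-`E4`
egg chambers with `E4` the most mature.

## Aggregated category table (CSV, `read_category_table()`, `--counts`)

`#key: value` header comments carry experiment totals, then a header row and
one line per clone category plus one `unlabeled` line:

```
# n_scored: 207
# total_ec: 253
# total_fsc: 111
category,n,mean_ec,mean_fsc
EC_only,46,2.4,
EC_FSC,24,4,4
FSC_only,3,,4.6666667
FC_only,9,,
EC_plus_FC,16,2.9,
unlabeled,109,,
```

`total_ec` / `total_fsc` are optional (reconstructed from the means when
absent); empty mean fields mean "not applicable".

## Production totals (CSV, `table2 --totals`)

Columns `x_r1`, `y_r2a`, `z_fsc` (summed marked r1 ECs, r2a ECs, FSCs over
all clones of one induction time) plus any identifying columns, one row per
clone-induction time.

## Simulation config (YAML or JSON, `simulate --config`, `recover --config`)

Fields of `simulation_config()`; `true_freqs` is a mapping with keys
`p_ec`, `p_ecfsc`, `p_fsc`, `p_fc`. Example:

```yaml
n_ovarioles: 5000
true_freqs: {p_ec: 0.63, p_ecfsc: 0.13, p_fsc: 0.05, p_fc: 0.19}
sigma_true: 0.3
labeled_fraction: 0.473
seed: 1
```

## Reports

All subcommands emit JSON (`--out`, default stdout). The `census` report
contains `observed` (category frequencies), `sigma` (value, mode, grid search
table and residual when estimated), `freqs` (the four single-lineage type
frequencies), `yields`, `total_lineages`, `census` (`n_total` and per-type
precursor counts) and `notes`. Logging goes to stderr only.
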