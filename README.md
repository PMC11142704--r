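# psinter

Multimodal joint representations for protein-small molecule interaction
prediction in R.

`psinter` is for computational biologists and cheminformaticians who need
to predict properties of protein-small molecule pairs — drug-target
binding affinities (pK<sub>d</sub>), enzyme-substrate relationships
(binary, typically at a 1:3 positive-to-negative ratio), or Michaelis
constants K<sub>M</sub> — and, just as importantly, to *evaluate* such
models honestly: with concordance and r<sub>m</sub>² metrics, cold-target
/ cold-drug splits, and similarity-stratified error analysis.

## The model

A protein sequence and a SMILES string are tokenized and embedded with
pre-learned (frozen) per-token embeddings, then processed **in a single
attention sequence**:

```
[ cls | p_1 ... p_Lp | sep | s_1 ... s_Ls ]
```

where `cls` (all ones) and `sep` (all zeros) are constant rows and the
protein/molecule token embeddings are mapped into the shared hidden
space (H = 768 = 6 heads x 128 at full scale) by trainable ReLU pooling
layers. A stack of bidirectional attention layers lets every residue
token attend to every chemistry token while the joint representation is
formed; the updated `cls` row is the learned pair representation.

Predictions do not come from the encoder head alone. Three
gradient-boosted tree models are trained on (i) the `cls` vector,
(ii) the concatenated mean-pooled protein and molecule embeddings, and
(iii) all three blocks, and the final output is the simplex-weighted
mean

&nbsp;&nbsp;&nbsp;&nbsp;ŷ = w₁p₁ + w₂p₂ + w₃p₃,&nbsp;&nbsp; wᵢ ≥ 0, Σwᵢ = 1,

with hyperparameters chosen by random search on a validation set and
the weights by exhaustive simplex-grid search (step 0.05). Evaluation
metrics include MSE, R², Pearson r, the concordance index (tie-aware),
r<sub>m</sub>² = r²(1 − √(r² − r₀²)), accuracy, MCC, and ROC-AUC.

A deterministic synthetic-data generator plants a recoverable
protein x molecule interaction signal (motif counts x fragment
indicators), so the entire pipeline is testable at desk scale with no
pretrained downloads. See the methods vignette
(`vignettes/psinter-methods.Rmd`) for the full model description and
every documented design choice.

## Worked example

Run the complete workflow — simulate a 1500-pair dataset with planted
signal, embed, split 80/10/10, train the joint encoder, extract
representations, search gradient-boosting hyperparameters, fit ensemble
weights, and evaluate on the untouched test set — with single-modality
baseline models for comparison:

```r
library(psinter)
res <- run_experiment(pipeline_config(list(seed = 5, baselines = TRUE)))
print(res)
```

```
<pipeline_result> task: regression, 1 repeat(s), 130s total
                    metric   mean sd
1                      mse 0.3150 NA
2                r_squared 0.7489 NA
3                pearson_r 0.8676 NA
4        concordance_index 0.8110 NA
5               rm_squared 0.7400 NA
6                   rm2_r2 0.7528 NA
7                  rm2_r02 0.7525 NA
8       r_squared_cls_only 0.7024 NA
9    r_squared_pooled_pair 0.7473 NA
10           r_squared_all 0.7021 NA
11  r_squared_protein_only 0.1122 NA
12 r_squared_molecule_only 0.2187 NA
```

Reading the output: the full ensemble explains ~75% of test-label
variance (`r_squared` 0.75, close to the noise ceiling of the
generator's default effect size and noise), correctly orders 81% of
comparable test pairs (`concordance_index`), and shows no
calibration-scale divergence (`rm2_r2` vs `rm2_r02`). The three
ensemble members each sit near 0.70-0.75. The decisive rows are the
baselines: a boosted model seeing only the protein representation
(0.11) or only the molecule representation (0.22) cannot recover the
planted *interaction* — only the joint pipeline can.

Individual stages are exported (`generate_dataset()`,
`embed_dataset()`, `make_split()`, `train_encoder()`,
`extract_representations()`, `random_search()`,
`fit_ensemble_weights()`, `finalize_models()`, `metric_report()`,
`stratified_metrics()`, ...), and a thin command-line interface with
the same stages as subcommands ships in `inst/scripts/psinter`.

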