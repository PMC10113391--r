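# Default evaluation settings (see challenge_config()).
threshold: 0.5          # binarisation threshold for the MCC
null_draws: 10000       # random prediction sets per null distribution
percentile: 0.95        # significance percentile of the null
percentile_type: interpolation   # or nearest_rank
aupr_grid: challenge    # moving threshold 1 -> 0.5 (or "full")
cv_folds: 5
cv_repeats: 10
signature_sizes: [4, 200]
subset_cap: 1000        # max sampled combinations per subset size
seed: 1
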