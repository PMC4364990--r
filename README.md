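# emosim

An event-driven, spatially explicit agent-based model of a small primate
group in which emotions regulate social behaviour, built to ask a
mechanistic question from behavioural ecology: **does partner-specific
reciprocal affiliation require emotional bookkeeping, and how selective
must partner choice be for it to emerge?**

Twenty agents on a continuous torus carry a fixed dominance strength
`myDOM`, an emotional state (arousal, anxiety, satisfaction on [0, 1]),
fixed `FEAR_ij = myDOM_j − myDOM_i`, and dynamic `LIKE_ij ∈ [0, 1]`
attitudes. In the **dynamic-attitude model**, LIKE integrates grooming
received from each partner:

    LIKE_ij(t_n) = max( (LHW·LIKE_ij(t_{n−1}) + Δt·PARTNER_SAT_ij(t_n)) / (LHW + Δt),
                        PARTNER_SAT_ij(t_n) ),         LHW = 1 DAY = 720 min

In the **fixed-attitude control**, `LIKE_ij = max(0, 0.243 − 0.36·|Δdom|)`
is frozen. The *LIKE-partner-selectivity* parameter `LPS ∈ [0, 1)`
controls how strongly LIKE biases affiliative partner choice (0 = null
model, identical in both variants; 0.99 = near-exclusive preference).
The package also implements the full observation protocol (one-zero
proximity sampling every 3.5 DAYS, dyadic hourly-rate matrices averaged
over the final YEAR) and the social-matrix statistics: rowwise Kendall
**Tau-Kr** reciprocity, Shannon/Buzas–Gibson evenness
`H* = exp(H)/(N−1)`, rank-distance categorisation (similar vs distant at
|Δdom| < 0.35), partner-specificity SD, and rowwise Pearson
predictability pooled by Fisher-z.

The hot loop (an activation-queue simulator with 3-second movement
substeps) is C++ via Rcpp; runs are bit-reproducible from `(config,
seed)`, and at `LPS = 0` the two model variants produce bit-identical
event logs under a shared seed.

## Worked example

A desk-scale run (1-week burn-in, 8-week recorded window) of the
bookkeeping model at high selectivity:

```r
library(emosim)
cfg <- scaled_config(variant = "dynamic", lps = 0.99)
run <- run_simulation(cfg, seed = 42)
print(run)
#> <emo_run> dynamic model, LPS = 0.99, seed = 42
#>   87668 directed events recorded over 40320 min (16 samples)
#>   mean grooming given: 6.75 min/h per individual

s <- summarize_run(run)
round(c(taukr = s$groom$taukr, h_star = s$groom$mean_h_star,
        sd = s$groom$partner_specificity,
        uphill_submission = s$submissive_signal$uphill_fraction), 3)
#>             taukr            h_star                sd uphill_submission
#>             0.872             0.642             0.161             0.909

rc <- rank_category_means(run$rates$groom, cfg$dom)
round(c(similar = rc$similar, distant = rc$distant), 3)
#> similar distant
#>   0.541   0.153
```

Reading: grooming is strongly reciprocated (Tau-Kr 0.87 vs ≈ 0.33 in
the null model), concentrated on fewer partners (mean H\* 0.64 vs ≈ 0.94
at LPS = 0), individualized beyond rank distance (partner-specificity SD
0.16 vs ≈ 0.07 in the fixed control), flows preferentially between
similar-ranked dyads (0.54 vs 0.15 min/h), and submissive signalling
remains a subordinate's behaviour (91% up-hierarchy).

The full experiment grid (2 variants × LPS ∈ {0, 0.5, 0.9, 0.95, 0.99} ×
10 replicates at the 2-YEAR scale) is:

```r
sw <- run_sweep(run_config(), base_seed = 1, out_dir = "sweep_out")
```

A command-line front end mirrors this: `inst/exec/emosim`
(`emosim validate|run|sweep|stats`, JSON configs, CSV matrix bundles).

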