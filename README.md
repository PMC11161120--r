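# hocoord

Dynamic inference of higher-order spiking coordination in neuronal
ensembles, from single-trial binned spike trains.

## The problem

Neurons spike together. Some of that coincidence is chance — independent
units with the right rates coincide too — and some reflects genuine
coordination, either *endogenous* (driven by the ensemble's own recent
spiking) or *exogenous* (driven by something unobserved). Pairwise
correlation measures cannot see beyond second order, and most model-based
analyses of higher-order structure need repeated trials to track dynamics.
`hocoord` implements an adaptive, single-trial framework that detects
significant *r*th-order coordination (three neurons firing together, four,
…) and tracks its strength and sign over time.

## The model and test

Binned spiking of *C* neurons is a discretized **marked point process**:
each bin holds at most one event, labelled by which of the 2^C − 1
simultaneous-spiking patterns occurred (pattern `(1,1,1,0,0)` is mark 7 in
the little-endian coding). The per-bin label follows a multinomial
logistic GLM whose log-odds for mark *m* versus no event are

    u_t(m) = mu_t(m) + x_t' theta_t(m)

with base rates `mu`, sparse couplings `theta` to lagged spiking of every
neuron (the ensemble history `x_t`), and the no-event outcome as reference.
Parameters are tracked over windows of `W` bins by maximizing the
forgetting-factor weighted log-likelihood
`(1 - beta) * sum_i beta^(k-i) l_i`, with greedy (orthogonal matching
pursuit) selection of the history couplings; de-sparsified estimates admit
normal confidence intervals.

For each window, the base rates of the *r*th-order marks are pinned at the
level implied by conditional independence of their neurons given history,
and the **adaptive de-biased deviance difference** between the full and
reduced fits is referred to its chi-square(M) limit (M = number of tested
marks). Its non-centrality is tracked by a state-space smoother and
summarized by a signed **Youden J-statistic** in (−(1−α), 1−α): values near
+1 mean strongly facilitated coordination, near −1 strong suppression, 0
no rejection. Comparing the history-dependent and history-independent
variants separates endogenous from exogenous coordination.

## A worked example

Simulate a 5-neuron ensemble in which a step exogenously facilitates all
ten 3rd-order patterns during the second half, fit the adaptive model, and
test for 3rd-order coordination:

```r
library(hocoord)
sc  <- scenario_step(n_realizations = 1, nbins = 4000, seed = 11)[[1]]
fit <- mkpp_fit(sc$spikes, W = 10, beta = 0.99, history = TRUE, L = 5)
ct  <- coordination_test(fit, r = 3, alpha = 0.01)
ct
#> rth-order coordination test: 400 windows, alpha = 0.01, beta = 0.99, W = 10
#>   model: history-dependent; bias estimator: none
#>   r = 3 (M = 10): rejected 189/400 windows (179 facilitation, 10 suppression); median D = 22.5
head(subset(ct$results, window > 300), 3)
#>     window time_start r        D    nu_hat h         J sum_gamma
#> 301    301       3.00 3 28.72840 18.11385 1 0.6587958  4.780186
#> 302    302       3.01 3 32.49090 18.40539 1 0.6696988  4.754553
#> 303    303       3.02 3 30.62872 18.64212 1 0.6783879  4.553443
```

The facilitated half is detected: windows past the step reject the
independence null (`h = 1`), the smoothed non-centrality `nu_hat` rises,
the signed J-statistic approaches +1, and `sum_gamma` (the summed exogenous
factors of the ten tested marks, in log-odds) is positive. The first half
is essentially quiet (the ~10 scattered rejections over 400 windows at
alpha = 0.01 are the expected false-positive rate plus the step
transient). `plot(ct)` draws the J trajectory; `confint(fit)` gives
de-sparsified confidence intervals for the base rates;
`smoothed_pearson()`, `spiking_regularity()` and `mark_cif_difference()`
compute the classical single-trial comparison measures.

A command-line interface over the same functions ships in
`inst/scripts/hocoord` (subcommands `simulate`, `fit`, `test`,
`baselines`).

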