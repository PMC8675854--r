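library(bgctdyn)
## landscape stage under a different --seed (42)
sL <- stage_seed(42, "landscape")
pbi <- bgct_params(T42 = (1.614213+2.340126)/2, T53 = 0)
lsb <- potential_landscape(estimate_pss(pbi, noise_spec(D=1e-6, seed=sL), ensemble=200))
cat("seed42 bistable minima:", nrow(lsb$minima), "\n")
posc <- bgct_params(T42 = (4.055343+5.762464)/2, T53 = 4)
lso <- potential_landscape(estimate_pss(posc, noise_spec(D=1e-6, seed=sL+1), ensemble=200))
cat("seed42 ring:", lso$ring_detected, "\n")
## README worked-example outputs
print(attractor_census(bgct_params(T42 = 5, T53 = 4)))
print(find_equilibria(bgct_params(T42 = 2, T53 = 0)))
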