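# Shared ground truths and small constructors used across the test files.

cop_truth <- default_polymer_truth()   # eta0 1e4, lam 0.5, a 2, n 0.3; WLF 8/120 @150

toy_api <- material_props("ToyAPI", tg = 50, delta_cp = 0.30, melting_point = 150)
toy_polymer <- material_props("ToyPolymer", tg = 110, delta_cp = 0.40)

# z-score helper for parameter-recovery checks
z_score <- function(est, truth, se) (est - truth) / se
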