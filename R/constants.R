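# Baseline 3-year progression-free survival of the default surrogate risk
# score at its centering profile. Calibrated once against the reference
# synthetic population (500,000 covariate draws) so that the comparator-arm
# marginal event rate equals 3.8 per 1000 person-years; see the methods
# vignette for the calibration procedure.
KB_S0_3Y_DEFAULT <- 0.9938972
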