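# homoscedastic replication design, desk scale
design = homoscedastic
N = 50
T = 50
tau = 0.5
estimators = iv_mdqr,mdqr,iv_feqr
reps = 200
seed = 7
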