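timestamp=2026-09-12T05:57:37
tau_broad=0.2
tau_specific=0.8
p_robust_cut=0.005
p_max_cut=0.05
min_species=68
long_lived_ml=30
k_strong=10
n_perm=500
n_draws=10000
seed=1
command=frobnicate
args=
timestamp=2026-09-12T06:07:27
tau_broad=0.2
tau_specific=0.8
p_robust_cut=0.005
p_max_cut=0.05
min_species=68
long_lived_ml=30
k_strong=10
n_perm=500
n_draws=10000
seed=1
command=frobnicate
args=
timestamp=2026-09-12T06:23:06
tau_broad=0.2
tau_specific=0.8
p_robust_cut=0.005
p_max_cut=0.05
min_species=68
long_lived_ml=30
k_strong=10
n_perm=500
n_draws=10000
seed=1
command=frobnicate
args=
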