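# Reprogramming of a terminally differentiated cell on a 3-level
# hierarchy, standard parameter set (defaults), 1000 replicate cells.
run.experiment = reprogram
run.levels = 3
run.n_trajectories = 1000
run.max_cycles = 200
run.seed = 7
run.out_dir = epihier-out

# standard parameters, spelled out for reference (these equal the
# defaults and could be omitted)
params.G = 25
params.H = 40
params.F = 2000
params.J = 3000
params.a = 0
params.b = 0.3
params.beta = 1
params.updates_per_phase = 50000

policy.k = 1
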