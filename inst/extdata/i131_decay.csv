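particle,energy_kev,yield
photon,29.46,0.0140
photon,29.78,0.0259
photon,33.60,0.0090
photon,80.185,0.0262
photon,177.21,0.0027
photon,284.305,0.0614
photon,325.78,0.0027
photon,364.489,0.8150
photon,502.99,0.0036
photon,636.989,0.0717
photon,642.72,0.0022
photon,722.911,0.0177
electron_mean,191.9,1.0
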