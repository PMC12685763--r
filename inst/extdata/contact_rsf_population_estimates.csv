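term,beta,se
anthropogenic,-1.051,0.513
fruiting_plant,-0.635,0.307
denning_tree,-0.521,0.184
meadow,-0.609,0.302
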