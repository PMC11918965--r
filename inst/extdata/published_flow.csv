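quantity,value
n_enrolled,6740
n_eligible,4832
n_person_trials,11482
n_vaccinated_person_trials,3987
n_vaccinated_preuniversal,3191
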