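osf,native
subject,subject_id
sub,subject_id
block_number,block
trial,trial_index
agent,recipient
choice_1,choice1
transition_type,transition
state_2,state2
choice_2,choice2
shock_outcome,outcome
rt_1,rt1
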