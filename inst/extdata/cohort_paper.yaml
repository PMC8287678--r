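# cohort generator settings matching the 77-subject study structure
n_case: 38
n_control: 39
p_dir_pos_case: 0.6052631578947368    # 23/38
p_dir_pos_control: 0.3589743589743590 # 14/39
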