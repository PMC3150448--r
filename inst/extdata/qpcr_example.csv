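target,E_target,Ct_target,E_ref,Ct_ref,replicate
orphan_immunity,1.95,22.1,1.98,14.3,1
orphan_immunity,1.95,22.4,1.98,14.5,2
orphan_immunity,1.95,21.9,1.98,14.2,3
orphan_toxin_ct,2.01,28.7,1.98,14.3,1
orphan_toxin_ct,2.01,29.1,1.98,14.5,2
orphan_toxin_ct,2.01,28.9,1.98,14.2,3
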