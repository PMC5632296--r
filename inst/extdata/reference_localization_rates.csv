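domain,class,false_positive_pct,false_negative_pct
root,root_tip,0.03,0.12
shoot,leaf_tip,0.24,0.12
shoot,leaf_base,0.22,0.10
shoot,ear_tip,0.08,0.02
shoot,ear_base,0.11,0.05
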