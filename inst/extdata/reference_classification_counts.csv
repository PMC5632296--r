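domain,class,correct,misclassified
root,root_tip,2904,73
root,root_negative,5687,65
shoot,leaf_tip,2225,113
shoot,leaf_base,2299,52
shoot,ear_tip,686,15
shoot,ear_base,765,23
shoot,shoot_negative,6110,136
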