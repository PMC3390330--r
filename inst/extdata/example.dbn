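>hpk_plus_kissing_synthetic
((..[[..))..]].((.[[.)).{{..]]..}}
>triple_h_pseudoknot_synthetic
([)]([)]([)]
>hairpin_synthetic
((((....))))
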