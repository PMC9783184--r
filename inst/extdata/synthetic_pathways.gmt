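SYN_LIPOGENESIS	synthetic lipogenesis-like set	gene0001	gene0002	gene0003	gene0010	gene0025	gene0031	gene0044	gene0052
SYN_PENTOSE_PHOSPHATE	synthetic pentose-phosphate-like set	gene0005	gene0017	gene0023	gene0038	gene0061	gene0072	gene0088
SYN_ADIPOGENESIS_EARLY	synthetic early-adipogenesis set	gene0009	gene0012	gene0019	gene0027	gene0036	gene0049	gene0057	gene0063	gene0071
SYN_MEMBRANE_LIPID	synthetic membrane-lipid set	gene0008	gene0014	gene0021	gene0033	gene0042	gene0055
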