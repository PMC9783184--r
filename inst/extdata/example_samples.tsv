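sample_id	group
WDLPS_1	WDLPS
WDLPS_2	WDLPS
WDLPS_3	WDLPS
DDLPS_1	DDLPS
DDLPS_2	DDLPS
DDLPS_3	DDLPS
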