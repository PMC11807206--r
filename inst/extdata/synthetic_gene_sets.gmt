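SET_METAL_TRANSPORT	synthetic metal ion transport set	GENE00001	GENE00002	GENE00003	GENE00004	GENE00005	GENE00006
SET_CELL_DEATH	synthetic cell death regulation set	GENE00005	GENE00006	GENE00007	GENE00008	GENE00009	GENE00010	GENE00011
SET_HOUSEKEEPING	synthetic housekeeping set	GENE00020	GENE00021	GENE00022	GENE00023	GENE00024	GENE00025	GENE00026	GENE00027	GENE00028	GENE00029
SET_SIGNALING	synthetic signaling set	GENE00030	GENE00035	GENE00040	GENE00045	GENE00050	GENE00055
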