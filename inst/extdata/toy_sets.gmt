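immune_response	toy set	GN0001	GN0002	GN0003	GN0004	GN0005
antigen_presentation	toy set	GN0003	GN0006	GN0007	GN0008
t_cell_signaling	toy set	GN0002	GN0009	GN0010	GN0011	GN0012	GN0013
cell_cycle	toy set	GN0014	GN0015	GN0016
dna_repair	toy set	GN0017	GN0018	GN0019	GN0020
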