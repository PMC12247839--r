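hu_lo: 2500
hu_hi: 20000
bth_radius: 3
sheet_scales: 1, 1.5, 2
sheet_alpha: 0.5
sheet_beta: 0.5
sheet_c_frac: 0.5
vote_sigma: 2
vote_saliency: plate
dilate_half_kernel: 2
dilate_shape: cube
model: classical-only
tile_edge: 352
tile_overlap: 0
topography: edt
connectivity: 26
min_voxels: 27
overlap_min: 0.5
include_missing: TRUE
out_dir: .
seed: 1
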