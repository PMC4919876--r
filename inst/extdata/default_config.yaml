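image_height: 1000
image_width: 1000
magnification: 40.0
ccd_pixel_size: 11.0
scalebar_length: ~
grade: 0
cellularity_epithelial: 1.0
cellularity_stromal: 1.0
max_overlap: 0.6
overlap_domain: nuclei
psf_sigma: 1.0
noise_variance: 0.00025
stain_matrix:
- - 0.6402
  - 0.6479
  - 0.4128
- - 0.3906
  - 0.7662
  - 0.5102
cell_radius: 6.0
seed: 1
n_images: 1
render: full
canvas_size: 256
window_radius: 5
error_threshold: 0.1
n_cancer_lumen: 7
max_attempts: 100
tumour_prob_per_grade: 0.2
n_vertices_crypt: 72
k_polygon: 10
beta_shape: 0.05
independent_cyto_factors: yes
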