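# Demonstration configuration for run_pipeline(): a reduced-size synthetic
# study that completes in well under a minute. Analysis settings mirror the
# package defaults (cluster alpha .01, primary vertexwise p < .001, age
# groups 3-9 / 10-15 / 16-21, six disorders with FDR); only the mesh
# resolution and permutation count are scaled down.
seed: 7
mesh:
  subdivisions: 3
  radius: 100
  medial_wall_frac: 0.05
nulls:
  n_perm: 500
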