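# Shared fixtures: anchored engines and geometries used across tests.
# Anchors are the 0.003 Gy summaries: small voxels f_{z=0} = 0.65,
# spread 343%; large voxels f_{z=0} = 0.35, spread 205%.

vx_sm <- voxel_geometry_preset("vx-sm")
vx_lg <- voxel_geometry_preset("vx-lg")

engine_sm <- calibrate_from_anchor(0.003, 0.65, 3.43)
engine_lg <- calibrate_from_anchor(0.003, 0.35, 2.05)

# a delta model with negligible spread at the doses used (lambda = D / mu1)
delta_engine <- function(mu1 = 1e-5) single_event_model("delta", mu1 = mu1)

# per-dose histograms for one-hit fitting
fit_histograms <- function(engine, geom, doses, n_voxels = 1e5, seed = 42) {
  set.seed(seed)
  lapply(doses, function(D) {
    histogram_f(sample_field(engine, geom, D,
                             c(100, 100, ceiling(n_voxels / 1e4))))
  })
}
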