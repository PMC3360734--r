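# Shared phantom conditions for the test suite. The geometry is a scaled
# region (200 um gel, 80 um post opening, 8 x 4 um z-sections at 2 um xy
# pixels) so each phantom renders in well under a second while keeping all
# structures several voxels wide.

test_geom <- function(nz = 8L, vz = 4) {
  device_geometry(n_regions = 1, gel_width_um = 200, post_spacing_um = 80,
                  post_top_um = 30, post_depth_um = 20, margin_um = 40,
                  channel_width_um = 100, stack_depth_um = vz * nz,
                  n_z_sections = nz, voxel_size_um = c(vz, 2, 2))
}

# straight monolayer 8 um inside the gel (y = 48 um)
test_monolayer <- function(geom = test_geom(), r = 48) {
  ext_x <- 2 * geom$post_top_um + geom$post_spacing_um
  monolayer_curve(seq(0, ext_x, length.out = 4), rep(r, 4))
}

# two sprouts safely inside the post opening ([30, 110] um laterally)
test_sprouts <- function() {
  list(sprout_spec(60, length_um = 80, radius_um = 12, n_nuclei = 3),
       sprout_spec(88, direction_deg = 5, length_um = 70, radius_um = 12,
                   n_nuclei = 3))
}

test_voxel_yx <- c(2, 2)

# render -> preprocess -> detect -> fit -> metrics for one seed; returns
# the per-stage recovery errors against the analytic ground truth
recover_phantom <- function(seed, sd = 0.05, mean = if (sd > 0) 0.1 else 0,
                            sprouts = test_sprouts(),
                            geom = test_geom(), ml = test_monolayer(geom)) {
  ph <- render_stack(geom, ml, sprouts, noise_spec(mean, sd, seed))
  pp <- preprocess_stack(ph$stack)
  reg <- detect_gel_boundaries(pp, geom)
  sig <- combined_signal(z_proj(pp, "cyto"), z_proj(pp, "trans"))
  cv <- fit_monolayer(sig, reg, test_voxel_yx)
  m <- compute_metrics(pp, reg, cv, 10)
  gt <- ph$ground_truth
  list(
    line_err = max(abs(reg$boundary_lines$line1["intercept"] -
                         gt$boundary_lines$line1["intercept"]),
                   abs(reg$boundary_lines$line2["intercept"] -
                         gt$boundary_lines$line2["intercept"])),
    ml_err = max(abs(cv$control_r - ml$control_r)),
    M_rel = m$M_cyto / gt$metrics_true$M_cyto - 1,
    J_rel = m$J_cyto / gt$metrics_true$J_cyto - 1,
    Mh_rel = m$M_hoechst / gt$metrics_true$M_hoechst - 1,
    metrics = m, truth = gt$metrics_true, region = reg, curve = cv,
    stack = pp)
}

# z mean-projection of a channel (mirrors the internal used by the pipeline)
z_proj <- function(stack, channel) {
  apply(stack$channels[[channel]], c(1, 2), mean)
}
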