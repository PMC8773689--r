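# Shared fixtures, built once per test run. All synthetic and deterministic.

h_ligand <- dp6c()
h_receptor <- make_mini_receptor()
h_fixture <- make_bound_pose_fixture(h_receptor, h_ligand, seed = 11)
h_restraints <- compile_restraints(h_fixture$contacts, h_receptor, h_ligand)
h_xyzP <- as.matrix(h_receptor[, c("x", "y", "z")])

# small annealing schedule used by the docking tests (problem sizes chosen
# for the synthetic mini-systems)
h_dock_config <- function(...) {
  dock_config(stage1_levels = 26, stage2_levels = 10, n_prop = 90,
              cool = 0.85, prescreen_top = 10, prescreen_levels = 6,
              prescreen_prop = 30, ...)
}

# dense two-site reference system (tight CTD-like site, weak NTD-like site)
h_two_site <- two_site_system(0.001, 0.15, 0.1,
                              shift1 = c(0.15, 0.5), shift2 = c(-0.15, -0.25))

standard_schedule <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.8, 1.0)
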