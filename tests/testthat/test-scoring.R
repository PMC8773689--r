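test_that("NOE score reduces to simple means of per-probe minima", {
  prot <- tibble::tibble(res_id = c(59L, 74L, 111L),
                         res_name = c("TRP", "TRP", "LYS"),
                         atom = c("HE1", "HE1", "H"), element = "H",
                         x = c(0, 10, 20), y = 0, z = 0, charge = 0)
  lig <- build_glycan("IdoA2S")
  i_h2 <- which(lig$atoms$atom == "H2")
  # place the ligand's H2 at controlled distances from each probe in turn
  xyzL <- chain_xyz(lig)
  xyzL <- sweep(xyzL, 2, xyzL[i_h2, ] - c(0, 5, 0))  # H2 at (0,5,0)
  probes <- tibble::tibble(group = "W59.HE1", protein_res = 59,
                           protein_atom = "HE1")
  s <- noe_score(as.matrix(prot[, c("x", "y", "z")]), xyzL, prot, lig, probes)
  expect_equal(s$score, 5, tolerance = 1e-9)

  # probes at min distances 4, 6, 8 -> mean 6, via exhaustive enumeration
  probes3 <- tibble::tibble(group = c("a", "b", "c"),
                            protein_res = c(59, 74, 111),
                            protein_atom = c("HE1", "HE1", "H"))
  acc <- tibble::tibble(ligand_res = "IdoA2S", ligand_atom = "H2")
  xyz3 <- rbind(c(0, 4, 0), c(10, 0, 0), c(28, 0, 0))
  prot3 <- prot; prot3$x <- xyz3[, 1]; prot3$y <- xyz3[, 2]
  xyzL2 <- sweep(chain_xyz(lig), 2, chain_xyz(lig)[i_h2, ] - c(0, 0, 0))
  # brute-force oracle over all probe x acceptor pairs
  d_or <- vapply(1:3, function(i)
    min(sqrt(colSums((t(xyzL2[i_h2, , drop = FALSE]) -
                        xyz3[i, ])^2))), numeric(1))
  s3 <- noe_score(xyz3, xyzL2, prot3, lig, probes3, acc)
  expect_equal(s3$score, mean(d_or), tolerance = 1e-9)
})

test_that("NOE score is permutation-invariant and acceptor-monotone", {
  res <- dock(h_receptor, h_ligand, h_restraints, seed = 2,
              config = dock_config(stage1_levels = 3, stage2_levels = 2,
                                   n_prop = 10, prescreen_top = 1,
                                   prescreen_levels = 2, prescreen_prop = 5))
  p <- res$pose[[which(res$refined)[1]]]
  pr <- ctd_probes()
  s1 <- noe_score(p$xyz_protein, p$xyz, h_receptor, h_ligand, pr)
  s2 <- noe_score(p$xyz_protein, p$xyz, h_receptor, h_ligand,
                  pr[rev(seq_len(nrow(pr))), ])
  expect_equal(s1$score, s2$score)
  # enlarging the acceptor set can only decrease per-probe distances
  acc_big <- dplyr::bind_rows(uronate_acceptors(),
                              tibble::tibble(ligand_res = "GlcNS6S",
                                             ligand_atom = "H*"))
  s3 <- noe_score(p$xyz_protein, p$xyz, h_receptor, h_ligand, pr, acc_big)
  expect_lte(s3$score, s1$score + 1e-12)
  # exhaustive-enumeration oracle for the full CTD probe set
  oracle <- local({
    groups <- unique(pr$group)
    acc_idx <- which((h_ligand$atoms$res_name == "IdoA2S" &
                        h_ligand$atoms$atom == "H2") |
                       (h_ligand$atoms$res_name == "dUA2S" &
                          h_ligand$atoms$atom == "H3"))
    mean(vapply(groups, function(g) {
      rows <- pr[pr$group == g, ]
      idx <- integer(0)
      for (k in seq_len(nrow(rows)))
        idx <- c(idx, which(h_receptor$res_id == rows$protein_res[k] &
                              grepl(utils::glob2rx(rows$protein_atom[k]),
                                    h_receptor$atom)))
      min(vapply(idx, function(i) min(sqrt(rowSums(
        sweep(p$xyz[acc_idx, , drop = FALSE], 2,
              p$xyz_protein[i, ])^2))), numeric(1)))
    }, numeric(1)))
  })
  expect_equal(s1$score, oracle, tolerance = 1e-9)
})

test_that("ranking retains ceil(fraction x N) models ordered by energy", {
  set.seed(8)
  sc <- tibble::tibble(pose_id = 1:64,
                       noe_uronate_A = runif(64, 3, 12),
                       energy = runif(64, -60, 0))
  r <- rank_models(sc, 0.10)
  expect_equal(sum(r$selected), 7)      # ceil(6.4)
  sel <- r[r$selected, ]
  expect_true(all(diff(sel$energy) >= 0))
  expect_equal(sel$rank, 1:7)
  # the selected set is exactly the 7 smallest primary scores
  expect_setequal(sel$pose_id, sc$pose_id[order(sc$noe_uronate_A)][1:7])
  # fraction 1 keeps everything, energy-ordered
  r1 <- rank_models(sc, 1)
  expect_true(all(r1$selected))
  expect_true(all(diff(r1$energy[order(r1$rank)]) >= 0))
  expect_error(rank_models(sc, 0), "top_fraction")
  expect_error(rank_models(sc, 1.2), "top_fraction")
})

test_that("ranking is stable under shuffling and ties break by pose id", {
  sc <- tibble::tibble(pose_id = 1:10, noe_uronate_A = rep(5, 10),
                       energy = rep(-10, 10))
  r <- rank_models(sc, 0.3)
  expect_equal(sort(sc$pose_id[r$selected]), 1:3)   # tie-break by id
  set.seed(1)
  sc2 <- sc[sample(10), ]
  r2 <- rank_models(sc2, 0.3)
  expect_setequal(r2$pose_id[r2$selected], r$pose_id[r$selected])
})

test_that("Kabsch superposition matches the bio3d oracle on toy coordinates", {
  a <- matrix(c(0, 0, 0, 1.5, 0, 0, 1.5, 1.5, 0, 0, 1.5, 1), 4, 3,
              byrow = TRUE)
  R <- rot_z(25) %*% rot_y(-40)
  b <- sweep(a %*% t(R), 2, c(3, -2, 7), `+`)
  expect_equal(backbone_deviation(a, a), 0)
  expect_equal(backbone_deviation(b, a), 0, tolerance = 1e-9)
  # perturbed coordinates: compare with bio3d's superposition RMSD
  set.seed(12)
  b2 <- b + matrix(rnorm(12, 0, 0.3), 4, 3)
  ours <- backbone_deviation(b2, a)
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b2)), fit = TRUE)
  # bio3d rounds its RMSD to 3 decimals
  expect_equal(ours, ref, tolerance = 1e-3)
  expect_error(backbone_deviation(a[1:3, ], a), "mismatch")
})

test_that("surrogate binding energy behaves like an interaction energy", {
  # infinitely separated molecules: zero
  far <- h_fixture$manifest$true_xyz + 1e4
  e_far <- surrogate_binding_energy(h_receptor, h_xyzP, h_ligand, far)
  expect_equal(e_far$energy, 0, tolerance = 1e-5)
  # bound fixture: favorable
  e0 <- surrogate_binding_energy(h_receptor, h_xyzP, h_ligand,
                                 h_fixture$manifest$true_xyz)
  expect_lt(e0$energy, -10)
  expect_false(e0$clash)
  # doubling all formal charges quadruples the Coulomb term
  prot2 <- h_receptor; prot2$charge <- 2 * prot2$charge
  lig2 <- h_ligand; lig2$atoms$charge <- 2 * lig2$atoms$charge
  e2 <- surrogate_binding_energy(prot2, h_xyzP, lig2,
                                 h_fixture$manifest$true_xyz)
  expect_equal(e2$coulomb, 4 * e0$coulomb, tolerance = 1e-9)
  # clash flag below 0.5 A
  clashing <- h_xyzP[1, , drop = FALSE]
  lig_at <- h_fixture$manifest$true_xyz
  lig_at[1, ] <- clashing + 0.2
  expect_warning(
    e3 <- surrogate_binding_energy(h_receptor, h_xyzP, h_ligand, lig_at),
    "clash")
  expect_true(e3$clash)
})

test_that("a more cationic patch binds the sulfated ligand more favorably", {
  # matched geometry, different charge counts (5 vs 2 cationic side chains)
  lay5 <- tibble::tibble(res_id = 1:9,
                         aa = c("A", "K", "K", "K", "A", "K", "K", "A", "A"))
  lay2 <- lay5; lay2$aa <- c("A", "K", "A", "A", "A", "A", "K", "A", "A")
  p5 <- make_mini_receptor(lay5); p2 <- make_mini_receptor(lay2)
  fx5 <- make_bound_pose_fixture(p5, h_ligand, seed = 1)
  e5 <- surrogate_binding_energy(p5, as.matrix(p5[, c("x", "y", "z")]),
                                 h_ligand, fx5$manifest$true_xyz)
  e2 <- surrogate_binding_energy(p2, as.matrix(p2[, c("x", "y", "z")]),
                                 h_ligand, fx5$manifest$true_xyz)
  expect_lt(e5$energy, e2$energy)
})

test_that("score_poses reports primary/secondary scores and backbone RMSD", {
  res <- dock(h_receptor, h_ligand, h_restraints, seed = 21,
              config = h_dock_config())
  sc <- score_poses(res)
  expect_equal(nrow(sc), 64)
  expect_true(all(sc$noe_uronate_A >= 0))
  expect_true(all(sc$backbone_rmsd_A < 1e-9))    # backbone held fixed
  ranked <- rank_models(sc)
  expect_equal(sum(ranked$selected), 7)
  # restraint-satisfying refined poses score uronate < glucosamine
  bp <- best_pose(res)
  expect_equal(bp$satisfied_frac, 1)
  expect_true(sc$uronate_lt_gluc[sc$pose_id == bp$start])
  expect_s3_class(autoplot(ranked), "ggplot")
})
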