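test_that("the hexasaccharide builds at the requested minimum-energy torsions", {
  mt <- measure_torsions(h_ligand)
  glc_ido <- mt[mt$donor == "GlcNS6S", ]
  uro_glc <- mt[mt$donor != "GlcNS6S", ]
  expect_equal(nrow(glc_ido), 2)
  expect_equal(nrow(uro_glc), 3)
  expect_lt(max(abs(glc_ido$phi - 80)), 0.5)
  expect_lt(max(abs(glc_ido$psi - (-170))), 0.5)
  expect_lt(max(abs(uro_glc$phi - (-80))), 0.5)
  expect_lt(max(abs(uro_glc$psi - (-140))), 0.5)
})

test_that("a single-residue chain is the unchanged template", {
  ch <- build_glycan("GlcNS6S")
  tmpl <- glycan_template("GlcNS6S")
  expect_equal(nrow(ch$linkages), 0)
  expect_equal(ch$atoms[, c("atom", "x", "y", "z")],
               tmpl[, c("atom", "x", "y", "z")])
})

test_that("torsions are periodic: phi+360 / psi-360 give identical coordinates", {
  t1 <- tibble::tibble(phi = 80, psi = -170)
  t2 <- tibble::tibble(phi = 80 + 360, psi = -170 - 360)
  a <- build_glycan(c("GlcNS6S", "IdoA2S"), t1)
  b <- build_glycan(c("GlcNS6S", "IdoA2S"), t2)
  expect_equal(a$atoms$x, b$atoms$x, tolerance = 1e-9)
  expect_equal(a$atoms$z, b$atoms$z, tolerance = 1e-9)
})

test_that("build/measure round-trips random torsions to well under half a degree", {
  set.seed(20)
  worst <- 0
  for (k in 1:100) {
    tor <- tibble::tibble(phi = runif(2, -179, 179), psi = runif(2, -179, 179))
    ch <- suppressWarnings(build_glycan(c("dUA2S", "GlcNS6S", "IdoA2S"), tor))
    mt <- measure_torsions(ch)
    worst <- max(worst,
                 abs(((mt$phi - tor$phi + 180) %% 360) - 180),
                 abs(((mt$psi - tor$psi + 180) %% 360) - 180))
  }
  expect_lt(worst, 0.5)
})

test_that("degenerate (collinear) dihedrals are flagged NA", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_true(is.na(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])))
})

test_that("ring puckers match their labels by Cremer-Pople theta", {
  cp <- cremer_pople(h_ligand)
  expect_lt(max(abs(cp$theta[cp$res_name == "IdoA2S"] - 180)), 15)
  expect_lt(max(cp$theta[cp$res_name == "GlcNS6S"]), 15)
  # ring closure: bonded ring atoms within 1.6 +/- 0.2 A
  for (ri in 1:6) {
    ring <- h_ligand$atoms[h_ligand$atoms$res_idx == ri &
                             h_ligand$atoms$atom %in%
                               c("O5", "C1", "C2", "C3", "C4", "C5"), ]
    xyz <- as.matrix(ring[match(c("O5", "C1", "C2", "C3", "C4", "C5"),
                                ring$atom), c("x", "y", "z")])
    bonds <- sqrt(rowSums((xyz - xyz[c(2:6, 1), ])^2))
    expect_true(all(bonds > 1.4 & bonds < 1.8))
  }
})

test_that("the chain build is deterministic and clash-free", {
  a <- dp6c(); b <- dp6c()
  expect_identical(a$atoms, b$atoms)
  # no non-bonded heavy-atom pair closer than 1.8 A
  expect_silent(dp6c())
})

test_that("formal charge bookkeeping: DP6-C carries -12", {
  expect_equal(chain_charge(h_ligand), -12)
  n_sulf <- sum(h_ligand$atoms$element == "S")
  n_carbox <- sum(h_ligand$atoms$group == "carboxylate" &
                    h_ligand$atoms$atom == "C6")
  expect_equal(chain_charge(h_ligand), -(n_sulf + n_carbox))
  expect_equal(n_sulf, 9)
})

test_that("2-O-desulfation removes three sulfates and raises the charge by 3", {
  d <- desulfate(h_ligand, "2-O")
  expect_equal(chain_charge(d) - chain_charge(h_ligand), 3)
  expect_equal(sum(d$atoms$element == "S"), 6)
  expect_equal(d$sequence[1], "dUA")
  expect_equal(d$sequence[3], "IdoA")
  # ring coordinates untouched
  ring_sel <- h_ligand$atoms$atom %in% c("O5", "C1", "C2", "C3", "C4", "C5")
  expect_equal(d$atoms$x[d$atoms$atom %in% c("O5", "C1", "C2", "C3", "C4", "C5")],
               h_ligand$atoms$x[ring_sel])
})

test_that("desulfation modes compose to full desulfation and are idempotent", {
  d <- desulfate(desulfate(desulfate(h_ligand, "6-O"), "2-O"), "N-to-NAc")
  expect_equal(sum(d$atoms$element == "S"), 0)
  expect_equal(chain_charge(d), -3)      # carboxylates remain
  expect_true(all(grepl("NAc", d$sequence[c(2, 4, 6)])))
  expect_warning(d2 <- desulfate(d, "2-O"), "matches no group")
  expect_identical(d2$atoms, d$atoms)
})

test_that("N-desulfation/N-acetylation leaves no N-sulfate distance entries", {
  d <- desulfate(h_ligand, "N-to-NAc")
  sd <- sulfate_distances(d)
  expect_false(any(sd$group1 == "N-sulfate" | sd$group2 == "N-sulfate"))
})

test_that("sulfate cluster analysis finds the across-linkage NS/2OS pair", {
  sd <- sulfate_distances(h_ligand)
  expect_true(all(diff(sd$dist_A) >= 0))
  expect_true(all(sd$dist_A <= 12))
  # in each GlcNS6S -> IdoA2S disaccharide the glucosamine N-sulfate to
  # iduronate 2-O-sulfate distance is the closest inter-residue S...S pair
  for (pair in list(c(2, 3), c(4, 5))) {
    p <- sd[sd$res1 == pair[1] & sd$res2 == pair[2], ]
    expect_gt(nrow(p), 0)
    ns <- p[(p$group1 == "N-sulfate" & p$group2 == "2-O-sulfate") |
              (p$group2 == "N-sulfate" & p$group1 == "2-O-sulfate"), ]
    expect_equal(min(p$dist_A), min(ns$dist_A))
  }
})

test_that("a lone GlcNS6S reports exactly its intra-residue sulfate pair", {
  ch <- build_glycan("GlcNS6S")
  sd <- sulfate_distances(ch)
  expect_equal(nrow(sd), 1)
  expect_setequal(c(sd$group1, sd$group2), c("N-sulfate", "6-O-sulfate"))
})

test_that("sequence text form round-trips, with and without torsion suffixes", {
  txt <- "dUA2S-GlcNS6S-IdoA2S-GlcNS6S-IdoA2S-GlcNS6S"
  ch <- build_glycan(txt)
  expect_equal(format_glycan_sequence(ch), txt)
  p <- parse_glycan_sequence("dUA2S-GlcNS6S[80,-170]-IdoA2S")
  expect_equal(p$sequence, c("dUA2S", "GlcNS6S", "IdoA2S"))
  expect_equal(p$torsions$phi, c(NA, 80))
  expect_equal(p$torsions$psi, c(NA, -170))
  expect_error(build_glycan("GlcXQ7S-IdoA2S"), "unknown residue")
  expect_error(build_glycan(c("GlcNS6S", "IdoA2S"),
                            tibble::tibble(phi = c(80, 80), psi = c(1, 1))),
               "one per linkage")
})

test_that("set_linkage_torsion rotates a built chain to new targets", {
  ch <- set_linkage_torsion(h_ligand, 2, phi = 123, psi = -45)
  mt <- measure_torsions(ch)
  expect_equal(mt$phi[2], 123, tolerance = 1e-6)
  expect_equal(mt$psi[2], -45, tolerance = 1e-6)
  # upstream residues unmoved
  up <- h_ligand$atoms$res_idx <= 2
  expect_equal(ch$atoms$x[up], h_ligand$atoms$x[up])
})
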