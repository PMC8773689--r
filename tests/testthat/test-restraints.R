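test_that("contact expansion produces the expected pair counts", {
  # unambiguous lysine contact: three zeta protons x one H4
  k45 <- tibble::tibble(protein_res = "45", protein_atom = "HZ*",
                        ligand_res = "dUA2S", ligand_atom = "H4")
  prot <- make_mini_receptor(ntd_like_layout())
  r <- compile_restraints(k45, prot, h_ligand)
  expect_equal(r$n_pairs, 3)

  # one indole proton x 9 terminal oxygens (three 2-O-sulfates x 3 oxygens)
  w <- tibble::tibble(protein_res = "74", protein_atom = "HE1",
                      ligand_res = "*", ligand_atom = "O2S*")
  r2 <- compile_restraints(w, h_receptor, h_ligand)
  expect_equal(r2$n_pairs, 9)

  # the K68/91 ambiguity group pools both residues into one restraint
  kk <- tibble::tibble(protein_res = "68/91", protein_atom = "HZ*",
                       ligand_res = "*", ligand_atom = "O2S*")
  r3 <- compile_restraints(kk, h_receptor, h_ligand)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$n_pairs, 2 * 3 * 9)

  empty <- compile_restraints(tibble::tibble(protein_res = character(0),
                                             protein_atom = character(0),
                                             ligand_res = character(0),
                                             ligand_atom = character(0)),
                              h_receptor, h_ligand)
  expect_equal(nrow(empty), 0)

  bad <- tibble::tibble(protein_res = "74", protein_atom = "HQ9",
                        ligand_res = "*", ligand_atom = "O2S*")
  expect_error(compile_restraints(bad, h_receptor, h_ligand),
               "no protein atom")
})

test_that("effective distance follows the r^-6 averaging closed forms", {
  expect_equal(effective_distance(5), 5)
  expect_equal(effective_distance(c(4, 4)), 4 * 2^(-1 / 6))
  expect_equal(effective_distance(c(4, 8)), (4^-6 + 8^-6)^(-1 / 6))
  expect_equal(effective_distance(c(4, 8)), 3.99, tolerance = 1e-2)
  expect_error(effective_distance(c(3, 0)), "distance 0")
})

test_that("d_eff is dominated by the shortest pair and is monotone in pairs", {
  # brute-force enumeration oracle over random pair sets
  set.seed(9)
  for (k in 1:50) {
    d <- runif(sample(2:12, 1), 2, 15)
    deff <- effective_distance(d)
    oracle <- sum(d^-6)^(-1 / 6)
    expect_equal(deff, oracle)
    expect_lt(deff, min(d))             # strict: more than one pair
    expect_lt(effective_distance(c(d, 20)), deff)  # adding a pair decreases it
  }
  expect_equal(effective_distance(7.3), 7.3)  # equality iff single pair
})

test_that("flat-bottom restraint energy is zero inside and quadratic outside", {
  prot <- tibble::tibble(res_id = 74L, res_name = "TRP", atom = "HE1",
                         element = "H", x = 0, y = 0, z = 0, charge = 0)
  lig <- build_glycan("dUA2S")
  ct <- tibble::tibble(protein_res = "74", protein_atom = "HE1",
                       ligand_res = "dUA2S", ligand_atom = "H4")
  rs <- compile_restraints(ct, prot, lig)
  place_at <- function(dist) {
    xyz <- chain_xyz(lig)
    i <- which(lig$atoms$atom == "H4")
    sweep(xyz, 2, xyz[i, ] - c(dist, 0, 0))
  }
  e_in <- restraint_energy(rs, as.matrix(prot[, c("x", "y", "z")]), place_at(5.5))
  expect_equal(e_in$total, 0)
  expect_true(e_in$table$satisfied)
  e_out <- restraint_energy(rs, as.matrix(prot[, c("x", "y", "z")]), place_at(9),
                            force_constant = 1)
  expect_equal(e_out$total, 4, tolerance = 1e-9)   # (9 - 7)^2
  e_low <- restraint_energy(rs, as.matrix(prot[, c("x", "y", "z")]), place_at(3),
                            force_constant = 1)
  expect_equal(e_low$total, 1, tolerance = 1e-9)   # (4 - 3)^2
})

test_that("analytic gradient matches central finite differences", {
  set.seed(4)
  nP <- 6; nL <- 10
  xyzP <- matrix(runif(3 * nP, -5, 5), nP, 3)
  xyzL <- matrix(runif(3 * nL, 2, 12), nL, 3)
  rs <- tibble::tibble(
    id = 1:10, label = paste0("r", 1:10), n_pairs = 0L,
    lower = 4, upper = 7, weight = runif(10, 0.5, 2),
    pairs = lapply(1:10, function(k) {
      np <- sample(1:4, 1)
      cbind(ip = sample(nP, np, replace = TRUE),
            il = sample(nL, np, replace = TRUE))
    }))
  rs$n_pairs <- vapply(rs$pairs, nrow, integer(1))
  class(rs) <- c("restraint_set", class(rs))
  g <- restraint_gradient(rs, xyzP, xyzL)
  h <- 1e-6
  fd <- matrix(0, nL, 3)
  for (i in seq_len(nL)) for (j in 1:3) {
    xp <- xyzL; xp[i, j] <- xp[i, j] + h
    xm <- xyzL; xm[i, j] <- xm[i, j] - h
    fd[i, j] <- (restraint_energy(rs, xyzP, xp)$total -
                   restraint_energy(rs, xyzP, xm)$total) / (2 * h)
  }
  denom <- max(abs(fd), 1)
  expect_lt(max(abs(g - fd)) / denom, 1e-5)
})

test_that("restraint energy is invariant under rigid motion of the complex", {
  e0 <- restraint_energy(h_restraints, h_xyzP, h_fixture$manifest$true_xyz,
                         force_constant = 10)
  R <- rot_z(37) %*% rot_x(11)
  tr <- c(5, -3, 2)
  move <- function(x) sweep(x %*% t(R), 2, tr, `+`)
  # displace the ligand to create violations, then move the whole complex
  xyzL <- h_fixture$manifest$true_xyz + 3
  e1 <- restraint_energy(h_restraints, h_xyzP, xyzL)
  e2 <- restraint_energy(h_restraints, move(h_xyzP), move(xyzL))
  expect_equal(e1$total, e2$total, tolerance = 1e-9)
  expect_gt(e1$total, 0)
  expect_equal(e0$total, 0)
})

test_that("the packaged CTD and NTD contact tables compile", {
  ctd <- example_contacts("ctd")
  expect_equal(nrow(ctd), 4)
  rs <- compile_restraints(ctd, h_receptor, h_ligand)
  expect_equal(nrow(rs), 4)
  expect_true(all(rs$n_pairs > 0))
  ntd <- example_contacts("ntd")
  expect_equal(nrow(ntd), 6)
  prot_ntd <- make_mini_receptor(ntd_like_layout())
  rs2 <- compile_restraints(ntd, prot_ntd, h_ligand)
  # the unambiguous K45 Hz - dUA2S H4 contact has exactly 3 pairs
  expect_equal(rs2$n_pairs[6], 3)
})
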