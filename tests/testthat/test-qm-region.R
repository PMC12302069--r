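# toy snapshot: solute centered, waters with O at controlled distances
toy_snapshot <- function(o_dists, box = 40, solute = tiny_solute()) {
  s0 <- snapshot(solute, box, validate = FALSE)
  com <- solute_com(s0)
  wat <- do.call(rbind, lapply(seq_along(o_dists), function(k) {
    dir <- c(1, 0, 0)
    water_at(com + dir * o_dists[k], k + 1L)
  }))
  snapshot(rbind(solute, wat), box, 1L)
}

test_that("COM criterion selects waters by oxygen distance with ties
           included", {
  snap <- toy_snapshot(c(3.0, 5.0, 9.0))
  reg <- select_qm_region(snap, qm_region_spec("com", 4.0))
  expect_length(reg$qm_water_residues, 1L)
  expect_equal(length(reg$qm_atom_indices), 3 + 3)  # solute + 1 water
  # cutoff 0.0 sentinel: solute-only QM, every water a point charge
  reg0 <- select_qm_region(snap, qm_region_spec("com", 0))
  expect_length(reg0$qm_water_residues, 0L)
  expect_equal(nrow(reg0$mm_point_charges), 9L)
  # tie at exactly the radius is included (single-atom solute puts the
  # COM exactly at the origin, so the distance is exactly 3.0)
  one <- atom_table("C", 0, 0, 0, charge_red = 0, charge_ox = 1,
                    role = "solute", residue_id = 1L)
  st <- snapshot(rbind(one, water_at(c(3, 0, 0), 2L)), 40)
  regt <- select_qm_region(st, qm_region_spec("com", 3.0))
  expect_length(regt$qm_water_residues, 1L)
  expect_error(select_qm_region(snap, qm_region_spec("com", 30)), "box_edge/2")
})

test_that("atom criterion reaches waters the COM criterion misses", {
  # elongated solute: edge atom 3 A from a water O whose COM distance is
  # about 6 A
  long_solute <- atom_table(c("C", "C", "C", "O"),
                            x = c(0, 2, 4, 6), y = 0, z = 0,
                            charge_red = 0, charge_ox = c(0.5, 0.5, 0, 0),
                            role = "solute", residue_id = 1L)
  s0 <- snapshot(long_solute, 40, validate = FALSE)
  com <- solute_com(s0)
  o <- c(9, 0, 0)  # 3 A from the edge atom at x = 6
  expect_gt(min_image_distance(com, o, 40), 4)
  snap <- snapshot(rbind(long_solute, water_at(o, 2L)), 40)
  by_atom <- select_qm_region(snap, qm_region_spec("atom", 4))
  by_com <- select_qm_region(snap, qm_region_spec("com", 4))
  expect_length(by_atom$qm_water_residues, 1L)
  expect_length(by_com$qm_water_residues, 0L)
})

test_that("selections nest with radius, atom dominates com, and the QM/MM
           partition is exact", {
  cfg <- synthetic_box_config("ring6", n_waters = 120, box_edge = 22,
                              n_frames = 6, seed = 41)
  traj <- generate_solvated_box(cfg)
  radii <- c(0, seq(4, 7.5, by = 0.5))
  n_decisions <- 0L
  n_dominance_violations <- 0L
  for (snap in traj$snapshots) {
    n_at <- nrow(snap$atoms)
    prev <- list(com = integer(0), atom = integer(0))
    for (r in radii) {
      regs <- list()
      for (cr in c("com", "atom")) {
        reg <- select_qm_region(snap, qm_region_spec(cr, r))
        # exact partition
        expect_identical(sort(c(reg$qm_atom_indices, reg$mm_atom_indices)),
                         seq_len(n_at))
        # nesting in radius (supersets, not just counts)
        expect_true(all(prev[[cr]] %in% reg$qm_water_residues))
        prev[[cr]] <- reg$qm_water_residues
        regs[[cr]] <- reg
      }
      # criterion dominance at equal radius holds except for the rare
      # axial geometry: a water can sit within r of the COM yet farther
      # than r from every atom (for a planar ring, an on-axis water at
      # COM distance d has nearest-atom distance sqrt(d^2 + r_ring^2))
      n_decisions <- n_decisions + length(regs$com$qm_water_residues)
      n_dominance_violations <- n_dominance_violations +
        sum(!regs$com$qm_water_residues %in% regs$atom$qm_water_residues)
    }
    # counterion is never QM
    ion <- which(snap$atoms$role == "counterion")
    reg75 <- select_qm_region(snap, qm_region_spec("atom", 7.5))
    expect_true(ion %in% reg75$mm_atom_indices)
  }
  expect_lt(n_dominance_violations, 0.01 * n_decisions)
})

test_that("cutoff sweep counts are non-decreasing and atom >= com", {
  cfg <- synthetic_box_config("ring6-OH", n_waters = 100, box_edge = 22,
                              n_frames = 4, seed = 42)
  traj <- generate_solvated_box(cfg)
  radii <- c(0, 4, 5, 6, 7.5)
  sw_com <- cutoff_sweep(traj, radii, "com")
  sw_atom <- cutoff_sweep(traj, radii, "atom")
  expect_true(all(diff(sw_com$mean_waters) >= 0))
  expect_true(all(diff(sw_atom$mean_waters) >= 0))
  expect_true(all(sw_atom$mean_waters >= sw_com$mean_waters))
  expect_equal(sw_com$mean_waters[1], 0)
  expect_equal(cutoff_sweep(traj, 0, "com")$mean_waters, 0)
})

test_that("surrogate gap: vacuum limit, Coulomb hand value, zero coupling", {
  snap <- toy_snapshot(c(3.0))
  # all waters QM -> exactly the gas-phase offset
  reg_all <- select_qm_region(snap, qm_region_spec("com", 10))
  expect_equal(surrogate_gap(snap, reg_all, 6.0), 6.0)
  # single unit MM charge at k_e angstrom from a +1-difference atom
  sol <- atom_table("C", 0, 0, 0, charge_red = 0, charge_ox = 1,
                    role = "solute", residue_id = 1L)
  probe <- atom_table("CL", redox_constants$k_e, 0, 0, charge_red = 1,
                      charge_ox = 1, role = "counterion", residue_id = 2L)
  s2 <- snapshot(rbind(sol, probe), 40)
  reg2 <- select_qm_region(s2, qm_region_spec("com", 0))
  expect_equal(surrogate_gap(s2, reg2, 6.0), 7.0, tolerance = 1e-9)
  # zero charge difference -> no coupling to any environment
  sol0 <- atom_table(c("C", "C"), c(0, 1.4), 0, 0,
                     charge_red = c(0.5, 0.5), charge_ox = c(1.0, 0.0),
                     role = "solute", residue_id = 1L)
  sol0$charge_ox <- sol0$charge_red  # explicit zero difference
  s3 <- snapshot(rbind(sol0, water_at(c(5, 0, 0), 2L)), 40, validate = FALSE)
  reg3 <- select_qm_region(s3, qm_region_spec("com", 0))
  expect_equal(surrogate_gap(s3, reg3, 4.2), 4.2)
  # clash detection names the offending pair
  s4 <- snapshot(rbind(sol, atom_table("CL", 0.2, 0, 0, -1, -1,
                                       "counterion", 2L)), 40,
                 validate = FALSE)
  reg4 <- select_qm_region(s4, qm_region_spec("com", 0))
  expect_error(surrogate_gap(s4, reg4, 6), "clash")
})

test_that("surrogate gap converges as the QM region grows (charged
           solute)", {
  cfg <- synthetic_box_config("ring6-O-", n_waters = 120, box_edge = 22,
                              n_frames = 10, seed = 43)
  traj <- generate_solvated_box(cfg)
  radii <- c(0, 4, 5, 6, 7, 7.5)
  G <- sapply(radii, function(r) sapply(traj$snapshots, function(s)
    surrogate_gap(s, select_qm_region(s, qm_region_spec("com", r)), 6)))
  # mean distance from the widest-region gap shrinks as the QM region
  # absorbs the dominant near-field waters
  d <- colMeans(abs(G - G[, length(radii)]))
  expect_gt(d[1], 1e-6)
  expect_true(all(diff(d) < 0))
})

test_that("embedding input files partition atoms and round-trip charges", {
  snap <- toy_snapshot(c(3.0, 5.0, 9.0))
  ion_snap <- snapshot(rbind(snap$atoms,
                             atom_table("CL", 15, 0, 0, -1, -1,
                                        "counterion", 99L)),
                       snap$box_edge)
  reg <- select_qm_region(ion_snap, qm_region_spec("com", 0), "oxidized")
  qm_f <- withr::local_tempfile(fileext = ".xyz")
  ch_f <- withr::local_tempfile(fileext = ".pc")
  write_embedding_input(ion_snap, reg, qm_f, ch_f)
  qm <- read_xyz(qm_f)
  expect_equal(nrow(qm$snapshots[[1]]$atoms), 3L)  # solute only
  pc <- read_point_charges(ch_f)
  expect_equal(nrow(pc), 10L)  # 9 water atoms + ion
  expect_equal(pc$q, reg$mm_point_charges$q, tolerance = 1e-6)
  expect_equal(nrow(qm$snapshots[[1]]$atoms) + nrow(pc),
               nrow(ion_snap$atoms))
})
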