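# Small in-code fixtures shared across test files.

# rigid 3-atom solute; ox - red charge difference = +1 split over two C
tiny_solute <- function(q_red_total = 0) {
  atom_table(c("C", "C", "O"),
             x = c(0, 1.4, 0.7), y = c(0, 0, 1.2), z = c(0, 0, 0),
             charge_red = c(0, 0, q_red_total),
             charge_ox = c(0.5, 0.5, q_red_total),
             role = "solute", residue_id = 1L)
}

# one rigid water with oxygen at `o`
water_at <- function(o, rid) {
  atom_table(c("O", "H", "H"),
             x = o[1] + c(0, 0.9572, -0.24), y = o[2] + c(0, 0, 0.927),
             z = o[3] + c(0, 0, 0),
             charge_red = c(-0.834, 0.417, 0.417),
             charge_ox = c(-0.834, 0.417, 0.417),
             role = "water", residue_id = rid)
}

# snapshot with a tiny solute, waters at given O positions (rows), and an
# optional chloride
make_snapshot <- function(water_o = NULL, ion = NULL, box = 50, frame = 1L,
                          solute = tiny_solute()) {
  atoms <- solute
  rid <- max(atoms$residue_id)
  if (!is.null(water_o)) {
    water_o <- matrix(water_o, ncol = 3)
    for (k in seq_len(nrow(water_o))) {
      rid <- rid + 1L
      atoms <- rbind(atoms, water_at(water_o[k, ], rid))
    }
  }
  if (!is.null(ion)) {
    atoms <- rbind(atoms, atom_table("CL", ion[1], ion[2], ion[3],
                                     charge_red = -1, charge_ox = -1,
                                     role = "counterion",
                                     residue_id = rid + 1L))
  }
  snapshot(atoms, box, frame)
}

# independent 27-image brute-force minimum-image oracle
brute_min_image <- function(a, b, L) {
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * L
  min(sqrt(rowSums(sweep(shifts, 2, b - a, "+")^2)))
}
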