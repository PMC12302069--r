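## Molecular snapshot containers and file I/O.
##
## A snapshot is a list(atoms, box_edge, frame_index) where `atoms` is a
## data.frame with columns element, x, y, z, charge_red, charge_ox, role,
## residue_id. Roles are "solute", "water", "counterion". Boxes are cubic;
## all coordinates in angstrom, charges in e.

.roles <- c("solute", "water", "counterion")
.water_resnames <- c("HOH", "TIP3", "WAT", "SOL")
.ion_elements <- c("NA", "CL", "K")

#' Construct an atom table
#'
#' @param element character vector of element symbols.
#' @param x,y,z numeric coordinates in angstrom.
#' @param charge_red,charge_ox partial charges (e) in the reduced and
#'   oxidized charge sets.
#' @param role one of "solute", "water", "counterion" per atom.
#' @param residue_id integer grouping atoms into molecules.
#' @return a data.frame with one row per atom.
#' @export
atom_table <- function(element, x, y, z, charge_red = 0, charge_ox = 0,
                       role = "solute", residue_id = 1L) {
  df <- data.frame(
    element = as.character(element), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), charge_red = as.numeric(charge_red),
    charge_ox = as.numeric(charge_ox), role = as.character(role),
    residue_id = as.integer(residue_id), stringsAsFactors = FALSE
  )
  df
}

#' Construct and validate a snapshot
#'
#' @param atoms an atom table (see [atom_table()]).
#' @param box_edge cubic box edge length, angstrom.
#' @param frame_index integer frame label.
#' @param validate run invariant checks (default TRUE).
#' @return an object of class `"snapshot"`.
#' @export
snapshot <- function(atoms, box_edge, frame_index = 1L, validate = TRUE) {
  obj <- structure(list(atoms = atoms, box_edge = as.numeric(box_edge),
                        frame_index = as.integer(frame_index)),
                   class = "snapshot")
  if (validate) validate_snapshot(obj)
  obj
}

#' Validate snapshot invariants
#'
#' Checks finiteness of coordinates, positive cubic box edge, water
#' residues of exactly three atoms (one O, two H), at most one counterion,
#' and that the solute charge sets differ by exactly one elementary charge
#' (oxidized = reduced + 1) within 1e-6 e.
#'
#' @param snap a snapshot.
#' @return the snapshot, invisibly; errors on violation.
#' @export
validate_snapshot <- function(snap) {
  a <- snap$atoms
  if (!is.finite(snap$box_edge) || snap$box_edge <= 0)
    .validation_error("box_edge must be positive and finite")
  if (nrow(a) == 0) .validation_error("snapshot has no atoms")
  if (!all(is.finite(c(a$x, a$y, a$z))))
    .validation_error("non-finite atom coordinates")
  if (any(!nzchar(a$element))) .validation_error("empty element symbol")
  if (!all(a$role %in% .roles))
    .validation_error("unknown role(s): ",
                      paste(setdiff(unique(a$role), .roles), collapse = ", "))
  wat <- a[a$role == "water", , drop = FALSE]
  if (nrow(wat) > 0) {
    for (rid in unique(wat$residue_id)) {
      r <- wat[wat$residue_id == rid, , drop = FALSE]
      el <- toupper(r$element)
      if (nrow(r) != 3 || sum(el == "O") != 1 || sum(el == "H") != 2)
        .validation_error("water residue ", rid,
                          " must contain exactly one O and two H")
    }
  }
  n_ion <- sum(a$role == "counterion")
  if (n_ion > 1) .validation_error("at most one counterion allowed, found ", n_ion)
  sol <- a[a$role == "solute", , drop = FALSE]
  if (nrow(sol) == 0) .validation_error("snapshot contains no solute atoms")
  dq <- sum(sol$charge_ox) - sum(sol$charge_red)
  if (abs(dq - 1) > 1e-6)
    .validation_error("solute charge sets must satisfy sum(ox) = sum(red) + 1; ",
                      "difference is ", format(dq))
  invisible(snap)
}

#' Construct a trajectory from snapshots
#'
#' All snapshots must share atom count, ordering and box edge;
#' frame indices must be strictly increasing.
#'
#' @param snapshots list of snapshot objects.
#' @param validate run invariant checks (default TRUE).
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(snapshots, validate = TRUE) {
  if (length(snapshots) < 1) .validation_error("trajectory needs >= 1 snapshot")
  n0 <- nrow(snapshots[[1]]$atoms)
  L0 <- snapshots[[1]]$box_edge
  idx <- vapply(snapshots, function(s) s$frame_index, integer(1))
  if (any(diff(idx) <= 0))
    .validation_error("frame_index must be strictly increasing")
  for (s in snapshots) {
    if (nrow(s$atoms) != n0)
      .validation_error("snapshots disagree on atom count (", n0, " vs ",
                        nrow(s$atoms), ")")
    if (abs(s$box_edge - L0) > 1e-9)
      .validation_error("snapshots disagree on box_edge")
    if (validate) validate_snapshot(s)
  }
  structure(list(snapshots = snapshots, box_edge = L0), class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$snapshots)

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$snapshots), "frame(s),",
      nrow(x$snapshots[[1]]$atoms), "atoms, cubic box",
      format(x$box_edge), "A\n")
  tab <- table(x$snapshots[[1]]$atoms$role)
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a topology sidecar table
#'
#' Comma-delimited with header `index,residue_id,role,charge_red,charge_ox`;
#' one row per atom in file order. XYZ files carry no charge or role
#' information, so these attributes travel in this sidecar.
#'
#' @param path file path.
#' @return data.frame with the sidecar columns.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) .io_error("topology file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "residue_id", "role", "charge_red", "charge_ox")
  if (!all(need %in% names(df)))
    .validation_error("topology file must have columns ",
                      paste(need, collapse = ","))
  if (any(df$index != seq_len(nrow(df))))
    .validation_error("topology index column must be 1..n in order")
  df
}

#' Write a topology sidecar table
#'
#' @param atoms an atom table.
#' @param path output path.
#' @export
write_topology <- function(atoms, path) {
  df <- data.frame(index = seq_len(nrow(atoms)),
                   residue_id = atoms$residue_id, role = atoms$role,
                   charge_red = atoms$charge_red, charge_ox = atoms$charge_ox)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: per frame, an atom-count line, a comment line, then
#' `element x y z` records. If the comment line carries a `box=<L>` token
#' it sets the cubic box edge; otherwise `box_edge` must be supplied.
#' Roles and the two charge sets come from a topology sidecar
#' ([read_topology()]); without one, all atoms are solute with zero/+1
#' spread charges disabled (charges 0; validation is skipped in that case).
#'
#' @param path XYZ file path.
#' @param topology optional topology data.frame or sidecar path.
#' @param box_edge cubic box edge (angstrom) used when the file has no
#'   `box=` token.
#' @return a trajectory.
#' @export
read_xyz <- function(path, topology = NULL, box_edge = NULL) {
  if (!file.exists(path)) .io_error("XYZ file not found: ", path)
  if (is.character(topology)) topology <- read_topology(topology)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  snaps <- list()
  i <- 1L
  frame <- 0L
  n_atoms_first <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      .io_error("malformed atom-count line at line ", i, ": '", lines[i], "'")
    if (i + 1L + n > length(lines))
      .io_error("truncated frame starting at line ", i)
    comment <- lines[i + 1L]
    L <- box_edge
    m <- regmatches(comment, regexec("box=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2) L <- as.numeric(m[2])
    if (is.null(L) || !is.finite(L))
      .validation_error("no box edge: supply box_edge or a 'box=<L>' comment token")
    rec <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rec), "[[:space:]]+")
    bad <- which(vapply(fields, length, integer(1)) < 4)
    if (length(bad))
      .io_error("malformed atom record at line ", i + 1L + bad[1])
    el <- vapply(fields, `[[`, "", 1)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    frame <- frame + 1L
    if (is.null(n_atoms_first)) n_atoms_first <- n
    else if (n != n_atoms_first)
      .validation_error("frame ", frame, " has ", n, " atoms but frame 1 had ",
                        n_atoms_first)
    if (!is.null(topology)) {
      if (nrow(topology) != n)
        .validation_error("topology rows (", nrow(topology),
                          ") do not match atom count (", n, ")")
      atoms <- atom_table(el, xyz[, 1], xyz[, 2], xyz[, 3],
                          topology$charge_red, topology$charge_ox,
                          topology$role, topology$residue_id)
      snaps[[frame]] <- snapshot(atoms, L, frame)
    } else {
      atoms <- atom_table(el, xyz[, 1], xyz[, 2], xyz[, 3],
                          residue_id = 1L)
      snaps[[frame]] <- snapshot(atoms, L, frame, validate = FALSE)
    }
    i <- i + 2L + n
  }
  trajectory(snaps, validate = FALSE)
}

#' Write a multi-frame XYZ trajectory
#'
#' Emits the `box=<L>` token on each comment line so boxes round-trip.
#' Coordinates are written with 6 decimal places.
#'
#' @param traj a trajectory.
#' @param path output path.
#' @param topology_path optional path for a topology sidecar written
#'   alongside (charges and roles do not fit in XYZ).
#' @export
write_xyz <- function(traj, path, topology_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in traj$snapshots) {
    a <- s$atoms
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("frame %d box=%.6f", s$frame_index, s$box_edge), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z),
               con)
  }
  if (!is.null(topology_path))
    write_topology(traj$snapshots[[1]]$atoms, topology_path)
  invisible(path)
}

#' Read a minimal PDB trajectory
#'
#' Parses ATOM/HETATM records; MODEL/ENDMDL delimit frames (a file with no
#' MODEL records is a single frame). Waters are recognized by residue name
#' (HOH, TIP3, WAT, SOL), counterions by element NA/CL/K; everything else
#' is solute. Occupancy, altloc and chain fields are ignored. CRYST1
#' records with a cubic cell set the box edge; non-cubic cells are
#' rejected.
#'
#' @param path PDB file path.
#' @param box_edge cubic box edge used when the file has no CRYST1 record.
#' @return a trajectory.
#' @export
read_pdb_minimal <- function(path, box_edge = NULL) {
  if (!file.exists(path)) .io_error("PDB file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  L <- box_edge
  cr <- which(trimws(rec) == "CRYST1")
  if (length(cr)) {
    abc <- as.numeric(c(substr(lines[cr[1]], 7, 15), substr(lines[cr[1]], 16, 24),
                        substr(lines[cr[1]], 25, 33)))
    if (max(abc) - min(abc) > 1e-6)
      .validation_error("non-cubic box (", paste(abc, collapse = " x "),
                        ") is unsupported")
    L <- abc[1]
  }
  if (is.null(L)) .validation_error("no box edge: supply box_edge or a CRYST1 record")
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  frame_of <- cumsum(trimws(rec) == "MODEL")
  if (max(frame_of) == 0) frame_of <- frame_of + 1L
  frames <- sort(unique(frame_of[is_atom]))
  snaps <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    sel <- which(is_atom & frame_of == frames[k])
    ln <- lines[sel]
    resname <- toupper(trimws(substr(ln, 18, 20)))
    resseq <- as.integer(trimws(substr(ln, 23, 26)))
    x <- as.numeric(substr(ln, 31, 38))
    y <- as.numeric(substr(ln, 39, 46))
    z <- as.numeric(substr(ln, 47, 54))
    el <- toupper(trimws(substr(ln, 77, 78)))
    noel <- !nzchar(el)
    if (any(noel)) {
      nm <- trimws(substr(ln, 13, 16))
      el[noel] <- toupper(gsub("[0-9'].*$", "", nm[noel]))
    }
    role <- rep("solute", length(ln))
    role[resname %in% .water_resnames] <- "water"
    role[role == "solute" & el %in% .ion_elements] <- "counterion"
    if (!any(role == "solute"))
      .validation_error("no solute atoms found in ", path)
    atoms <- atom_table(el, x, y, z, role = role, residue_id = resseq)
    snaps[[k]] <- snapshot(atoms, L, k, validate = FALSE)
  }
  trajectory(snaps, validate = FALSE)
}

#' Read a gap table
#'
#' Comma-delimited text with header `frame,state,cutoff,gap_eV`. State
#' labels must be "reduced" or "oxidized"; (frame, state, cutoff) keys
#' must be unique and gaps finite.
#'
#' @param path file path.
#' @return a data.frame of class `"gap_table"`.
#' @export
read_gap_table <- function(path) {
  if (!file.exists(path)) .io_error("gap table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "state", "cutoff", "gap_eV")
  if (!all(need %in% names(df)))
    .validation_error("gap table must have header ", paste(need, collapse = ","))
  as_gap_table(df)
}

#' Coerce a data.frame to a validated gap table
#'
#' @param df data.frame with columns frame, state, cutoff, gap_eV.
#' @return the data.frame with class `"gap_table"` prepended.
#' @export
as_gap_table <- function(df) {
  bad <- which(!df$state %in% c("reduced", "oxidized"))
  if (length(bad))
    .validation_error("unknown state label '", df$state[bad[1]], "' at row ",
                      bad[1])
  if (any(!is.finite(df$gap_eV)))
    .validation_error("non-finite gap_eV at row ", which(!is.finite(df$gap_eV))[1])
  key <- paste(df$frame, df$state, df$cutoff, sep = "\r")
  if (anyDuplicated(key))
    .validation_error("duplicate (frame,state,cutoff) at row ",
                      which(duplicated(key))[1])
  df$frame <- as.integer(df$frame)
  df$cutoff <- as.character(df$cutoff)
  class(df) <- c("gap_table", class(df))
  df
}

#' Write a gap table
#'
#' Emits the same comma-delimited dialect read by [read_gap_table()],
#' with gaps printed to 6 decimal places.
#'
#' @param table a gap table.
#' @param path output path.
#' @export
write_gap_table <- function(table, path) {
  out <- data.frame(frame = table$frame, state = table$state,
                    cutoff = table$cutoff,
                    gap_eV = sprintf("%.6f", table$gap_eV))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
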