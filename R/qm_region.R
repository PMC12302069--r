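## Construction of QM regions for electrostatic-embedding single points.
##
## The solute is always quantum; whole water molecules join it when their
## oxygen lies within a cutoff radius of either the solute center of mass
## ("com" criterion) or the nearest solute atom ("atom" criterion).
## Radius 0.0 is the solute-only sentinel. Everything not in the QM set
## becomes an MM point charge; the counterion is always MM.

#' QM-region specification
#'
#' @param criterion water-selection criterion: "com" (distance from the
#'   solute center of mass to the water oxygen) or "atom" (shortest
#'   solute-atom-to-water-oxygen distance).
#' @param radius cutoff radius, angstrom; 0.0 means solute-only QM.
#' @return list of class `"qm_region_spec"`.
#' @export
qm_region_spec <- function(criterion = c("com", "atom"), radius = 0) {
  criterion <- match.arg(criterion)
  if (!is.finite(radius) || radius < 0)
    .validation_error("radius must be >= 0")
  structure(list(criterion = criterion, radius = radius),
            class = "qm_region_spec")
}

#' Resolve a QM region on a snapshot
#'
#' Water membership is decided solely by the oxygen atom (hydrogens
#' follow their oxygen); ties at exactly the radius are included. Every
#' atom lands in exactly one of the QM set or the MM point-charge list;
#' MM charges are drawn from the charge set matching `charge_state`.
#'
#' @param snap a snapshot.
#' @param spec a [qm_region_spec()].
#' @param charge_state which charge set the MM environment carries,
#'   "reduced" or "oxidized".
#' @return list of class `"qm_region"`: `qm_atom_indices`,
#'   `qm_water_residues`, `mm_point_charges` (data.frame x,y,z,q),
#'   `mm_atom_indices`, `charge_state_used`, `spec`.
#' @export
select_qm_region <- function(snap, spec, charge_state = c("reduced", "oxidized")) {
  charge_state <- match.arg(charge_state)
  stopifnot(inherits(spec, "qm_region_spec"))
  a <- snap$atoms
  L <- snap$box_edge
  if (spec$radius > L / 2)
    .validation_error("radius (", spec$radius, ") exceeds box_edge/2")
  sol <- which(a$role == "solute")
  wat_o <- which(a$role == "water" & toupper(a$element) == "O")
  sel_res <- integer(0)
  if (spec$radius > 0 && length(wat_o) > 0) {
    O <- as.matrix(a[wat_o, c("x", "y", "z")])
    if (spec$criterion == "com") {
      d <- min_image_distance(O, solute_com(snap), L)
    } else {
      S <- as.matrix(a[sol, c("x", "y", "z")])
      D <- .min_image_cross(O, S, L)
      d <- apply(D, 1, min)
    }
    sel_res <- a$residue_id[wat_o[d <= spec$radius]]
  }
  qm_idx <- sort(c(sol, which(a$role == "water" & a$residue_id %in% sel_res)))
  mm_idx <- setdiff(seq_len(nrow(a)), qm_idx)
  qcol <- if (charge_state == "reduced") "charge_red" else "charge_ox"
  mm <- data.frame(x = a$x[mm_idx], y = a$y[mm_idx], z = a$z[mm_idx],
                   q = a[[qcol]][mm_idx])
  structure(list(qm_atom_indices = qm_idx,
                 qm_water_residues = sort(unique(sel_res)),
                 mm_point_charges = mm, mm_atom_indices = mm_idx,
                 charge_state_used = charge_state, spec = spec),
            class = "qm_region")
}

#' @export
print.qm_region <- function(x, ...) {
  cat("QM region (", x$spec$criterion, " cutoff ", x$spec$radius, " A): ",
      length(x$qm_atom_indices), " QM atoms (",
      length(x$qm_water_residues), " waters), ",
      nrow(x$mm_point_charges), " MM point charges [", x$charge_state_used,
      " charges]\n", sep = "")
  invisible(x)
}

#' Sweep QM cutoff radii over a trajectory
#'
#' For each radius, the mean and standard deviation over frames of the
#' number of water molecules selected into the QM region. The default
#' radius list is the solute-only sentinel plus 4.0 to 7.5 A in 0.5 A
#' steps.
#'
#' @param traj a trajectory.
#' @param radii ascending cutoff radii, angstrom.
#' @param criterion "com" or "atom".
#' @return data.frame with columns radius, mean_waters, sd_waters.
#' @export
cutoff_sweep <- function(traj, radii = c(0, seq(4, 7.5, by = 0.5)),
                         criterion = c("com", "atom")) {
  criterion <- match.arg(criterion)
  if (is.unsorted(radii)) .validation_error("radii must be sorted ascending")
  counts <- matrix(0, length(traj$snapshots), length(radii))
  for (k in seq_along(traj$snapshots)) {
    for (j in seq_along(radii)) {
      reg <- select_qm_region(traj$snapshots[[k]],
                              qm_region_spec(criterion, radii[j]))
      counts[k, j] <- length(reg$qm_water_residues)
    }
  }
  data.frame(radius = radii, mean_waters = colMeans(counts),
             sd_waters = apply(counts, 2, stats::sd))
}

#' Electrostatic surrogate for the vertical energy gap
#'
#' A fixed-charge stand-in for the quantum single points: the gap is a
#' gas-phase offset plus the Coulomb interaction of the solute's
#' oxidation charge difference with the MM point charges,
#' \deqn{\Delta E = \Delta E_{gas} + \sum_{i \in solute} \sum_{j \in MM}
#'   k_e (q_i^{ox} - q_i^{red}) q_j / r_{ij}} with minimum-image
#' distances and k_e = 14.399645 eV.A/e^2. Waters inside the QM region
#' contribute no point-charge term (their polarization is what a real
#' quantum treatment would capture). The surrogate has no polarization
#' and exists to exercise the pipeline and qualitative trends; it does
#' not reproduce quantum-chemistry gaps.
#'
#' @param snap a snapshot carrying both charge sets.
#' @param region a [select_qm_region()] result for that snapshot.
#' @param dE_gas gas-phase gap offset, eV.
#' @return surrogate gap, eV.
#' @export
surrogate_gap <- function(snap, region, dE_gas) {
  stopifnot(inherits(region, "qm_region"))
  a <- snap$atoms
  sol <- which(a$role == "solute")
  dq <- a$charge_ox[sol] - a$charge_red[sol]
  mm <- region$mm_point_charges
  if (nrow(mm) == 0) return(dE_gas)
  S <- as.matrix(a[sol, c("x", "y", "z")])
  M <- as.matrix(mm[, c("x", "y", "z")])
  D <- .min_image_cross(S, M, snap$box_edge)
  clash <- which(D < 0.5, arr.ind = TRUE)
  if (nrow(clash) > 0)
    .validation_error("clash: solute atom ", sol[clash[1, 1]],
                      " and MM charge ", region$mm_atom_indices[clash[1, 2]],
                      " are ", format(D[clash[1, , drop = FALSE]]),
                      " A apart (< 0.5 A)")
  dE_gas + redox_constants$k_e * sum((dq %o% mm$q) / D)
}

#' Write electrostatic-embedding input files
#'
#' Writes the QM atoms (solute plus selected waters, original order) as
#' a single-frame XYZ and the MM point charges as plain text: a count
#' line, then one `x y z q` line per charge with 6 decimals.
#'
#' @param snap a snapshot.
#' @param region its QM region.
#' @param path_qm output path for the QM-atom XYZ.
#' @param path_charges output path for the point-charge file.
#' @export
write_embedding_input <- function(snap, region, path_qm, path_charges) {
  a <- snap$atoms
  qm <- a[region$qm_atom_indices, , drop = FALSE]
  ok <- tryCatch({
    con <- file(path_qm, "w"); on.exit(close(con))
    writeLines(as.character(nrow(qm)), con)
    writeLines(sprintf("qm region %s cutoff %.2f box=%.6f",
                       region$spec$criterion, region$spec$radius,
                       snap$box_edge), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f",
                       qm$element, qm$x, qm$y, qm$z), con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .io_error("cannot write QM file ", path_qm, ": ",
                             conditionMessage(ok))
  mm <- region$mm_point_charges
  ok <- tryCatch({
    lines <- c(as.character(nrow(mm)),
               sprintf("%14.6f %14.6f %14.6f %12.6f", mm$x, mm$y, mm$z, mm$q))
    writeLines(lines, path_charges)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .io_error("cannot write charge file ", path_charges, ": ",
                             conditionMessage(ok))
  invisible(list(qm = path_qm, charges = path_charges))
}

#' Read a point-charge file written by [write_embedding_input()]
#'
#' @param path file path.
#' @return data.frame with columns x, y, z, q.
#' @export
read_point_charges <- function(path) {
  if (!file.exists(path)) .io_error("charge file not found: ", path)
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n)) .io_error("malformed count line in ", path)
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), q = numeric(0)))
  f <- t(vapply(strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+"),
                function(v) as.numeric(v[1:4]), numeric(4)))
  data.frame(x = f[, 1], y = f[, 2], z = f[, 3], q = f[, 4])
}
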