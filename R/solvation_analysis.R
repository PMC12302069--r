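## Solvent structure around the solute under cubic periodic boundaries:
## minimum-image distances, radial distribution functions, first-shell
## quantities and solute-counterion distance binning.

#' Minimum-image distance in a cubic box
#'
#' Component-wise wrapped difference, each component mapped into
#' (-L/2, L/2], then the Euclidean norm. `a` may be a matrix of row
#' vectors; `b` a single position or a matrix conformable with `a`.
#'
#' @param a,b positions (length-3 vectors or n x 3 matrices), angstrom.
#' @param box_edge cubic box edge L, angstrom.
#' @return distance(s), angstrom.
#' @export
min_image_distance <- function(a, b, box_edge) {
  if (!is.finite(box_edge) || box_edge <= 0)
    .validation_error("box_edge must be > 0")
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, nrow = nrow(a), byrow = TRUE)
  d <- a - b
  d <- d - box_edge * round(d / box_edge)
  ## round() maps to [-L/2, L/2]; fold exact -L/2 onto +L/2
  d[d == -box_edge / 2] <- box_edge / 2
  r <- sqrt(rowSums(d * d))
  if (length(r) == 1) r[[1]] else r
}

## all pairwise min-image distances between row sets A (n x 3) and B (m x 3)
.min_image_cross <- function(A, B, L) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (j in seq_len(m)) out[, j] <- min_image_distance(A, B[j, ], L)
  out
}

## resolve a role/element selection against an atom table -> row indices
.select_atoms <- function(atoms, selection) {
  idx <- rep(TRUE, nrow(atoms))
  if (!is.null(selection$role)) idx <- idx & atoms$role %in% selection$role
  if (!is.null(selection$element))
    idx <- idx & toupper(atoms$element) %in% toupper(selection$element)
  if (isTRUE(selection$heavy)) idx <- idx & toupper(atoms$element) != "H"
  which(idx)
}

#' Solute center of mass
#'
#' Mass-weighted with standard atomic masses.
#'
#' @param snap a snapshot.
#' @return length-3 numeric position, angstrom.
#' @export
solute_com <- function(snap) {
  sol <- snap$atoms[snap$atoms$role == "solute", , drop = FALSE]
  m <- atomic_mass(sol$element)
  colSums(as.matrix(sol[, c("x", "y", "z")]) * m) / sum(m)
}

#' Radial distribution function
#'
#' Pooled g(r) between a reference selection and a target selection over
#' all frames, normalized by the ideal-gas expectation: shell counts in
#' [r, r+dr) divided by N_ref * frames * rho_target * (4pi/3)[(r+dr)^3 -
#' r^3], with rho_target = N_target / box volume. Distances use the
#' minimum image, so r_cut may not exceed half the box edge. Selections
#' are lists with optional `role`, `element`, `heavy` entries, e.g.
#' `list(role = "solute", heavy = TRUE)` for solute heavy atoms and
#' `list(role = "water", element = "O")` for water oxygens.
#'
#' @param traj a trajectory.
#' @param reference,target atom selections.
#' @param bin_width bin width, angstrom (default 0.05).
#' @param r_cut maximum distance, angstrom (default 10).
#' @return object of class `"rdf_profile"`: `bin_centers`, `g`,
#'   `raw_counts`, `solvent_density`, `bin_width`, plus first-shell
#'   fields filled by [first_shell()].
#' @export
radial_distribution <- function(traj, reference, target, bin_width = 0.05,
                                r_cut = 10) {
  stopifnot(inherits(traj, "trajectory"))
  L <- traj$box_edge
  if (r_cut > L / 2 + 1e-9)
    .validation_error("r_cut (", r_cut, ") exceeds box_edge/2 (", L / 2,
                      "): minimum image is ambiguous")
  a0 <- traj$snapshots[[1]]$atoms
  iref <- .select_atoms(a0, reference)
  itar <- .select_atoms(a0, target)
  if (length(iref) == 0 || length(itar) == 0)
    .validation_error("empty reference or target selection")
  edges <- seq(0, r_cut + bin_width, by = bin_width)
  edges <- edges[edges <= r_cut + 1e-12]
  if (edges[length(edges)] < r_cut) edges <- c(edges, r_cut)
  counts <- numeric(length(edges) - 1)
  same <- identical(sort(iref), sort(itar))
  for (s in traj$snapshots) {
    A <- as.matrix(s$atoms[iref, c("x", "y", "z")])
    B <- as.matrix(s$atoms[itar, c("x", "y", "z")])
    D <- .min_image_cross(A, B, L)
    if (same) diag(D) <- Inf  # exclude self pairs
    d <- D[D < r_cut]
    counts <- counts + graphics::hist(d, breaks = edges, plot = FALSE,
                                      right = FALSE)$counts
  }
  rho <- length(itar) / L^3
  nfr <- length(traj$snapshots)
  shell_vol <- (4 * pi / 3) * diff(edges^3)
  g <- counts / (length(iref) * nfr * rho * shell_vol)
  structure(list(bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 g = g, raw_counts = counts, bin_width = bin_width,
                 solvent_density = rho, n_reference = length(iref),
                 n_frames = nfr, r_max = NA_real_, r_min1 = NA_real_,
                 n_wat = NA_real_,
                 reference_selection = paste(deparse(reference), collapse = ""),
                 target_selection = paste(deparse(target), collapse = "")),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("RDF profile:", length(x$g), "bins of", x$bin_width, "A,",
      x$n_reference, "reference atoms,", x$n_frames, "frame(s)\n")
  if (is.finite(x$r_max))
    cat(sprintf("  first shell: r_max = %.3f A, r_min1 = %.3f A, n_wat = %.2f\n",
                x$r_max, x$r_min1, x$n_wat))
  invisible(x)
}

#' First solvation shell from an RDF profile
#'
#' After 3-bin moving-average smoothing, r_max is the center of the
#' first strict local maximum with g > 1, r_min1 the first strict local
#' minimum after it, and n_wat the coordination number
#' 4 pi rho sum g(r) r^2 dr over bins up to r_min1 (raw g). Locating the
#' first peak is ambiguous for structureless profiles, so a profile with
#' no qualifying maximum returns NA fields with `undefined = TRUE`
#' rather than fabricated values.
#'
#' @param profile an `"rdf_profile"` with at least 5 bins.
#' @return the profile with `r_max`, `r_min1`, `n_wat` filled (or an
#'   `undefined` flag).
#' @export
first_shell <- function(profile) {
  stopifnot(inherits(profile, "rdf_profile"))
  g <- profile$g
  if (length(g) < 5) .validation_error("need >= 5 RDF bins")
  s <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  s[is.na(s)] <- g[is.na(s)]
  s <- as.numeric(s)
  imax <- NA_integer_
  for (i in 2:(length(s) - 1)) {
    if (s[i] > s[i - 1] && s[i] > s[i + 1] && s[i] > 1) { imax <- i; break }
  }
  if (is.na(imax)) {
    profile$undefined <- TRUE
    return(profile)
  }
  imin <- NA_integer_
  for (i in (imax + 1):(length(s) - 1)) {
    if (s[i] < s[i - 1] && s[i] < s[i + 1]) { imin <- i; break }
  }
  if (is.na(imin)) imin <- length(s)  # shell unterminated within r_cut
  r <- profile$bin_centers
  dr <- profile$bin_width
  upto <- seq_len(imin)
  n_wat <- 4 * pi * profile$solvent_density * sum(g[upto] * r[upto]^2 * dr)
  profile$r_max <- r[imax]
  profile$r_min1 <- r[imin]
  profile$n_wat <- n_wat
  profile$undefined <- FALSE
  profile
}

#' Solute-counterion distance bins with per-bin gap averages
#'
#' Frames are partitioned by the minimum-image distance from the solute
#' center of mass to the counterion, with default edges 10 and 20 A
#' producing bins r < 10, 10 <= r <= 20, r > 20 (interior edges belong
#' to the bounded bin). The mean gap per bin tests whether the sampled
#' gaps depend on where the neutralizing ion happens to sit.
#'
#' @param traj a trajectory whose frames each contain one counterion.
#' @param gaps a gap ensemble, one gap per frame.
#' @param edges ascending bin edges, angstrom (default c(10, 20)).
#' @return object of class `"ion_distance_bins"`: data.frame `bins` with
#'   label, count, mean_gap, sd_gap, plus `distances`.
#' @export
ion_distance_bins <- function(traj, gaps, edges = c(10, 20)) {
  stopifnot(inherits(traj, "trajectory"), inherits(gaps, "gap_ensemble"))
  if (is.unsorted(edges, strictly = TRUE))
    .validation_error("edges must be strictly ascending")
  n <- length(traj$snapshots)
  if (length(gaps$gaps) != n)
    .validation_error("one gap per frame required")
  d <- numeric(n)
  for (k in seq_len(n)) {
    s <- traj$snapshots[[k]]
    ion <- which(s$atoms$role == "counterion")
    if (length(ion) != 1)
      .validation_error("counterion check failed: frame ", k, " has ",
                        length(ion), " counterions (exactly 1 required)")
    d[k] <- min_image_distance(solute_com(s),
                               as.numeric(s$atoms[ion, c("x", "y", "z")]),
                               s$box_edge)
  }
  ## bin 1: r < e1; bin k (interior): e_{k-1} <= r <= e_k; last: r > e_last
  nb <- length(edges) + 1L
  bin <- findInterval(d, edges) + 1L
  on_edge <- d %in% edges[-1]
  bin[on_edge] <- match(d[on_edge], edges)  # upper edge belongs to its bin
  labels <- c(paste0("r<", edges[1]),
              if (nb > 2) paste0(edges[-length(edges)], "<=r<=", edges[-1]),
              paste0("r>", edges[length(edges)]))
  g <- gaps$gaps
  bins <- data.frame(label = labels,
                     count = tabulate(bin, nbins = nb),
                     mean_gap = NA_real_, sd_gap = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nb)) {
    sel <- bin == k
    if (any(sel)) {
      bins$mean_gap[k] <- mean(g[sel])
      if (sum(sel) > 1) bins$sd_gap[k] <- stats::sd(g[sel])
    }
  }
  structure(list(bins = bins, edges = edges, distances = d),
            class = "ion_distance_bins")
}

#' @export
print.ion_distance_bins <- function(x, ...) {
  cat("Solute-counterion distance bins (A) with mean gap (eV)\n")
  print.data.frame(x$bins, row.names = FALSE, digits = 4)
  invisible(x)
}
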