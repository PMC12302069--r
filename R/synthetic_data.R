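## Synthetic study conditions: gap ensembles obeying linear-response
## statistics and solvated cubic boxes with a rigid solute template,
## 3-site rigid waters and an optional neutralizing counterion. Frames
## are independent draws, not time-correlated dynamics.

#' Configuration for the synthetic gap generator
#'
#' Under linear response the reduced-state gaps are
#' Normal(dG + lambda, sigma) and the oxidized-state gaps
#' Normal(dG - lambda, sigma) with sigma^2 = 2 k_B T lambda.
#'
#' @param dG_true true oxidation free energy, eV.
#' @param lambda_true true reorganization energy, eV (>= 0).
#' @param temperature K (default 310).
#' @param n_per_state samples per state (default 500, one per frame of a
#'   production run).
#' @param seed RNG seed.
#' @param skew skew-normal shape parameter (0 = Gaussian); non-zero
#'   values keep the mean and variance matched while breaking symmetry,
#'   for robustness checks.
#' @return list of class `"synthetic_gap_config"`.
#' @export
synthetic_gap_config <- function(dG_true, lambda_true,
                                 temperature = redox_constants$T_default,
                                 n_per_state = 500L, seed = 1L, skew = 0) {
  if (!is.finite(lambda_true) || lambda_true < 0)
    .validation_error("lambda_true must be >= 0")
  if (n_per_state < 1) .validation_error("n_per_state must be >= 1")
  structure(list(dG_true = dG_true, lambda_true = lambda_true,
                 temperature = temperature,
                 n_per_state = as.integer(n_per_state),
                 seed = as.integer(seed), skew = skew),
            class = "synthetic_gap_config")
}

## standardized skew-normal draws (mean 0, var 1) with shape alpha
.rskewnorm_std <- function(n, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (z - mu) / sqrt(1 - mu^2)
}

#' Generate a pair of linear-response gap ensembles
#'
#' Fully determined by the seed in the config.
#'
#' @param cfg a [synthetic_gap_config()].
#' @return list with `reduced` and `oxidized` gap ensembles.
#' @export
generate_gap_ensembles <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_gap_config"))
  kT <- redox_constants$k_B * cfg$temperature
  sigma <- sqrt(2 * kT * cfg$lambda_true)
  n <- cfg$n_per_state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  draw <- function() {
    if (cfg$skew == 0) stats::rnorm(n) else .rskewnorm_std(n, cfg$skew)
  }
  g_red <- cfg$dG_true + cfg$lambda_true + sigma * draw()
  g_ox <- cfg$dG_true - cfg$lambda_true + sigma * draw()
  list(reduced = gap_ensemble(g_red, "reduced", cfg$temperature),
       oxidized = gap_ensemble(g_ox, "oxidized", cfg$temperature))
}

#' Rigid solute templates
#'
#' Idealized geometric stand-ins for the benchmark molecule set: regular
#' polygon rings with 1.4 A bonds and hand-assigned partial charges
#' whose sums give the correct formal charges with ox - red = +1
#' overall. The charges are plausible bookkeeping values, not derived
#' from any electronic-structure calculation.
#'
#' Available templates: `ring6` (benzene-like C6H6, neutral), `ring6-OH`
#' (phenol-like, neutral, with a hydroxyl), `ring6-O-` (phenolate-like,
#' anionic), `ring9` (indole-sized 9-heavy-atom bicyclic stand-in,
#' neutral), `tricycle` (lumiflavin-sized fused three-ring stand-in,
#' neutral).
#'
#' @param name template name.
#' @return an atom table with role "solute" and both charge sets.
#' @export
solute_template <- function(name) {
  templates <- c("ring6", "ring6-OH", "ring6-O-", "ring9", "tricycle")
  if (!name %in% templates)
    .validation_error("unknown template '", name, "'; available: ",
                      paste(templates, collapse = ", "))
  ring <- function(n, r, z = 0, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1) / n
    cbind(r * cos(th), r * sin(th), z)
  }
  bond <- 1.4
  if (name %in% c("ring6", "ring6-OH", "ring6-O-")) {
    rC <- bond  # hexagon circumradius equals the bond length
    C <- ring(6, rC)
    H <- ring(6, rC + 1.08)
    el <- c(rep("C", 6), rep("H", 6))
    xyz <- rbind(C, H)
    if (name != "ring6") {
      ## replace H1 with an exocyclic O along the C1 direction
      xyz[7, ] <- C[1, ] * ((rC + bond) / rC)
      el[7] <- "O"
      if (name == "ring6-OH") {
        xyz <- rbind(xyz, xyz[7, ] + c(0.76, 0.59, 0))
        el <- c(el, "H")
      }
    }
    n_heavy <- sum(el != "H")
    q_formal <- if (name == "ring6-O-") -1 else 0
    q_red <- ifelse(el == "H", 0.10, (q_formal - 0.10 * sum(el == "H")) / n_heavy)
    q_ox <- q_red + ifelse(el != "H", 1 / n_heavy, 0)
  } else if (name == "ring9") {
    ## two fused rings approximated by 9 heavy atoms on two circles
    A <- ring(6, bond)
    B <- ring(5, 1.19, phase = pi)[1:3, ] + matrix(rep(c(2.2, 0, 0), 3),
                                                   ncol = 3, byrow = TRUE)
    heavy <- rbind(A, B)
    el_h <- c(rep("C", 8), "N")
    H <- sweep(heavy[c(2:6, 8, 9), ], 2, c(0, 0, 0)) * 1.45
    el <- c(el_h, rep("H", nrow(H)))
    xyz <- rbind(heavy, H)
    n_heavy <- 9
    q_red <- ifelse(el == "H", 0.10, -0.10 * sum(el == "H") / n_heavy)
    q_ox <- q_red + ifelse(el != "H", 1 / n_heavy, 0)
  } else {  # tricycle
    A <- ring(6, bond)
    B <- A + matrix(rep(c(2.42, 0, 0), 6), ncol = 3, byrow = TRUE)
    C3 <- A + matrix(rep(c(4.84, 0, 0), 6), ncol = 3, byrow = TRUE)
    heavy <- rbind(A, B, C3)
    el_h <- c(rep("C", 12), rep("N", 4), rep("O", 2))
    H <- sweep(heavy[seq(1, 17, by = 2), ], 2, c(2.42, 0, 0)) * 1.25 +
      matrix(rep(c(2.42, 0, 0.9), 9), ncol = 3, byrow = TRUE)
    el <- c(el_h, rep("H", nrow(H)))
    xyz <- rbind(heavy, H)
    n_heavy <- 18
    q_red <- ifelse(el == "H", 0.10, -0.10 * sum(el == "H") / n_heavy)
    q_ox <- q_red + ifelse(el != "H", 1 / n_heavy, 0)
  }
  atom_table(el, xyz[, 1], xyz[, 2], xyz[, 3], q_red, q_ox,
             role = "solute", residue_id = 1L)
}

#' Configuration for the synthetic solvated-box generator
#'
#' @param solute_template template name (see [solute_template()]).
#' @param n_waters number of water molecules.
#' @param box_edge cubic box edge, angstrom (default 50).
#' @param include_counterion place one monovalent counterion chosen to
#'   neutralize the system (Cl- unless the reduced solute is anionic, in
#'   which case Na+).
#' @param n_frames number of independent frames.
#' @param jitter_sd per-frame Gaussian jitter applied to the solute
#'   atoms, angstrom (default 0.05).
#' @param seed RNG seed.
#' @return list of class `"synthetic_box_config"`.
#' @export
synthetic_box_config <- function(solute_template = "ring6", n_waters = 500L,
                                 box_edge = 50, include_counterion = TRUE,
                                 n_frames = 1L, jitter_sd = 0.05, seed = 1L) {
  if (n_waters < 0) .validation_error("n_waters must be >= 0")
  if (n_frames < 1) .validation_error("n_frames must be >= 1")
  structure(list(solute_template = solute_template,
                 n_waters = as.integer(n_waters), box_edge = box_edge,
                 include_counterion = isTRUE(include_counterion),
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_box_config")
}

## rigid 3-site water with O-H 0.9572 A and H-O-H 104.52 deg, randomly
## oriented about a given oxygen position; TIP3P-style charges
.place_water <- function(o_pos, rid) {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  h_local <- rbind(c(r_oh * sin(half), 0, r_oh * cos(half)),
                   c(-r_oh * sin(half), 0, r_oh * cos(half)))
  ## random rotation from a QR decomposition of a Gaussian matrix
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  h <- t(Q %*% t(h_local)) + matrix(rep(o_pos, 2), ncol = 3, byrow = TRUE)
  atom_table(c("O", "H", "H"),
             c(o_pos[1], h[, 1]), c(o_pos[2], h[, 2]), c(o_pos[3], h[, 3]),
             charge_red = c(-0.834, 0.417, 0.417),
             charge_ox = c(-0.834, 0.417, 0.417),
             role = "water", residue_id = rid)
}

#' Generate a synthetic solvated trajectory
#'
#' The solute sits at the box center (jittered per frame); water oxygens
#' are placed by seeded rejection sampling keeping every heavy-atom pair
#' at least 2.4 A apart under the minimum image, with hydrogens at the
#' rigid water geometry in a random orientation; the optional counterion
#' is placed uniformly at random at least 3 A from every solute atom.
#' Frames are independent placements.
#'
#' @param cfg a [synthetic_box_config()].
#' @return a trajectory.
#' @export
generate_solvated_box <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_box_config"))
  L <- cfg$box_edge
  sol0 <- solute_template(cfg$solute_template)
  center <- L / 2
  sol0[, c("x", "y", "z")] <- sweep(as.matrix(sol0[, c("x", "y", "z")]), 2,
                                    colMeans(as.matrix(sol0[, c("x", "y", "z")])) - center)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  min_sep <- 2.4
  snaps <- vector("list", cfg$n_frames)
  for (fr in seq_len(cfg$n_frames)) {
    sol <- sol0
    if (cfg$jitter_sd > 0) {
      sol$x <- sol$x + stats::rnorm(nrow(sol), 0, cfg$jitter_sd)
      sol$y <- sol$y + stats::rnorm(nrow(sol), 0, cfg$jitter_sd)
      sol$z <- sol$z + stats::rnorm(nrow(sol), 0, cfg$jitter_sd)
    }
    heavy <- as.matrix(sol[toupper(sol$element) != "H", c("x", "y", "z")])
    o_pos <- matrix(0, 0, 3)
    attempts <- 0L
    while (nrow(o_pos) < cfg$n_waters) {
      attempts <- attempts + 1L
      if (attempts > 1e5)
        .validation_error("water placement failed after 1e5 attempts; ",
                          "reduce n_waters or enlarge the box")
      p <- stats::runif(3, 0, L)
      occupied <- rbind(heavy, o_pos)
      if (nrow(occupied) == 0 ||
          min(min_image_distance(occupied, p, L)) >= min_sep)
        o_pos <- rbind(o_pos, p)
    }
    atoms <- sol
    rid <- 1L
    if (cfg$n_waters > 0) {
      wl <- vector("list", cfg$n_waters)
      for (w in seq_len(cfg$n_waters)) {
        rid <- rid + 1L
        wl[[w]] <- .place_water(o_pos[w, ], rid)
      }
      atoms <- rbind(atoms, do.call(rbind, wl))
    }
    if (cfg$include_counterion) {
      q_sol_red <- sum(sol$charge_red)
      ion_el <- if (q_sol_red < -0.5) "NA" else "CL"
      ion_q <- if (ion_el == "NA") 1 else -1
      S <- as.matrix(sol[, c("x", "y", "z")])
      repeat {
        p <- stats::runif(3, 0, L)
        if (min(min_image_distance(S, p, L)) >= 3 &&
            (nrow(o_pos) == 0 || min(min_image_distance(o_pos, p, L)) >= min_sep))
          break
      }
      atoms <- rbind(atoms, atom_table(ion_el, p[1], p[2], p[3],
                                       charge_red = ion_q, charge_ox = ion_q,
                                       role = "counterion",
                                       residue_id = rid + 1L))
    }
    snaps[[fr]] <- snapshot(atoms, L, fr)
  }
  trajectory(snaps)
}
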