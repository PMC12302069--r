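## Free-energy estimation from vertical energy gap (VEG) ensembles.
##
## The reaction is one-electron oxidation, Reduced -> Oxidized + e-, with
## the gap defined as dE = E_ox - E_red at fixed nuclei. Under linear
## response the two state distributions of dE are Gaussians with means
## dG +/- lambda and common variance 2*k_B*T*lambda; the free energy is
## the half-sum of the mean gaps and the reorganization energy the
## half-difference.

#' Construct a gap ensemble
#'
#' A labeled vector of vertical energy gaps for one oxidation state at
#' one QM cutoff.
#'
#' @param gaps numeric vector of gaps dE = E_ox - E_red, eV.
#' @param state "reduced" or "oxidized" (which surface was sampled).
#' @param temperature simulation temperature, K (default 310).
#' @param cutoff_label text label for the QM cutoff the gaps belong to.
#' @return an object of class `"gap_ensemble"`.
#' @export
gap_ensemble <- function(gaps, state = c("reduced", "oxidized"),
                         temperature = redox_constants$T_default,
                         cutoff_label = "7.5") {
  state <- match.arg(state)
  gaps <- as.numeric(gaps)
  if (length(gaps) < 1) .validation_error("gap ensemble needs >= 1 sample")
  if (any(!is.finite(gaps))) .validation_error("non-finite gap values")
  if (!is.finite(temperature) || temperature <= 0)
    .validation_error("temperature must be > 0 K")
  structure(list(state = state, gaps = gaps, temperature = temperature,
                 cutoff_label = as.character(cutoff_label)),
            class = "gap_ensemble")
}

#' @export
print.gap_ensemble <- function(x, ...) {
  cat("Gap ensemble (", x$state, "), n = ", length(x$gaps),
      ", cutoff ", x$cutoff_label, ", T = ", x$temperature, " K\n",
      "  mean ", sprintf("%.4f", mean(x$gaps)), " eV, sd ",
      sprintf("%.4f", stats::sd(x$gaps)), " eV\n", sep = "")
  invisible(x)
}

#' Split a gap table into per-state ensembles
#'
#' @param table a gap table (see [read_gap_table()]).
#' @param cutoff which cutoff label to extract (default: the only one
#'   present; error if ambiguous).
#' @param temperature temperature attached to the ensembles, K.
#' @return list with elements `reduced` and `oxidized` (either may be
#'   NULL if that state is absent).
#' @export
ensembles_from_table <- function(table, cutoff = NULL,
                                 temperature = redox_constants$T_default) {
  cuts <- unique(table$cutoff)
  if (is.null(cutoff)) {
    if (length(cuts) > 1)
      .validation_error("table has multiple cutoffs (",
                        paste(cuts, collapse = ", "), "); pick one")
    cutoff <- cuts
  }
  sub <- table[table$cutoff == cutoff, , drop = FALSE]
  mk <- function(st) {
    g <- sub$gap_eV[sub$state == st]
    if (length(g) == 0) return(NULL)
    gap_ensemble(g, st, temperature, cutoff)
  }
  list(reduced = mk("reduced"), oxidized = mk("oxidized"))
}

#' Ensemble-average vertical energy gap (AVEG)
#'
#' @param ensemble a gap ensemble.
#' @return arithmetic mean gap, eV.
#' @export
average_gap <- function(ensemble) {
  stopifnot(inherits(ensemble, "gap_ensemble"))
  mean(ensemble$gaps)
}

#' Exponential-average (Zwanzig) oxidation free energy
#'
#' One-sided free-energy perturbation between the reduced and oxidized
#' surfaces using the gap as the perturbation energy. Sampling the
#' reduced state gives the forward direction
#' \deqn{\Delta G = -k_B T \ln \langle e^{-\Delta E/k_B T}\rangle_{red},}
#' sampling the oxidized state the reverse direction
#' \deqn{\Delta G = +k_B T \ln \langle e^{+\Delta E/k_B T}\rangle_{ox}.}
#' Evaluated by log-sum-exp (max exponent subtracted), so no overflow
#' occurs for |dE|/k_BT up to several hundred.
#'
#' Exponential averages converge extremely slowly when the gap spread is
#' large relative to k_BT (the average is dominated by rarely sampled
#' tails); for aqueous redox gaps, where sd(dE) is roughly ten k_BT, the
#' finite-sample estimate is systematically biased at any practical
#' sample size and the linear-response estimator [lra_free_energy()] is
#' the usable one. This function is exact in the narrow-spread limit and
#' is provided for the full exponential formula.
#'
#' @param ensemble a gap ensemble (either state).
#' @return free energy of oxidation, eV.
#' @export
zwanzig_free_energy <- function(ensemble) {
  stopifnot(inherits(ensemble, "gap_ensemble"))
  kT <- redox_constants$k_B * ensemble$temperature
  g <- ensemble$gaps
  lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  if (ensemble$state == "reduced") -kT * lse(-g / kT) else kT * lse(g / kT)
}

#' Fit the linear-response oxidation free energy
#'
#' The central estimator: truncating the exponential free-energy formula
#' after the first cumulant on each surface gives
#' \deqn{\Delta G^\circ_{ox} = \tfrac12(\langle\Delta E\rangle_{red} +
#'   \langle\Delta E\rangle_{ox}), \qquad
#'   \lambda = \tfrac12(\langle\Delta E\rangle_{red} -
#'   \langle\Delta E\rangle_{ox}),}
#' where lambda is the reorganization energy (half the splitting of the
#' two displaced Marcus surfaces). Uncertainty comes from a seeded
#' within-state paired bootstrap (percentile 2.5/97.5 interval).
#'
#' @param red gap ensemble sampled on the reduced surface.
#' @param ox gap ensemble sampled on the oxidized surface.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `"lra_fit"` with components `dG_ox`,
#'   `mean_red`, `mean_ox`, `lambda_reorg`, `sd_red`, `sd_ox`, `ci_dG`,
#'   `n_red`, `n_ox`, `temperature`, `boot_dG`, and `anomalous_lambda`
#'   (TRUE when mean_red < mean_ox, i.e. a negative reorganization
#'   energy, which is physically anomalous but not an error).
#' @seealso [oxidation_potential()], [marcus_parabolas()]
#' @examples
#' red <- gap_ensemble(rnorm(500, 9.32, 0.23), "reduced")
#' ox  <- gap_ensemble(rnorm(500, 4.95, 0.23), "oxidized")
#' fit <- lra_free_energy(red, ox, seed = 1)
#' coef(fit)
#' @export
lra_free_energy <- function(red, ox, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(red, "gap_ensemble"), inherits(ox, "gap_ensemble"))
  if (red$state != "reduced" || ox$state != "oxidized")
    .validation_error("arguments must be (reduced, oxidized) ensembles, got (",
                      red$state, ", ", ox$state, ")")
  if (abs(red$temperature - ox$temperature) > 1e-9)
    .validation_error("ensemble temperatures differ (", red$temperature,
                      " vs ", ox$temperature, " K)")
  m_red <- mean(red$gaps); m_ox <- mean(ox$gaps)
  dG <- (m_red + m_ox) / 2
  lam <- (m_red - m_ox) / 2
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      nr <- length(red$gaps); no <- length(ox$gaps)
      ir <- matrix(sample.int(nr, nr * n_boot, replace = TRUE), nrow = nr)
      io <- matrix(sample.int(no, no * n_boot, replace = TRUE), nrow = no)
      (colMeans(matrix(red$gaps[ir], nrow = nr)) +
         colMeans(matrix(ox$gaps[io], nrow = no))) / 2
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
    ci <- c(min(ci[1], dG), max(ci[2], dG))  # percentile CI always brackets the point estimate
  }
  structure(list(
    dG_ox = dG, mean_red = m_red, mean_ox = m_ox, lambda_reorg = lam,
    sd_red = stats::sd(red$gaps), sd_ox = stats::sd(ox$gaps),
    ci_dG = ci, n_red = length(red$gaps), n_ox = length(ox$gaps),
    temperature = red$temperature, cutoff_label = red$cutoff_label,
    boot_dG = boot, anomalous_lambda = lam < 0,
    gaps_red = red$gaps, gaps_ox = ox$gaps
  ), class = "lra_fit")
}

#' @export
print.lra_fit <- function(x, ...) {
  cat("Linear-response oxidation free energy\n")
  cat(sprintf("  <dE>_red = %.4f eV (n=%d, sd=%.4f)\n", x$mean_red, x$n_red,
              x$sd_red))
  cat(sprintf("  <dE>_ox  = %.4f eV (n=%d, sd=%.4f)\n", x$mean_ox, x$n_ox,
              x$sd_ox))
  cat(sprintf("  dG_ox    = %.4f eV", x$dG_ox))
  if (all(is.finite(x$ci_dG)))
    cat(sprintf("  [95%% CI %.4f, %.4f]", x$ci_dG[1], x$ci_dG[2]))
  cat(sprintf("\n  lambda   = %.4f eV\n", x$lambda_reorg))
  if (x$anomalous_lambda)
    cat("  warning: mean_red < mean_ox (negative reorganization energy)\n")
  invisible(x)
}

#' @export
coef.lra_fit <- function(object, ...) {
  c(dG_ox = object$dG_ox, lambda_reorg = object$lambda_reorg,
    mean_red = object$mean_red, mean_ox = object$mean_ox)
}

#' @export
confint.lra_fit <- function(object, parm = "dG_ox", level = 0.95, ...) {
  if (length(object$boot_dG) == 0)
    .validation_error("fit carries no bootstrap samples (n_boot = 0)")
  a <- (1 - level) / 2
  q <- stats::quantile(object$boot_dG, c(a, 1 - a), type = 7)
  out <- matrix(unname(q), nrow = 1,
                dimnames = list("dG_ox", sprintf("%.1f %%", 100 * c(a, 1 - a))))
  out
}

#' @export
summary.lra_fit <- function(object, dG_SHE = redox_constants$dG_SHE, ...) {
  kT <- redox_constants$k_B * object$temperature
  structure(list(
    fit = object,
    E_ox = oxidation_potential(object$dG_ox, dG_SHE),
    dG_SHE = dG_SHE,
    sigma_lr = sqrt(2 * kT * max(object$lambda_reorg, 0)),
    se_dG = sqrt(object$sd_red^2 / object$n_red +
                   object$sd_ox^2 / object$n_ox) / 2
  ), class = "summary.lra_fit")
}

#' @export
print.summary.lra_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  E_ox vs SHE = %.4f V (dG_SHE = %.2f eV)\n", x$E_ox, x$dG_SHE))
  cat(sprintf("  analytic SE(dG) = %.4f eV; LR-consistent gap sd = %.4f eV\n",
              x$se_dG, x$sigma_lr))
  invisible(x)
}

#' Predicted Marcus free-energy surfaces
#'
#' Evaluates the two linear-response parabolas at gap-coordinate values.
#'
#' @param object an `"lra_fit"`.
#' @param newdata numeric vector of gap-coordinate abscissae (eV);
#'   default spans both wells.
#' @param ... unused.
#' @return data.frame with columns `x`, `G_red`, `G_ox` (eV).
#' @export
predict.lra_fit <- function(object, newdata = NULL, ...) {
  p <- marcus_parabolas(object)
  if (is.null(newdata)) {
    lo <- object$mean_ox - 2 * object$lambda_reorg
    hi <- object$mean_red + 2 * object$lambda_reorg
    newdata <- seq(lo, hi, length.out = 201)
  }
  evalq3 <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2
  data.frame(x = newdata,
             G_red = evalq3(p$G_red, newdata),
             G_ox = evalq3(p$G_ox, newdata))
}

#' Residuals of a linear-response fit
#'
#' Gaps minus their state mean, concatenated (reduced first); under the
#' linear-response model both sets are mean-zero Gaussians with common
#' sd sqrt(2 k_B T lambda).
#'
#' @param object an `"lra_fit"`.
#' @param ... unused.
#' @return numeric vector with a `state` attribute.
#' @export
residuals.lra_fit <- function(object, ...) {
  r <- c(object$gaps_red - object$mean_red, object$gaps_ox - object$mean_ox)
  attr(r, "state") <- rep(c("reduced", "oxidized"),
                          c(object$n_red, object$n_ox))
  r
}

#' Simulate gap ensembles from a fitted model
#'
#' Draws new reduced/oxidized ensembles from the fitted dG, lambda and
#' temperature using the linear-response generative model (see
#' [generate_gap_ensembles()]).
#'
#' @param object an `"lra_fit"`.
#' @param nsim number of replicate pairs.
#' @param seed RNG seed.
#' @param n_per_state samples per state per replicate (default: the
#'   fitted n_red).
#' @param ... unused.
#' @return list of `nsim` lists, each with `reduced` and `oxidized`
#'   ensembles.
#' @export
simulate.lra_fit <- function(object, nsim = 1, seed = 1L,
                             n_per_state = object$n_red, ...) {
  lapply(seq_len(nsim), function(k) {
    cfg <- synthetic_gap_config(dG_true = object$dG_ox,
                                lambda_true = max(object$lambda_reorg, 0),
                                temperature = object$temperature,
                                n_per_state = n_per_state,
                                seed = seed + k - 1L)
    generate_gap_ensembles(cfg)
  })
}

#' Plot a linear-response fit
#'
#' Left panel: the two Marcus parabolas with well positions marked.
#' Right panel: per-state gap histograms. Base graphics.
#'
#' @param x an `"lra_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lra_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (x$lambda_reorg > 0) {
    pr <- predict(x)
    graphics::matplot(pr$x, cbind(pr$G_red, pr$G_ox), type = "l", lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = "gap coordinate dE (eV)", ylab = "G (eV)",
                      main = "Marcus surfaces", ...)
    graphics::abline(v = c(x$mean_red, x$mean_ox), lty = 3, col = "grey50")
    graphics::legend("top", c("reduced", "oxidized"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  } else {
    graphics::plot.new()
    graphics::title(main = "lambda <= 0: no parabolas")
  }
  rng <- range(c(x$gaps_red, x$gaps_ox))
  br <- seq(rng[1], rng[2] + 0.05, by = 0.05)
  hr <- graphics::hist(x$gaps_red, breaks = br, plot = FALSE)
  ho <- graphics::hist(x$gaps_ox, breaks = br, plot = FALSE)
  ylim <- c(0, max(hr$counts, ho$counts))
  graphics::plot(hr, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, xlim = rng, ylim = ylim, main = "gap samples",
                 xlab = "dE (eV)")
  graphics::plot(ho, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, add = TRUE)
  invisible(x)
}

#' Marcus parabola coefficients
#'
#' The linear-response construction places two parabolas of common
#' curvature 1/(4 lambda) on the gap coordinate:
#' G_red(x) = (x - mean_red)^2 / (4 lambda) and
#' G_ox(x) = (x - mean_ox)^2 / (4 lambda) + dG_ox, which satisfy the
#' identity G_ox(x) - G_red(x) = x for all x.
#'
#' @param result an `"lra_fit"` (or any list with mean_red, mean_ox,
#'   lambda_reorg, dG_ox).
#' @return list with `G_red` and `G_ox`, each a numeric triple
#'   (intercept, linear, quadratic) in eV units.
#' @export
marcus_parabolas <- function(result) {
  lam <- result$lambda_reorg
  if (!is.finite(lam) || lam <= 0)
    .validation_error("marcus_parabolas requires lambda_reorg > 0, got ",
                      format(lam))
  a <- 1 / (4 * lam)
  g_red <- c(a * result$mean_red^2, -2 * a * result$mean_red, a)
  g_ox <- c(a * result$mean_ox^2 + result$dG_ox, -2 * a * result$mean_ox, a)
  list(G_red = g_red, G_ox = g_ox)
}

#' Running average of a gap ensemble
#'
#' Element k is the mean of the first k gaps; the convergence diagnostic
#' plotted against frame number.
#'
#' @param ensemble a gap ensemble.
#' @return numeric vector of the same length as the gaps.
#' @export
running_average <- function(ensemble) {
  stopifnot(inherits(ensemble, "gap_ensemble"))
  cumsum(ensemble$gaps) / seq_along(ensemble$gaps)
}

#' Gap histogram and mode count
#'
#' Histograms the gaps at a fixed bin width over [min, max] and counts
#' strict local maxima after 3-bin moving-average smoothing; a converged
#' unimodal ensemble has one mode.
#'
#' @param ensemble a gap ensemble.
#' @param bin_width histogram bin width, eV (default 0.05).
#' @param smooth_window moving-average window in bins (default 3).
#' @return list with `bin_edges`, `counts`, `n_modes`.
#' @export
gap_histogram_modes <- function(ensemble, bin_width = 0.05,
                                smooth_window = 3) {
  stopifnot(inherits(ensemble, "gap_ensemble"))
  if (!is.finite(bin_width) || bin_width <= 0)
    .validation_error("bin_width must be > 0")
  g <- ensemble$gaps
  rng <- range(g)
  if (bin_width >= diff(rng) || diff(rng) == 0) {
    return(list(bin_edges = c(rng[1], rng[1] + max(bin_width, diff(rng))),
                counts = length(g), n_modes = 1L))
  }
  edges <- seq(rng[1], rng[2] + bin_width, by = bin_width)
  counts <- graphics::hist(g, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  s <- stats::filter(counts, rep(1 / smooth_window, smooth_window),
                     sides = 2)
  s[is.na(s)] <- counts[is.na(s)]
  s <- as.numeric(s)
  n_modes <- 0L
  if (length(s) >= 3) {
    for (i in 2:(length(s) - 1))
      if (s[i] > s[i - 1] && s[i] > s[i + 1]) n_modes <- n_modes + 1L
  }
  if (n_modes == 0L) n_modes <- 1L  # monotone or flat profile: one mode
  list(bin_edges = edges, counts = counts, n_modes = n_modes)
}

#' PCA decorrelation diagnostic
#'
#' Checks that the sampled gaps are uncorrelated with the dominant
#' conformational motions. Solute coordinates of every frame are
#' rigid-body aligned to frame 1 (centroids removed, optimal rotation by
#' the orthogonal-Procrustes/Kabsch SVD solution), PCA is an
#' eigendecomposition of the aligned-coordinate covariance, and Pearson
#' correlations of the first two principal-component projections against
#' the gaps are reported. Independent sampling shows all three
#' correlations near zero.
#'
#' @param traj a trajectory (one gap per snapshot, same order).
#' @param ensemble the matching gap ensemble.
#' @return list of class `"convergence_report"` with `running_mean`,
#'   `histogram`, `n_modes`, `pc_gap_correlations` (named |rho| values
#'   for PC1-gap, PC2-gap, PC1-PC2), `pc_variance`.
#' @export
decorrelation_check <- function(traj, ensemble) {
  stopifnot(inherits(traj, "trajectory"), inherits(ensemble, "gap_ensemble"))
  n <- length(traj$snapshots)
  if (n < 3) .validation_error("need >= 3 snapshots for PCA")
  if (length(ensemble$gaps) != n)
    .validation_error("one gap per snapshot required (", length(ensemble$gaps),
                      " gaps, ", n, " frames)")
  sol_idx <- which(traj$snapshots[[1]]$atoms$role == "solute")
  if (length(sol_idx) < 3)
    .validation_error("alignment needs >= 3 solute atoms")
  ref <- as.matrix(traj$snapshots[[1]]$atoms[sol_idx, c("x", "y", "z")])
  ref <- sweep(ref, 2, colMeans(ref))
  X <- matrix(0, n, 3 * length(sol_idx))
  for (k in seq_len(n)) {
    P <- as.matrix(traj$snapshots[[k]]$atoms[sol_idx, c("x", "y", "z")])
    P <- sweep(P, 2, colMeans(P))
    sv <- svd(crossprod(P, ref))
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    X[k, ] <- as.vector(t(R %*% t(P)))  # aligned coords, row-flattened
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 2)
  pc_var <- sv$d^2 / (n - 1)
  proj1 <- as.numeric(Xc %*% sv$v[, 1])
  proj2 <- as.numeric(Xc %*% sv$v[, 2])
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    abs(stats::cor(a, b))
  }
  g <- ensemble$gaps
  rho <- c(pc1_gap = safe_cor(proj1, g), pc2_gap = safe_cor(proj2, g),
           pc1_pc2 = safe_cor(proj1, proj2))
  hm <- gap_histogram_modes(ensemble)
  structure(list(running_mean = running_average(ensemble),
                 histogram = hm[c("bin_edges", "counts")],
                 n_modes = hm$n_modes, pc_gap_correlations = rho,
                 pc_variance = pc_var[1:2]),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report\n")
  cat(sprintf("  final running mean: %.4f eV over %d frames\n",
              x$running_mean[length(x$running_mean)], length(x$running_mean)))
  cat(sprintf("  histogram modes: %d\n", x$n_modes))
  cat(sprintf("  |rho|: PC1-gap %.3f, PC2-gap %.3f, PC1-PC2 %.3f\n",
              x$pc_gap_correlations[1], x$pc_gap_correlations[2],
              x$pc_gap_correlations[3]))
  invisible(x)
}
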