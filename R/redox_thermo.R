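## Electrode potentials from oxidation free energies.
##
## E = (dG_ox - dG_SHE) / (n F) in the Nernst convention; with energies
## expressed in eV per transferred electron the Faraday constant cancels
## numerically (1 eV per e- corresponds to 1 V), so no explicit F appears.

#' Oxidation potential vs the standard hydrogen electrode
#'
#' @param dG_ox oxidation free energy, eV per transferred electron.
#' @param dG_SHE absolute SHE oxidation free energy, eV (default 4.44).
#' @param n_electrons number of electrons transferred (>= 1).
#' @return potential vs SHE, volt.
#' @examples
#' oxidation_potential(7.135)  # 2.695 V
#' @export
oxidation_potential <- function(dG_ox, dG_SHE = redox_constants$dG_SHE,
                                n_electrons = 1L) {
  if (!is.numeric(n_electrons) || n_electrons < 1 ||
      n_electrons != round(n_electrons))
    .validation_error("n_electrons must be an integer >= 1")
  (dG_ox - dG_SHE) / n_electrons
}

#' Construct a redox record
#'
#' One molecule/sampling-protocol combination with its free energy and
#' derived potential, optionally with an experimental value or range.
#'
#' @param molecule molecule name.
#' @param sampling_label sampling protocol label, e.g. "MM" or "QM/MM".
#' @param dG_ox oxidation free energy, eV.
#' @param dG_SHE SHE reference, eV.
#' @param E_expt optional experimental potential: a single value or a
#'   length-2 range (low, high), V vs SHE.
#' @return list of class `"redox_record"`.
#' @export
redox_record <- function(molecule, sampling_label, dG_ox,
                         dG_SHE = redox_constants$dG_SHE, E_expt = NULL) {
  structure(list(molecule = molecule, sampling_label = sampling_label,
                 dG_ox = dG_ox, E_ox = oxidation_potential(dG_ox, dG_SHE),
                 dG_SHE = dG_SHE, E_expt = E_expt),
            class = "redox_record")
}

#' Potential shift between two sampling protocols
#'
#' Signed difference E_ox(a) - E_ox(b) for the same molecule; quantifies
#' how much the conformational-sampling protocol moves the predicted
#' potential.
#'
#' @param record_a,record_b redox records for the same molecule.
#' @return shift in volt.
#' @export
sampling_shift <- function(record_a, record_b) {
  stopifnot(inherits(record_a, "redox_record"), inherits(record_b, "redox_record"))
  if (!identical(record_a$molecule, record_b$molecule))
    .validation_error("records are for different molecules ('",
                      record_a$molecule, "' vs '", record_b$molecule, "')")
  record_a$E_ox - record_b$E_ox
}

#' Bundled experimental oxidation potentials
#'
#' Static reference data (V vs SHE) for the benchmark molecule set, as a
#' data.frame with a citation key column. Ranges carry distinct low/high
#' values; point values repeat. These are literature data, not
#' computation; the benzene value was measured in acetonitrile and the
#' flavin value refers to FMN.
#'
#' @return data.frame with columns molecule, E_low, E_high, note.
#' @export
experimental_potentials <- function() {
  data.frame(
    molecule = c("benzene", "phenol", "phenolate", "indole", "lumiflavin"),
    E_low = c(2.72, 1.0, 0.83, 1.24, 0.101),
    E_high = c(2.72, 1.5, 0.86, 1.24, 0.101),
    note = c("in acetonitrile", "", "", "", "for FMN"),
    stringsAsFactors = FALSE
  )
}

#' Comparison table of computed and experimental potentials
#'
#' Assembles per-molecule rows with one (dG_ox, E_ox) column pair per
#' sampling protocol and an experimental column; experimental ranges
#' render as "low-high", missing values as blank.
#'
#' @param records list of redox records.
#' @return data.frame of class `"redox_comparison"`, one row per
#'   molecule, columns `dG_<label>` and `E_<label>` per sampling label
#'   plus `E_expt`.
#' @export
comparison_table <- function(records) {
  if (length(records) < 1) .validation_error("need >= 1 record")
  stopifnot(all(vapply(records, inherits, logical(1), "redox_record")))
  mols <- unique(vapply(records, `[[`, "", "molecule"))
  labs <- unique(vapply(records, `[[`, "", "sampling_label"))
  out <- data.frame(molecule = mols, stringsAsFactors = FALSE)
  for (lb in labs) {
    out[[paste0("dG_", lb)]] <- NA_real_
    out[[paste0("E_", lb)]] <- NA_real_
  }
  out$E_expt <- ""
  fmt_expt <- function(e) {
    if (is.null(e) || length(e) == 0) return("")
    if (length(e) == 2 && e[1] != e[2])
      sprintf("%.2f-%.2f", e[1], e[2])
    else sprintf("%.3g", e[1])
  }
  for (r in records) {
    i <- match(r$molecule, out$molecule)
    out[i, paste0("dG_", r$sampling_label)] <- r$dG_ox
    out[i, paste0("E_", r$sampling_label)] <- r$E_ox
    if (!is.null(r$E_expt)) out$E_expt[i] <- fmt_expt(r$E_expt)
  }
  class(out) <- c("redox_comparison", class(out))
  out
}

#' @export
print.redox_comparison <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v)
    ifelse(is.na(v), "", sprintf(paste0("%.", digits, "f"), round_half_up(v, digits))))
  cat("Oxidation free energies (eV) and potentials vs SHE (V)\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
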