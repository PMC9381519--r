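#' Construct an SLA archetype
#'
#' An archetype is the stated marker-expression world for one stage of
#' leukemia arrest: the fraction of blasts positive for each marker, the
#' two-component (negative/positive) log-normal intensity model per marker,
#' and the CD34+CD38-CD123+ leukemic stem cell (LSC) fraction. Event-level
#' simulation ([simulate_events()]) and cohort simulation
#' ([simulate_cohort()]) draw from these.
#'
#' The positive fractions must place the archetype strictly inside its own
#' classifier decision region (e.g. an MPP-L archetype has MPO < 0.10 and
#' CD34 >= 0.20); this is validated at construction.
#'
#' @param label one of [sla_levels()].
#' @param positive_fraction named numeric vector of per-marker probabilities
#'   in \[0, 1\]; must cover the six core markers; may add CD38, CD123, CD45.
#' @param lsc_fraction proportion of blasts with the CD34+CD38-CD123+
#'   phenotype, in \[0, 1\].
#' @param intensity named list with elements `neg` and `pos`, each a list
#'   `list(meanlog=, sdlog=)` giving the log-normal component shared by all
#'   markers (per-marker refinement is not needed for the synthetic world).
#' @param params [classifier_params()] used to validate region membership.
#' @return An object of class `sla_archetype`.
#' @export
sla_archetype <- function(label,
                          positive_fraction,
                          lsc_fraction = 0,
                          intensity = default_intensity_model(),
                          params = classifier_params()) {
  if (!label %in% sla_levels()) {
    slaml_stop(sprintf("unknown SLA label '%s'", label), "slaml_argument_error")
  }
  pf <- positive_fraction
  missing_core <- setdiff(core_markers(), names(pf))
  if (length(missing_core)) {
    slaml_stop(paste("archetype missing core markers:",
                     paste(missing_core, collapse = ", ")),
               "slaml_argument_error")
  }
  if (!is_prob(pf)) {
    slaml_stop("positive_fraction values must lie in [0, 1]", "slaml_argument_error")
  }
  if (!is_prob(lsc_fraction)) {
    slaml_stop("lsc_fraction must lie in [0, 1]", "slaml_argument_error")
  }
  # default joint-phenotype markers if not supplied: CD38 positive on all
  # non-LSC blasts (so the LSC compartment is exactly lsc_fraction), CD123
  # moderately expressed, CD45 on every leukocyte
  if (!"CD38" %in% names(pf))  pf[["CD38"]]  <- 1 - lsc_fraction
  if (!"CD123" %in% names(pf)) pf[["CD123"]] <- 0.6
  if (!"CD45" %in% names(pf))  pf[["CD45"]]  <- 1
  # the archetype must classify as itself at zero jitter
  prof <- as.list(100 * pf[core_markers()])
  names(prof) <- core_markers()
  got <- classify_sla(prof, params)$label
  if (got != label) {
    slaml_stop(sprintf(
      "archetype positive fractions fall in the %s decision region, not %s",
      got, label), "slaml_argument_error")
  }
  structure(
    list(label = label, positive_fraction = pf,
         lsc_fraction = lsc_fraction, intensity = intensity),
    class = "sla_archetype"
  )
}

#' Shared two-component log-normal intensity model
#'
#' Negative events sit around 50 arbitrary fluorescence units, positive
#' events around 500, both with sdlog 0.4, so a cutoff at 150 separates the
#' components with < 0.5% spillover either way.
#'
#' @return list with `neg` and `pos` components (`meanlog`, `sdlog`).
#' @export
default_intensity_model <- function() {
  list(neg = list(meanlog = log(50), sdlog = 0.4),
       pos = list(meanlog = log(500), sdlog = 0.4))
}

#' Default archetypes for the six stages of leukemia arrest
#'
#' Marker positive fractions follow the staged expression model: CD34+ in
#' immature arrest, MPO absent in HSC/MPP-L, intermediate (10-70%) in CMP-L
#' and high (>70%) in GMP-L; CD13/CD33 detectable from the MPP stage onward;
#' HLA-DR separating MP-L (positive) from GP-L (negative). LSC fractions
#' default to the reported per-stage medians (18.03% in HSC/MPP-L, 11.54%
#' CMP-L, 7.83% GMP-L, <1% in the mature stages).
#'
#' @param params [classifier_params()] used for validation.
#' @return Named list of `sla_archetype`, one per level of [sla_levels()].
#' @export
default_archetypes <- function(params = classifier_params()) {
  pf <- list(
    "HSC-L" = c(CD34 = 0.85, CD117 = 0.30, CD13 = 0.05, CD33 = 0.08,
                MPO = 0.02, "HLA-DR" = 0.60),
    "MPP-L" = c(CD34 = 0.80, CD117 = 0.50, CD13 = 0.60, CD33 = 0.70,
                MPO = 0.05, "HLA-DR" = 0.40),
    "CMP-L" = c(CD34 = 0.75, CD117 = 0.60, CD13 = 0.70, CD33 = 0.75,
                MPO = 0.40, "HLA-DR" = 0.50),
    "GMP-L" = c(CD34 = 0.85, CD117 = 0.60, CD13 = 0.70, CD33 = 0.65,
                MPO = 0.85, "HLA-DR" = 0.30),
    "GP-L"  = c(CD34 = 0.05, CD117 = 0.15, CD13 = 0.60, CD33 = 0.80,
                MPO = 0.45, "HLA-DR" = 0.08),
    "MP-L"  = c(CD34 = 0.05, CD117 = 0.10, CD13 = 0.60, CD33 = 0.80,
                MPO = 0.40, "HLA-DR" = 0.70)
  )
  lsc <- c("HSC-L" = 0.1803, "MPP-L" = 0.1803, "CMP-L" = 0.1154,
           "GMP-L" = 0.0783, "GP-L" = 0.005, "MP-L" = 0.005)
  out <- lapply(sla_levels(), function(s) {
    sla_archetype(s, pf[[s]], lsc_fraction = lsc[[s]], params = params)
  })
  names(out) <- sla_levels()
  out
}

#' @export
print.sla_archetype <- function(x, ...) {
  cat(sprintf("<sla_archetype> %s  (LSC fraction %.4f)\n", x$label, x$lsc_fraction))
  print(round(100 * x$positive_fraction, 1))
  invisible(x)
}
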