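#' Classifier thresholds
#'
#' Positivity on the percent-of-blasts scale: a marker is "+" at >= 20% of
#' blasts. Cytoplasmic MPO drives the CD34+ branch in three tiers: < 10%
#' (HSC/MPP-L), 10-70% inclusive (CMP-L), > 70% (GMP-L). HLA-DR splits the
#' CD34- branch at 20% (MP-L >= 20, GP-L < 20).
#'
#' @param positivity percent-of-blasts positivity threshold (default 20).
#' @param mpo_low lower MPO tier bound (default 10).
#' @param mpo_high upper MPO tier bound (default 70).
#' @param hladr_split HLA-DR split (default 20).
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(positivity = 20, mpo_low = 10, mpo_high = 70,
                              hladr_split = 20) {
  stopifnot(positivity > 0, positivity < 100,
            hladr_split > 0, hladr_split < 100,
            mpo_low > 0, mpo_high < 100, mpo_low < mpo_high)
  structure(list(positivity = positivity, mpo_low = mpo_low,
                 mpo_high = mpo_high, hladr_split = hladr_split),
            class = "classifier_params")
}

#' Assign the stage of leukemia arrest from a marker profile
#'
#' Decision tree over percent-of-blasts values, evaluated in order:
#' \enumerate{
#'   \item CD34 >= 20\%:
#'     (1a) CD13 < 20 and CD33 < 20 and MPO < 10 -> HSC-L;
#'     (1b) MPO < 10 -> MPP-L;
#'     (1c) 10 <= MPO <= 70 -> CMP-L;
#'     (1d) MPO > 70 -> GMP-L.
#'   \item CD34 < 20\%: HLA-DR >= 20 -> MP-L; HLA-DR < 20 -> GP-L.
#' }
#' Boundary ties: MPO exactly at a tier bound belongs to CMP-L; positivity
#' comparisons use `>=` (a marker is "+" at exactly 20%).
#'
#' The `atypical` flag records secondary-expectation violations that do not
#' change the label: a CD34+ non-HSC-L profile with both CD13 < 20 and
#' CD33 < 20 (i.e. MPO in myeloid range without myeloid surface markers),
#' or CD117 < 20 in a CD34+ profile.
#'
#' @param profile named list / one-row data.frame with the six core marker
#'   percentages (names as in [core_markers()], `HLA-DR` may be spelled
#'   `HLADR` or `HLA.DR`).
#' @param params [classifier_params()].
#' @return list of class `sla_label`: `label`, `atypical`, `rationale`
#'   (ordered rule identifiers fired).
#' @export
classify_sla <- function(profile, params = classifier_params()) {
  profile <- normalize_profile_names(profile)
  vals <- vapply(core_markers(), function(m) {
    v <- profile[[m]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      slaml_stop(sprintf("core marker '%s' missing or undefined", m),
                 "slaml_classification_error")
    }
    as.numeric(v)
  }, numeric(1))
  t <- params$positivity
  cd34 <- vals[["CD34"]]; cd117 <- vals[["CD117"]]
  cd13 <- vals[["CD13"]]; cd33 <- vals[["CD33"]]
  mpo <- vals[["MPO"]]; hladr <- vals[["HLA-DR"]]

  fired <- character(0)
  atypical <- FALSE
  if (cd34 >= t) {
    fired <- c(fired, "CD34+")
    if (cd13 < t && cd33 < t && mpo < params$mpo_low) {
      label <- "HSC-L"; fired <- c(fired, "CD13-/CD33-/MPO<low")
    } else if (mpo < params$mpo_low) {
      label <- "MPP-L"; fired <- c(fired, "MPO<low")
    } else if (mpo <= params$mpo_high) {
      label <- "CMP-L"; fired <- c(fired, "MPO in [low, high]")
    } else {
      label <- "GMP-L"; fired <- c(fired, "MPO>high")
    }
    if (label != "HSC-L" && cd13 < t && cd33 < t) {
      atypical <- TRUE; fired <- c(fired, "atypical: CD13-/CD33- with myeloid MPO")
    }
    if (cd117 < t) {
      atypical <- TRUE; fired <- c(fired, "atypical: CD117- in CD34+ profile")
    }
  } else {
    fired <- c(fired, "CD34-")
    if (hladr >= params$hladr_split) {
      label <- "MP-L"; fired <- c(fired, "HLA-DR+")
    } else {
      label <- "GP-L"; fired <- c(fired, "HLA-DR-")
    }
  }
  structure(list(label = label, atypical = atypical, rationale = fired),
            class = "sla_label")
}

#' @export
print.sla_label <- function(x, ...) {
  cat(sprintf("<sla_label> %s%s  [%s]\n", x$label,
              if (x$atypical) " (atypical)" else "",
              paste(x$rationale, collapse = "; ")), sep = "")
  invisible(x)
}

# accept HLADR / HLA.DR spellings from CSV round-trips
normalize_profile_names <- function(profile) {
  nm <- names(profile)
  nm[nm %in% c("HLADR", "HLA.DR", "HLA_DR")] <- "HLA-DR"
  names(profile) <- nm
  profile
}

#' Classify a cohort of marker profiles
#'
#' @param profiles data.frame, one row per patient, with `patient_id` (or
#'   rownames) and the six core marker percentage columns.
#' @param params [classifier_params()].
#' @return list of class `sla_cohort_labels`: `labels` (data.frame:
#'   patient_id, label, atypical, rationale), `frequency` (data.frame: sla,
#'   n, percent to one decimal), `n_atypical`.
#' @export
classify_cohort <- function(profiles, params = classifier_params()) {
  if (NROW(profiles) < 1) {
    slaml_stop("classify_cohort() needs at least one profile", "slaml_empty_cohort_error")
  }
  profiles <- normalize_profile_names(profiles)
  ids <- if ("patient_id" %in% names(profiles)) profiles$patient_id
         else as.character(seq_len(nrow(profiles)))
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    classify_sla(as.list(profiles[i, , drop = FALSE]), params)
  })
  labels <- data.frame(
    patient_id = ids,
    label = vapply(res, `[[`, character(1), "label"),
    atypical = vapply(res, `[[`, logical(1), "atypical"),
    rationale = vapply(res, function(r) paste(r$rationale, collapse = "; "),
                       character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels,
                 frequency = sla_frequency_table(labels$label),
                 n_atypical = sum(labels$atypical)),
            class = "sla_cohort_labels")
}

#' SLA frequency table at reporting precision
#'
#' @param labels character vector of SLA labels.
#' @return data.frame: sla, n, percent (one decimal, half-away-from-zero).
#'   Percentages sum to 100 within rounding.
#' @export
sla_frequency_table <- function(labels) {
  tab <- table(factor(labels, levels = sla_levels()))
  data.frame(sla = sla_levels(),
             n = as.integer(tab),
             percent = percent_of(as.integer(tab), sum(tab), 1),
             stringsAsFactors = FALSE)
}

#' Principal component projection of a marker-percentage matrix
#'
#' Column-centered (optionally unit-scaled) decomposition of the per-patient
#' percent-positive matrix over an extended marker set, as used to verify
#' that the six-marker signature separates the SLA groups.
#'
#' @param x numeric matrix / data.frame, patients x markers, no missing
#'   values, >= 2 rows and >= 2 columns.
#' @param scale. standardize columns to unit variance (default FALSE).
#' @return list of class `sla_pca`: `scores` (patients x components),
#'   `rotation`, `variance_explained` (non-negative, sums to 1).
#' @export
project_pca <- function(x, scale. = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    slaml_stop("project_pca() needs >= 2 patients and >= 2 markers",
               "slaml_argument_error")
  }
  if (anyNA(x)) {
    slaml_stop("marker matrix contains undefined values", "slaml_argument_error")
  }
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) {
    slaml_stop("constant marker matrix: degenerate decomposition",
               "slaml_degenerate_error")
  }
  if (scale. && any(sds == 0)) {
    slaml_stop("cannot unit-scale constant marker columns", "slaml_degenerate_error")
  }
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, rotation = pc$rotation,
                 variance_explained = ve),
            class = "sla_pca")
}
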