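#' Pipeline run configuration
#'
#' Exactly one of `simulate` (a [cohort_config()]) or `inputs` (paths to
#' profiles/genotypes/outcomes CSVs) must be supplied.
#'
#' @param simulate optional [cohort_config()] for a fully synthetic run.
#' @param inputs optional named list of paths: `profiles` (required),
#'   `genotypes`, `outcomes`.
#' @param classifier [classifier_params()].
#' @param analyses character subset of c("pca", "association", "survival",
#'   "saml") to enable.
#' @param out_dir optional directory; when given, all bundle tables are
#'   written there as CSV.
#' @param seed integer seed recorded in the manifest (and used for
#'   simulation when `simulate` carries no explicit seed).
#' @return object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       classifier = classifier_params(),
                       analyses = c("association", "survival"),
                       out_dir = NULL, seed = 1) {
  if (is.null(simulate) == is.null(inputs)) {
    slaml_stop("supply exactly one of `simulate` or `inputs`",
               "slaml_config_error")
  }
  if (!is.null(inputs) && is.null(inputs$profiles)) {
    slaml_stop("inputs$profiles path is required", "slaml_config_error")
  }
  bad <- setdiff(analyses, c("pca", "association", "survival", "saml"))
  if (length(bad)) {
    slaml_stop(paste("unknown analysis toggle(s):", paste(bad, collapse = ", ")),
               "slaml_config_error")
  }
  structure(list(simulate = simulate, inputs = inputs, classifier = classifier,
                 analyses = analyses, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# internal: read + schema-check a genotype CSV (0/1/NA flags)
read_genotypes <- function(path) {
  g <- read.csv(path, check.names = FALSE)
  for (col in setdiff(names(g), "patient_id")) {
    v <- g[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      slaml_stop(sprintf("genotype column '%s' is not 0/1/NA", col),
                 "slaml_schema_error")
    }
  }
  g
}

#' Run the canonical simulate -> classify -> associate -> survive pipeline
#'
#' Executes the enabled stages in order and returns a report bundle whose
#' percentages are all reproducible from its count tables. Identical config
#' and seed give an identical bundle.
#'
#' @param config [run_config()].
#' @return list of class `report_bundle`: `frequency` (SLA frequency
#'   table), `labels`, `summary` (per-SLA clinical summary), `volcano`
#'   (association results, if enabled), `skipped_lesions`, `survival`
#'   (per-SLA OS Kaplan-Meier step tables + log-rank), `cir` (cumulative
#'   incidence steps + Fine-Gray comparison), `saml`, `pca`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    profiles <- cohort$profiles
    genotypes <- cohort$genotypes
    outcomes <- cohort$outcomes
  } else {
    profiles <- read.csv(config$inputs$profiles, check.names = FALSE)
    genotypes <- if (!is.null(config$inputs$genotypes))
      read_genotypes(config$inputs$genotypes) else NULL
    outcomes <- if (!is.null(config$inputs$outcomes))
      read.csv(config$inputs$outcomes, check.names = FALSE) else NULL
  }

  cls <- classify_cohort(profiles, config$classifier)
  labels <- cls$labels$label
  bundle <- list(frequency = cls$frequency, labels = cls$labels,
                 summary = summarize_cohort(cbind(profiles, sla = labels)))

  if ("pca" %in% config$analyses) {
    mm <- intersect(core_markers(), names(normalize_profile_names(profiles)))
    bundle$pca <- project_pca(normalize_profile_names(profiles)[mm])
  }
  if ("association" %in% config$analyses && !is.null(genotypes)) {
    scr <- association_screen(labels, genotypes)
    bundle$volcano <- scr$results
    bundle$skipped_lesions <- scr$skipped
    bundle$modules <- functional_module_tally(labels, genotypes)$screen$results
  }
  if ("saml" %in% config$analyses && !is.null(genotypes) &&
      all(c("history_mds", "history_mpn", "karyotype_mrc") %in% names(genotypes))) {
    bundle$saml <- classify_secondary_aml(genotypes)
  }
  if ("survival" %in% config$analyses && !is.null(outcomes)) {
    os_by <- lapply(split(outcomes, labels), function(d) {
      km_estimate(d$os_months, d$os_event)$steps
    })
    lr <- logrank_test(outcomes$os_months, outcomes$os_event, labels)
    crd <- outcomes[!is.na(outcomes$event_type), ]
    cir <- cumulative_incidence(crd$relapse_months, crd$event_type)
    bundle$survival <- list(os_steps = os_by, logrank = lr)
    bundle$cir <- list(steps = cir$steps,
                       test = tryCatch(
                         compare_cir(crd$relapse_months, crd$event_type,
                                     labels[!is.na(outcomes$event_type)]),
                         error = function(e) NULL))
  }

  bundle$manifest <- run_manifest(config)
  class(bundle) <- "report_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# manifest: everything needed to re-run bit-identically
run_manifest <- function(config) {
  cfg_json <- jsonlite::toJSON(serialize_config(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(seed = config$seed,
       package_version = as.character(utils::packageVersion("slaml")),
       config = as.character(cfg_json),
       config_md5 = hash)
}

serialize_config <- function(config) {
  sim <- config$simulate
  list(
    seed = config$seed,
    analyses = config$analyses,
    classifier = unclass(config$classifier),
    inputs = config$inputs,
    simulate = if (is.null(sim)) NULL else list(
      n_patients = sim$n_patients,
      sla_proportions = as.list(sim$sla_proportions),
      jitter_sd = sim$jitter_sd,
      events_per_specimen = sim$events_per_specimen,
      seed = sim$seed,
      mutation_prevalence = sim$mutation_prevalence,
      outcome_model = sim$outcome_model)
  )
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$frequency, file.path(dir, "sla_frequency.csv"), row.names = FALSE)
  write.csv(bundle$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  write.csv(bundle$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  if (!is.null(bundle$volcano))
    write.csv(bundle$volcano, file.path(dir, "volcano.csv"), row.names = FALSE)
  if (!is.null(bundle$cir))
    write.csv(bundle$cir$steps, file.path(dir, "cir_steps.csv"), row.names = FALSE)
  if (!is.null(bundle$saml))
    write.csv(bundle$saml, file.path(dir, "saml.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Per-SLA clinical summary table
#'
#' Medians and interquartile ranges (type-7 linear-interpolation quantiles)
#' for numeric fields, counts and one-decimal percentages for the group
#' sizes. Denominators are per-field non-missing counts, matching the
#' mutated/tested convention of the source tables; missing fields yield
#' explicit NA cells.
#'
#' @param records data.frame with an `sla` column plus numeric fields.
#' @param fields numeric columns to summarize (default: all numeric).
#' @return data.frame, one row per SLA plus an `All` row: n, percent, and
#'   per-field `<f>_median`, `<f>_q1`, `<f>_q3`, `<f>_n`.
#' @export
summarize_cohort <- function(records, fields = NULL) {
  if (NROW(records) < 1) slaml_stop("no records", "slaml_argument_error")
  if (!"sla" %in% names(records)) {
    slaml_stop("records need an `sla` column", "slaml_argument_error")
  }
  if (is.null(fields)) {
    fields <- names(records)[vapply(records, is.numeric, logical(1))]
    fields <- setdiff(fields, c("n_blasts"))
  }
  groups <- c(list(All = records), split(records, factor(records$sla, sla_levels())))
  n_all <- nrow(records)
  rows <- lapply(names(groups), function(gn) {
    d <- groups[[gn]]
    row <- data.frame(sla = gn, n = nrow(d),
                      percent = percent_of(max(nrow(d), 0), n_all, 1),
                      stringsAsFactors = FALSE)
    for (f in fields) {
      v <- d[[f]]
      v <- v[!is.na(v)]
      if (length(v)) {
        q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        row[[paste0(f, "_median")]] <- round_half_up(q[2], 1)
        row[[paste0(f, "_q1")]] <- round_half_up(q[1], 1)
        row[[paste0(f, "_q3")]] <- round_half_up(q[3], 1)
      } else {
        row[[paste0(f, "_median")]] <- NA_real_
        row[[paste0(f, "_q1")]] <- NA_real_
        row[[paste0(f, "_q3")]] <- NA_real_
      }
      row[[paste0(f, "_n")]] <- length(v)
    }
    row
  })
  do.call(rbind, rows)
}
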