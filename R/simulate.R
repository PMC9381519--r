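#' Simulate an event-level specimen for one SLA archetype
#'
#' Draws `n_events` cytometry events. A configurable majority of events are
#' CD45-dim blasts; the remainder are CD45-bright lymphocyte-like events
#' (markers drawn from the negative component) so that blast gating is
#' non-trivial. For each marker a blast event comes from the positive
#' log-normal component with probability `positive_fraction[marker]`. A
#' fraction `lsc_fraction` of blasts is forced to the CD34+CD38-CD123+
#' phenotype; the remaining blasts have their CD34/CD38 component
#' probabilities adjusted so the configured marginals are preserved.
#'
#' @param archetype [sla_archetype()].
#' @param n_events number of events (>= 0).
#' @param seed integer seed; identical seed, identical output.
#' @param lymphocyte_fraction proportion of CD45-bright contaminating
#'   events (default 0.1).
#' @param specimen_id identifier stored on the result.
#' @return [event_matrix()] with channels CH1..CHk mapped to
#'   CD45, SSC and the archetype's markers.
#' @export
simulate_events <- function(archetype, n_events, seed = 1,
                            lymphocyte_fraction = 0.1,
                            specimen_id = NULL) {
  if (!inherits(archetype, "sla_archetype")) {
    slaml_stop("simulate_events() expects an sla_archetype", "slaml_argument_error")
  }
  if (!is.numeric(n_events) || length(n_events) != 1 || is.na(n_events) ||
      n_events < 0 || n_events != floor(n_events)) {
    slaml_stop("n_events must be a non-negative integer", "slaml_argument_error")
  }
  stopifnot(is_prob(lymphocyte_fraction))
  if (is.null(specimen_id)) {
    specimen_id <- paste0("sim-", archetype$label, "-", seed)
  }

  markers <- setdiff(names(archetype$positive_fraction), "CD45")
  channels <- c("CD45", "SSC", markers)
  chan_ids <- paste0("CH", seq_along(channels))
  map <- setNames(channels, chan_ids)
  mat <- matrix(0, nrow = n_events, ncol = length(channels),
                dimnames = list(NULL, chan_ids))
  if (n_events == 0) {
    return(event_matrix(mat, map, specimen_id))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  im <- archetype$intensity
  rcomp <- function(n, pos) {
    comp <- if (pos) im$pos else im$neg
    rlnorm(n, comp$meanlog, comp$sdlog)
  }
  is_blast <- runif(n_events) >= lymphocyte_fraction
  nb <- sum(is_blast)

  # CD45: dim blasts, bright lymphocytes; SSC low/intermediate throughout
  cd45 <- numeric(n_events)
  cd45[is_blast] <- rlnorm(nb, log(150), 0.3)
  cd45[!is_blast] <- rlnorm(n_events - nb, log(2000), 0.25)
  ssc <- numeric(n_events)
  ssc[is_blast] <- rlnorm(nb, log(300), 0.35)
  ssc[!is_blast] <- rlnorm(n_events - nb, log(150), 0.3)
  mat[, 1] <- cd45
  mat[, 2] <- ssc

  pf <- archetype$positive_fraction
  lsc <- archetype$lsc_fraction
  is_lsc <- logical(n_events)
  if (lsc > 0 && nb > 0) {
    is_lsc[is_blast] <- runif(nb) < lsc
  }
  # marginal-preserving conditional probabilities for non-LSC blasts
  p_non <- function(marker, forced_on_lsc) {
    p <- pf[[marker]]
    if (lsc >= 1) return(if (forced_on_lsc) 1 else 0)
    if (forced_on_lsc) max(0, min(1, (p - lsc) / (1 - lsc)))
    else min(1, p / (1 - lsc))
  }
  for (j in seq_along(markers)) {
    m <- markers[j]
    pos <- logical(n_events)
    blasts <- which(is_blast)
    if (m == "CD34") {
      pos[blasts] <- ifelse(is_lsc[blasts], TRUE,
                            runif(length(blasts)) < p_non("CD34", TRUE))
    } else if (m == "CD123") {
      pos[blasts] <- ifelse(is_lsc[blasts], TRUE,
                            runif(length(blasts)) < p_non("CD123", TRUE))
    } else if (m == "CD38") {
      pos[blasts] <- ifelse(is_lsc[blasts], FALSE,
                            runif(length(blasts)) < p_non("CD38", FALSE))
    } else {
      pos[blasts] <- runif(length(blasts)) < pf[[m]]
    }
    # lymphocyte-like events stay in the negative component
    mat[, j + 2] <- ifelse(pos, rcomp(n_events, TRUE), rcomp(n_events, FALSE))
  }
  event_matrix(mat, map, specimen_id)
}

# save/restore the global RNG state so simulate_* are pure in `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cohort simulation configuration
#'
#' The stated cohort world: SLA mixture proportions (defaults are the
#' 2087-patient discovery-cohort frequencies 0.9 / 21.9 / 30.2 / 17.2 /
#' 5.7 / 24.1 percent for HSC-L...MP-L in [sla_levels()] order),
#' SLA-conditional lesion prevalences (defaults estimated from the printed
#' mutated/tested counts, see [default_mutation_prevalence()]), per-SLA
#' complete-remission probabilities and exponential outcome hazards
#' (see [default_outcome_model()]).
#'
#' @param n_patients positive integer.
#' @param sla_proportions named 6-vector over [sla_levels()], summing to 1
#'   within 1e-9.
#' @param mutation_prevalence data.frame with columns `gene` plus one column
#'   per SLA giving P(lesion | SLA) in \[0, 1\].
#' @param outcome_model per-SLA data.frame, see [default_outcome_model()].
#' @param jitter_sd logit-scale standard deviation of the marker-profile
#'   jitter around the archetype (0 = exact archetype percentages).
#' @param events_per_specimen events per simulated specimen when event-level
#'   output is requested (0 = marker profiles only).
#' @param archetypes named list of [sla_archetype()]s.
#' @param seed single integer; all draws flow from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2087,
                          sla_proportions = default_sla_proportions(),
                          mutation_prevalence = default_mutation_prevalence(),
                          outcome_model = default_outcome_model(),
                          jitter_sd = 0.3,
                          events_per_specimen = 0,
                          archetypes = default_archetypes(),
                          seed = 1) {
  stopifnot(is.numeric(n_patients), n_patients >= 1)
  p <- sla_proportions
  if (!setequal(names(p), sla_levels())) {
    slaml_stop("sla_proportions must be named by the six SLA levels",
               "slaml_config_error")
  }
  p <- p[sla_levels()]
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
    slaml_stop("sla_proportions must be non-negative and sum to 1 (1e-9)",
               "slaml_config_error")
  }
  missing_sla <- setdiff(sla_levels(), names(mutation_prevalence))
  if (length(missing_sla)) {
    slaml_stop(paste("mutation_prevalence missing SLA columns:",
                     paste(missing_sla, collapse = ", ")), "slaml_config_error")
  }
  if (!is_prob(as.matrix(mutation_prevalence[sla_levels()]))) {
    slaml_stop("mutation prevalences must lie in [0, 1]", "slaml_config_error")
  }
  om <- outcome_model
  need <- c("sla", "cr_prob", "os_hazard", "relapse_hazard",
            "death_in_cr_hazard", "censor_max")
  if (!all(need %in% names(om))) {
    slaml_stop("outcome_model must carry cr_prob and per-SLA hazards",
               "slaml_config_error")
  }
  if (any(om$os_hazard < 0) || any(om$relapse_hazard < 0) ||
      any(om$death_in_cr_hazard < 0)) {
    slaml_stop("hazards must be non-negative", "slaml_config_error")
  }
  if (!is_prob(om$cr_prob)) {
    slaml_stop("cr_prob must lie in [0, 1]", "slaml_config_error")
  }
  structure(list(n_patients = as.integer(n_patients),
                 sla_proportions = p,
                 mutation_prevalence = mutation_prevalence,
                 outcome_model = om,
                 jitter_sd = jitter_sd,
                 events_per_specimen = as.integer(events_per_specimen),
                 archetypes = archetypes,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Discovery-cohort SLA mixture proportions
#' @return named numeric 6-vector summing to 1.
#' @export
default_sla_proportions <- function() {
  counts <- c("HSC-L" = 18, "MPP-L" = 458, "CMP-L" = 630,
              "GMP-L" = 360, "GP-L" = 119, "MP-L" = 502)
  counts / sum(counts)
}

#' SLA-conditional lesion prevalences from the printed mutated/tested counts
#'
#' Point estimates P(lesion | SLA) = mutated / tested for the seven
#' mutation rows of the discovery-cohort characteristics table, shipped in
#' `inst/extdata/discovery_mutations.csv`.
#'
#' @return data.frame: `gene` plus one probability column per SLA.
#' @export
default_mutation_prevalence <- function() {
  path <- system.file("extdata", "discovery_mutations.csv", package = "slaml")
  raw <- read.csv(path, check.names = FALSE)
  genes <- unique(raw$gene)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in sla_levels()) {
    rows <- raw[raw$sla == s, ]
    out[[s]] <- rows$mutated[match(genes, rows$gene)] /
      rows$tested[match(genes, rows$gene)]
  }
  out
}

#' Default per-SLA outcome model
#'
#' Exponential hazards per month with independent uniform censoring.
#' Complete-remission probabilities are the printed per-SLA CR rates
#' (HSC/MPP-L 72%, CMP-L 76%, GMP-L 87%, GP-L 79%, MP-L 85%). The OS and
#' relapse hazards are chosen once so survival orders immature-worse
#' (median OS ~14-15 months in HSC/MPP-L, ~20 CMP-L, ~58 GMP-L, ~35-39 in
#' the mature stages); the source data print no parametric rates.
#'
#' @return data.frame with columns sla, cr_prob, os_hazard, relapse_hazard,
#'   death_in_cr_hazard, censor_max (months).
#' @export
default_outcome_model <- function() {
  data.frame(
    sla = sla_levels(),
    cr_prob = c(0.72, 0.72, 0.76, 0.87, 0.79, 0.85),
    os_hazard = c(0.050, 0.045, 0.035, 0.012, 0.018, 0.020),
    relapse_hazard = c(0.060, 0.055, 0.045, 0.015, 0.022, 0.025),
    death_in_cr_hazard = 0.010,
    censor_max = 120,
    stringsAsFactors = FALSE
  )
}

# logit-normal jitter of a percentage around its archetype value
jitter_percent <- function(p, sd, n) {
  if (sd == 0) return(rep(100 * p, n))
  p <- min(max(p, 1e-6), 1 - 1e-6)
  100 * plogis(rnorm(n, qlogis(p), sd))
}

#' Simulate a full patient cohort
#'
#' Each patient receives a true SLA drawn from the mixture, a marker profile
#' jittered (logit-normal) around the SLA archetype, independent lesion
#' flags per P(lesion | SLA), a complete-remission indicator, and outcome
#' times from the per-SLA exponential competing-risks model with independent
#' uniform censoring. The true SLA is returned alongside for recovery tests.
#'
#' @param config [cohort_config()].
#' @return list of class `sla_cohort` with elements
#'   `profiles` (marker-profile data.frame incl. `true_sla`),
#'   `genotypes` (0/1 flags, NA = untested),
#'   `outcomes` (os/dfs/relapse times, indicators, cr flag, event_type),
#'   `events` (list of [event_matrix()] or NULL), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    slaml_stop("simulate_cohort() expects a cohort_config", "slaml_config_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  sla <- sample(sla_levels(), n, replace = TRUE, prob = config$sla_proportions)

  # marker profiles around the archetypes
  prof <- data.frame(patient_id = ids, true_sla = sla, stringsAsFactors = FALSE)
  for (m in core_markers()) prof[[m]] <- NA_real_
  for (s in sla_levels()) {
    idx <- which(sla == s)
    if (!length(idx)) next
    arc <- config$archetypes[[s]]
    for (m in core_markers()) {
      prof[[m]][idx] <- jitter_percent(arc$positive_fraction[[m]],
                                       config$jitter_sd, length(idx))
    }
  }

  # genotype flags, independent across lesions given SLA
  prev <- config$mutation_prevalence
  geno <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(prev))) {
    g <- prev$gene[k]
    p <- vapply(sla, function(s) prev[[s]][k], numeric(1))
    geno[[g]] <- as.integer(runif(n) < p)
  }

  # outcomes: exponential per (SLA, event type), uniform censoring
  om <- config$outcome_model
  row <- match(sla, om$sla)
  cr <- as.integer(runif(n) < om$cr_prob[row])
  t_death <- rexp(n, rate = pmax(om$os_hazard[row], 1e-12))
  cens_os <- runif(n, 0, om$censor_max[row])
  os_time <- pmin(t_death, cens_os)
  os_event <- as.integer(t_death <= cens_os)

  t_rel <- rexp(n, rate = pmax(om$relapse_hazard[row], 1e-12))
  t_dcr <- rexp(n, rate = pmax(om$death_in_cr_hazard[row], 1e-12))
  cens_cr <- runif(n, 0, om$censor_max[row])
  first <- pmin(t_rel, t_dcr, cens_cr)
  event_type <- rep(NA_character_, n)
  dfs_time <- rep(NA_real_, n)
  dfs_event <- rep(NA_integer_, n)
  relapse_time <- rep(NA_real_, n)
  relapse_event <- rep(NA_integer_, n)
  in_cr <- cr == 1
  event_type[in_cr] <- ifelse(t_rel[in_cr] <= first[in_cr], "relapse",
                       ifelse(t_dcr[in_cr] <= first[in_cr], "death", "censored"))
  dfs_time[in_cr] <- first[in_cr]
  dfs_event[in_cr] <- as.integer(event_type[in_cr] != "censored")
  relapse_time[in_cr] <- first[in_cr]
  relapse_event[in_cr] <- as.integer(event_type[in_cr] == "relapse")

  outcomes <- data.frame(
    patient_id = ids, true_sla = sla, cr = cr,
    os_months = os_time, os_event = os_event,
    dfs_months = dfs_time, dfs_event = dfs_event,
    relapse_months = relapse_time, relapse_event = relapse_event,
    death_prior_relapse = as.integer(in_cr & event_type == "death"),
    event_type = event_type,
    treatment = "intensive",
    stringsAsFactors = FALSE
  )

  events <- NULL
  if (config$events_per_specimen > 0) {
    events <- lapply(seq_len(n), function(i) {
      simulate_events(config$archetypes[[sla[i]]],
                      config$events_per_specimen,
                      seed = config$seed + i,
                      specimen_id = ids[i])
    })
    names(events) <- ids
  }

  structure(list(profiles = prof, genotypes = geno, outcomes = outcomes,
                 events = events, config = config),
            class = "sla_cohort")
}

#' @export
print.sla_cohort <- function(x, ...) {
  cat(sprintf("<sla_cohort> %d patients, %d lesions, seed %d\n",
              nrow(x$profiles), ncol(x$genotypes) - 1L, x$config$seed))
  print(table(factor(x$profiles$true_sla, levels = sla_levels())))
  invisible(x)
}

#' Write a simulated cohort as CSV tables
#'
#' Emits `profiles.csv`, `genotypes.csv`, `outcomes.csv` (and per-patient
#' `events/<id>.csv` when event-level data were simulated) under `dir`.
#'
#' @param cohort [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$profiles, file.path(dir, "profiles.csv"), row.names = FALSE)
  write.csv(cohort$genotypes, file.path(dir, "genotypes.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  if (!is.null(cohort$events)) {
    evdir <- file.path(dir, "events")
    dir.create(evdir, showWarnings = FALSE)
    for (id in names(cohort$events)) {
      write_event_csv(cohort$events[[id]], file.path(evdir, paste0(id, ".csv")))
    }
  }
  invisible(dir)
}
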