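#' 2x2 contingency table for a one-vs-rest lesion screen
#'
#' Counts restricted to patients tested for the lesion: `a` lesion-positive
#' within the SLA of interest, `b` lesion-negative within it, `c`
#' lesion-positive outside it, `d` lesion-negative outside it.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    slaml_stop("contingency cells must be non-negative integers",
               "slaml_argument_error")
  }
  structure(as.list(counts), class = "contingency_2x2")
}

#' One-vs-rest relative risk
#'
#' RR = (a/(a+b)) / (c/(c+d)): lesion prevalence inside the SLA over
#' prevalence outside it. When any cell is zero the Haldane-Anscombe +0.5
#' correction is applied to all four cells and flagged, so the RR stays
#' finite rather than 0/Inf.
#'
#' @param t [contingency_2x2()].
#' @return list: `rr` (> 0), `corrected` flag.
#' @export
relative_risk <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  if (a + b == 0 || c + d == 0) {
    slaml_stop("relative risk undefined: empty row margin", "slaml_undefined_rr_error")
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(rr = (a / (a + b)) / (c / (c + d)), corrected = corrected)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table whose point probability does not exceed that of the observed
#' table (point-probability two-sided rule, the convention of
#' `stats::fisher.test`). A table with a zero margin admits a single
#' attainable configuration and returns p = 1.
#'
#' @param t [contingency_2x2()].
#' @return two-sided p-value in \[0, 1\].
#' @export
fisher_exact_2x2 <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  m <- a + c          # column-1 margin (lesion positive)
  n <- b + d
  k <- a + b          # row-1 margin (inside SLA)
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  # tolerance guards against ties broken by floating-point noise
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' One-vs-rest genotype association screen
#'
#' For every (SLA, lesion) pair, builds the 2x2 table over tested patients
#' (lesion flag 0/1, NA = untested), computes the relative risk (with
#' zero-cell correction) and the two-sided Fisher exact p, and emits a
#' volcano-ready table. Raw p-values are reported by default to match the
#' original screens; Benjamini-Hochberg adjustment is available behind
#' `adjust`.
#'
#' @param sla_labels character vector of per-patient SLA labels.
#' @param genotypes data.frame of 0/1/NA lesion columns (a `patient_id`
#'   column is ignored); lesions listed in `lesions` but absent from the
#'   table, or never tested, are reported in `skipped`, not fatal.
#' @param lesions lesion columns to screen (default: all).
#' @param adjust add a `p_adj` Benjamini-Hochberg column (default FALSE).
#' @return list of class `association_screen`: `results` data.frame (sla,
#'   lesion, a, b, c, d, rr, corrected, p, log2_rr, neglog10_p), `skipped`
#'   character vector.
#' @export
association_screen <- function(sla_labels, genotypes, lesions = NULL,
                               adjust = FALSE) {
  geno <- genotypes[setdiff(names(genotypes), "patient_id")]
  if (is.null(lesions)) lesions <- names(geno)
  if (length(sla_labels) != nrow(geno)) {
    slaml_stop("sla_labels and genotypes must align row-wise", "slaml_argument_error")
  }
  skipped <- character(0)
  rows <- list()
  for (g in lesions) {
    if (!g %in% names(geno) || all(is.na(geno[[g]]))) {
      skipped <- c(skipped, g)
      next
    }
    flag <- geno[[g]]
    tested <- !is.na(flag)
    for (s in sla_levels()) {
      inside <- sla_labels == s
      a <- sum(flag[tested & inside] == 1)
      b <- sum(flag[tested & inside] == 0)
      c <- sum(flag[tested & !inside] == 1)
      d <- sum(flag[tested & !inside] == 0)
      if (a + b == 0 || c + d == 0) next  # SLA absent among tested patients
      tab <- contingency_2x2(a, b, c, d)
      rr <- relative_risk(tab)
      p <- fisher_exact_2x2(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        sla = s, lesion = g, a = a, b = b, c = c, d = d,
        rr = rr$rr, corrected = rr$corrected, p = p,
        log2_rr = log2(rr$rr), neglog10_p = -log10(max(p, .Machine$double.xmin)),
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sla = character(0), lesion = character(0))
  if (adjust && nrow(results)) results$p_adj <- stats::p.adjust(results$p, "BH")
  structure(list(results = results, skipped = skipped),
            class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  cat(sprintf("<association_screen> %d (SLA, lesion) tests, %d skipped lesions\n",
              nrow(x$results), length(x$skipped)))
  print(head(x$results, 12))
  invisible(x)
}
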