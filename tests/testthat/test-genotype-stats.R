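test_that("relative_risk matches direct arithmetic and the +0.5 rule", {
  # printed mutated/tested row: 269/421 inside vs 158/1000 outside
  rr <- relative_risk(contingency_2x2(269, 152, 158, 842))
  expect_equal(rr$rr, (269 / 421) / (158 / 1000), tolerance = 1e-12)
  expect_equal(round_half_up(rr$rr, 2), 4.04)
  expect_false(rr$corrected)

  expect_equal(relative_risk(contingency_2x2(10, 90, 10, 90))$rr, 1.0)

  cor <- relative_risk(contingency_2x2(5, 5, 0, 10))
  expect_true(cor$corrected)
  expect_equal(cor$rr, (5.5 / 11) / (0.5 / 11), tolerance = 1e-12)  # = 11

  expect_error(relative_risk(contingency_2x2(0, 0, 3, 4)),
               class = "slaml_undefined_rr_error")
  expect_error(contingency_2x2(-1, 2, 3, 4), class = "slaml_argument_error")
})

test_that("relative_risk is invariant to scaling all cells (pre-correction)", {
  for (k in c(2, 5, 10)) {
    base <- relative_risk(contingency_2x2(3, 7, 4, 16))$rr
    expect_equal(relative_risk(contingency_2x2(3 * k, 7 * k, 4 * k, 16 * k))$rr,
                 base, tolerance = 1e-12)
  }
})

test_that("fisher_exact_2x2 matches enumeration on the worked examples", {
  expect_equal(fisher_exact_2x2(contingency_2x2(5, 0, 0, 5)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(contingency_2x2(2, 3, 3, 2)), 1.0)
  expect_equal(fisher_exact_2x2(contingency_2x2(0, 0, 3, 4)), 1)
  expect_equal(fisher_exact_2x2(contingency_2x2(0, 4, 0, 6)), 1)
})

test_that("fisher_exact_2x2 agrees with stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:60) {
    cells <- rpois(4, 6)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_2x2(t), ref, tolerance = 1e-9)
  }
})

test_that("association_screen recovers an enriched lesion and the null", {
  lev <- sla_levels()
  set.seed(77)
  n <- 2000
  sla <- sample(lev, n, replace = TRUE,
                prob = unname(default_sla_proportions()[lev]))
  # one lesion at prevalence 0.8 in GP-L, 0.1 elsewhere
  p <- ifelse(sla == "GP-L", 0.8, 0.1)
  geno <- data.frame(LES = as.integer(runif(n) < p),
                     NULLG = as.integer(runif(n) < 0.3))
  scr <- association_screen(sla, geno)
  les <- scr$results[scr$results$lesion == "LES", ]
  expect_gt(les$rr[les$sla == "GP-L"], 1)
  expect_lt(les$p[les$sla == "GP-L"], 1e-6)
  expect_true(all(les$rr[les$sla != "GP-L"] < 1))
  nullg <- scr$results[scr$results$lesion == "NULLG", ]
  expect_true(all(abs(log2(nullg$rr)) < 1))
  expect_gt(min(nullg$p), 0.001)
})

test_that("untested lesions are skipped, not fatal; positives partition", {
  co <- simulate_cohort(fixture_config(n = 500, seed = 55))
  geno <- co$genotypes
  geno$GHOST <- NA_integer_
  scr <- association_screen(co$profiles$true_sla, geno,
                            lesions = c(names(geno)[-1], "ABSENT"))
  expect_setequal(scr$skipped, c("GHOST", "ABSENT"))
  # partition conservation: sum of within-SLA positives = total positives
  for (g in c("NPM1", "FLT3-ITD")) {
    rows <- scr$results[scr$results$lesion == g, ]
    expect_equal(sum(rows$a), sum(geno[[g]], na.rm = TRUE))
    # and a+c is constant = total positives among tested
    expect_true(all(rows$a + rows$c == sum(geno[[g]], na.rm = TRUE)))
  }
})

test_that("uniform prevalence gives RR = 1 exactly for all SLA", {
  # deterministic construction: equal prevalence in every SLA
  sla <- rep(sla_levels(), each = 20)
  flag <- rep(c(1, 1, 0, 0, 0), times = 24)  # 40% everywhere
  scr <- association_screen(sla, data.frame(L = flag))
  expect_true(all(abs(scr$results$rr - 1) < 1e-12))
})

test_that("Benjamini-Hochberg adjustment is available behind a flag", {
  co <- simulate_cohort(fixture_config(n = 300, seed = 5))
  scr <- association_screen(co$profiles$true_sla, co$genotypes, adjust = TRUE)
  expect_true("p_adj" %in% names(scr$results))
  expect_true(all(scr$results$p_adj >= scr$results$p - 1e-12))
})

test_that("classify_secondary_aml combines the three criteria", {
  rec <- data.frame(
    patient_id = c("post_mds", "srsf2", "denovo", "kary", "unknown"),
    history_mds = c(1, 0, 0, 0, NA),
    history_mpn = c(0, 0, 0, 0, NA),
    karyotype_mrc = c(0, 0, 0, 1, 0),
    SRSF2 = c(0, 1, 0, 0, 0),
    ASXL1 = c(0, 0, 0, 0, 0)
  )
  lab <- classify_secondary_aml(rec)
  expect_true(lab$clinical[1]); expect_false(lab$molecular[1]); expect_true(lab$saml[1])
  expect_true(lab$molecular[2]); expect_false(lab$clinical[2]); expect_true(lab$saml[2])
  expect_false(any(unlist(lab[3, c("clinical", "molecular", "karyotypic", "saml")])))
  expect_true(lab$karyotypic[4]); expect_true(lab$saml[4])
  # missing history: explicit unknown, never silent FALSE
  expect_true(is.na(lab$clinical[5]))
  expect_true(is.na(lab$saml[5]))
  # overall flag is true iff any component true (on defined rows)
  defined <- complete.cases(lab[c("clinical", "molecular", "karyotypic")])
  expect_identical(lab$saml[defined],
                   lab$clinical[defined] | lab$molecular[defined] | lab$karyotypic[defined])

  expect_error(classify_secondary_aml(rec[setdiff(names(rec), "history_mds")]),
               class = "slaml_argument_error")
})

test_that("functional_module_tally counts patients once per module", {
  geno <- data.frame(RUNX1 = c(1, 0, 0), ETV6 = c(1, 0, 0), SRSF2 = c(0, 0, 1),
                     NOVEL = c(0, 1, 0))
  sla <- c("MPP-L", "CMP-L", "GP-L")
  tal <- functional_module_tally(sla, geno)
  expect_equal(tal$indicators$transcription_factor, c(1L, 0L, 0L))
  expect_equal(tal$indicators$spliceosome, c(0L, 0L, 1L))
  expect_identical(tal$unmapped, "NOVEL")
  # patient 2 has no mapped mutations: contributes to no numerator
  expect_true(all(unlist(tal$indicators[2, ]) == 0))
})

test_that("a module enriched by construction screens RR > 1", {
  lev <- sla_levels()
  set.seed(9)
  n <- 2000
  sla <- sample(lev, n, replace = TRUE, prob = unname(default_sla_proportions()[lev]))
  p <- ifelse(sla == "MPP-L", 0.45, 0.15)  # spliceosome prevalence ratio 3
  geno <- data.frame(SRSF2 = as.integer(runif(n) < p),
                     SF3B1 = as.integer(runif(n) < 0.02))
  tal <- functional_module_tally(sla, geno)
  row <- tal$screen$results
  row <- row[row$lesion == "spliceosome" & row$sla == "MPP-L", ]
  expect_gt(row$rr, 1)
  expect_lt(row$p, 0.001)
})
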