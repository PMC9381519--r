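#' Default MDS-pattern gene set for molecular secondary AML
#'
#' The eight genes whose mutation marks an MDS-like molecular background:
#' SRSF2, SF3B1, U2AF1, ZRSR2, ASXL1, EZH2, BCOR, STAG2. Shipped as the
#' editable resource `inst/extdata/mds_genes.csv`.
#'
#' @return character vector of gene symbols.
#' @export
mds_gene_set <- function() {
  read.csv(system.file("extdata", "mds_genes.csv", package = "slaml"))$gene
}

#' Label secondary AML from clinical, molecular and karyotypic criteria
#'
#' A patient is secondary AML (s-AML) if any of: clinical (history of MDS
#' or MPN), molecular (mutation in any gene of the MDS-pattern set), or
#' karyotypic (precomputed MRC-defining karyotype flag). Missing history or
#' karyotype fields yield an explicit NA state, never a silent FALSE; the
#' overall flag is the three-way OR under NA propagation (TRUE wins over
#' NA).
#'
#' @param records data.frame with logical/0-1 columns `history_mds`,
#'   `history_mpn`, `karyotype_mrc`, plus 0/1/NA mutation flag columns.
#' @param genes molecular gene set (default [mds_gene_set()]); genes absent
#'   from `records` are ignored for the molecular flag.
#' @return data.frame: patient_id (if present), clinical, molecular,
#'   karyotypic, saml (logical, NA-propagating OR).
#' @export
classify_secondary_aml <- function(records, genes = mds_gene_set()) {
  need <- c("history_mds", "history_mpn", "karyotype_mrc")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    slaml_stop(paste("records missing fields:", paste(miss, collapse = ", ")),
               "slaml_argument_error")
  }
  as_flag <- function(x) {
    if (is.logical(x)) x else as.logical(as.integer(x))
  }
  clinical <- as_flag(records$history_mds) | as_flag(records$history_mpn)
  present <- intersect(genes, names(records))
  if (length(present)) {
    mut <- as.matrix(records[present])
    mode(mut) <- "numeric"
    # any mutated gene => TRUE even if others untested; all-NA => NA
    molecular <- apply(mut, 1, function(r) {
      if (any(r == 1, na.rm = TRUE)) TRUE
      else if (all(is.na(r))) NA
      else FALSE
    })
  } else {
    molecular <- rep(NA, nrow(records))
  }
  karyotypic <- as_flag(records$karyotype_mrc)
  saml <- clinical | molecular | karyotypic  # R's 3-valued OR: TRUE beats NA
  out <- data.frame(clinical = clinical, molecular = molecular,
                    karyotypic = karyotypic, saml = saml)
  if ("patient_id" %in% names(records)) {
    out <- cbind(patient_id = records$patient_id, out)
  }
  out
}

#' Default gene-to-functional-module map
#'
#' Assigns each gene of the 46-gene myeloid panel to one of eight functional
#' categories (NPM1, DNA methylation, chromatin, spliceosome, cohesin,
#' myeloid transcription factors, signaling, tumor suppressors). Shipped as
#' the editable resource `inst/extdata/gene_modules.csv`.
#'
#' @return data.frame: gene, module.
#' @export
default_module_map <- function() {
  read.csv(system.file("extdata", "gene_modules.csv", package = "slaml"),
           stringsAsFactors = FALSE)
}

#' Tally functional mutation modules and screen them per SLA
#'
#' A patient counts for a module if any mutation in a gene mapped to it; a
#' patient counts as tested for a module if tested for at least one of its
#' genes. Module indicators are then screened with the one-vs-rest
#' [association_screen()] machinery. Mutated genes absent from the map are
#' returned in `unmapped`.
#'
#' @param sla_labels per-patient SLA labels.
#' @param genotypes data.frame of 0/1/NA gene columns.
#' @param module_map data.frame (gene, module), each gene in exactly one
#'   module; default [default_module_map()].
#' @return list of class `module_tally`: `indicators` (patients x modules,
#'   0/1/NA), `screen` ([association_screen()] result), `unmapped`.
#' @export
functional_module_tally <- function(sla_labels, genotypes,
                                    module_map = default_module_map()) {
  if (anyDuplicated(module_map$gene)) {
    slaml_stop("module_map must assign each gene to exactly one module",
               "slaml_argument_error")
  }
  genes <- setdiff(names(genotypes), "patient_id")
  unmapped <- setdiff(genes, module_map$gene)
  modules <- unique(module_map$module)
  ind <- data.frame(row.names = seq_along(sla_labels))
  for (mod in modules) {
    mg <- intersect(module_map$gene[module_map$module == mod], genes)
    if (!length(mg)) next
    sub <- as.matrix(genotypes[mg])
    mode(sub) <- "numeric"
    ind[[mod]] <- apply(sub, 1, function(r) {
      if (any(r == 1, na.rm = TRUE)) 1L
      else if (all(is.na(r))) NA_integer_
      else 0L
    })
  }
  structure(list(indicators = ind,
                 screen = association_screen(sla_labels, ind),
                 unmapped = unmapped),
            class = "module_tally")
}
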