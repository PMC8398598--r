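#' Default pathway gene sets for ultra-high-risk assessment
#'
#' Working stand-in gene sets for the RAS/MAPK and p53/MDM2 pathways;
#' user-overridable via `classify_risk(pathway_gene_sets = ...)` or a
#' two-column TSV (`pathway`, `gene`).
#'
#' @return named list of character vectors.
#' @export
default_pathway_gene_sets <- function() {
  list(
    RAS_MAPK = c("ALK", "NRAS", "KRAS", "HRAS", "BRAF", "RAF1", "NF1",
                 "PTPN11", "FGFR1"),
    p53_MDM2 = c("TP53", "MDM2", "PPM1D", "CDKN2A")
  )
}

#' Read pathway gene sets from a TSV
#'
#' @param path TSV with columns `pathway` and `gene`.
#' @return named list of character vectors.
#' @export
read_pathway_gene_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "gene") %in% names(tab)))
  lapply(split(tab$gene, tab$pathway), unique)
}

#' Assemble one sample's marker profile
#'
#' Collects a sample's caller outputs into the marker slots that drive
#' risk assessment: MYCN and chromosomal-region copy-number calls, TERT
#' rearrangements, ATRX events (SNV or deletion), and the full SNV
#' list.
#'
#' @param sample_id sample identifier.
#' @param cnv_calls data.frame from `call_cnvs()` (may be empty/NULL).
#' @param sv_calls data.frame from `call_svs()` or annotated
#'   breakpoints (may be empty/NULL).
#' @param snv_calls data.frame from `call_snvs()` after gene/hotspot
#'   annotation and germline flagging (may be empty/NULL).
#' @param atrx_events data.frame from `detect_partial_deletion()` for
#'   ATRX (may be NULL).
#' @param timepoint one of "primary_biopsy", "post_induction_surgery",
#'   "relapse".
#' @param material "fresh_frozen" or "FFPE".
#' @param purity tumor purity in (0, 1].
#' @return An `nb_tumor_profile`.
#' @export
tumor_profile <- function(sample_id, cnv_calls = NULL, sv_calls = NULL,
                          snv_calls = NULL, atrx_events = NULL,
                          timepoint = c("primary_biopsy",
                                        "post_induction_surgery", "relapse"),
                          material = c("fresh_frozen", "FFPE"),
                          purity = 1) {
  timepoint <- match.arg(timepoint)
  material <- match.arg(material)
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  structure(list(
    sample_id = sample_id, cnv_calls = cnv_calls, sv_calls = sv_calls,
    snv_calls = snv_calls, atrx_events = atrx_events,
    timepoint = timepoint, material = material, purity = purity
  ), class = "nb_tumor_profile")
}

cnv_call_for <- function(profile, region) {
  cc <- profile$cnv_calls
  if (is.null(cc) || nrow(cc) == 0) return(NULL)
  row <- cc[cc$region == region & cc$call, , drop = FALSE]
  if (nrow(row) == 0) NULL else row
}

#' Positive telomere-maintenance markers of a profile
#'
#' @param profile an `nb_tumor_profile`.
#' @return character vector drawn from `mycn_amplification`,
#'   `tert_rearrangement_upstream`, `tert_rearrangement_intragenic`,
#'   `atrx_alteration`.
#' @export
tmm_markers <- function(profile) {
  markers <- character(0)
  mycn <- cnv_call_for(profile, "MYCN")
  if (!is.null(mycn) && any(mycn$category == "amplification")) {
    markers <- c(markers, "mycn_amplification")
  }
  sv <- profile$sv_calls
  if (!is.null(sv) && nrow(sv) > 0 && "annotation" %in% names(sv)) {
    if (any(sv$annotation == "tert_upstream")) {
      markers <- c(markers, "tert_rearrangement_upstream")
    }
    if (any(sv$annotation == "tert_intragenic")) {
      markers <- c(markers, "tert_rearrangement_intragenic")
    }
  }
  atrx <- FALSE
  snv <- profile$snv_calls
  if (!is.null(snv) && nrow(snv) > 0 && "gene" %in% names(snv)) {
    atrx <- atrx || any(!is.na(snv$gene) & snv$gene == "ATRX")
  }
  atrx_cnv <- cnv_call_for(profile, "ATRX")
  if (!is.null(atrx_cnv)) {
    atrx <- atrx || any(atrx_cnv$category %in% c("loss", "deep_loss"))
  }
  if (!is.null(profile$atrx_events) && nrow(profile$atrx_events) > 0) {
    atrx <- atrx || any(profile$atrx_events$type == "partial_deletion")
  }
  if (atrx) markers <- c(markers, "atrx_alteration")
  markers
}

#' Telomere-maintenance status of a profile
#'
#' The recognized telomere-maintenance mechanisms (TMM) are MYCN
#' amplification, TERT rearrangement (upstream or intragenic breakpoint,
#' reported distinctly by `tmm_markers()`) and ATRX alteration (SNV,
#' whole-gene loss or partial deletion). One positive marker returns
#' that mechanism; two or more return `multiple`; none returns `none`.
#'
#' @param profile an `nb_tumor_profile`.
#' @return one of "mycn_amplification", "tert_rearrangement",
#'   "atrx_alteration", "multiple", "none".
#' @export
telomere_maintenance_status <- function(profile) {
  markers <- tmm_markers(profile)
  groups <- unique(ifelse(grepl("^tert_", markers), "tert_rearrangement", markers))
  if (length(groups) == 0) return("none")
  if (length(groups) > 1) return("multiple")
  groups
}

#' Classify a sample's neuroblastoma risk
#'
#' Truth table: a sample with an active telomere-maintenance mechanism
#' and at least one pathway hit (SNV or amplification of a RAS/MAPK- or
#' p53/MDM2-pathway gene) is `ultra_high_risk`; telomere maintenance
#' without a pathway hit is `high_risk_tmm`; no telomere maintenance is
#' `tmm_negative`, with an explicit caveat that alternative telomere
#' lengthening and telomerase expression are not assessed genomically,
#' so `tmm_negative` is not a low-risk assertion. Germline-flagged SNVs
#' are excluded from pathway counting by default.
#'
#' @param profile an `nb_tumor_profile`.
#' @param pathway_gene_sets named list of gene vectors (default
#'   `default_pathway_gene_sets()`).
#' @param include_germline count germline-flagged SNVs as pathway hits
#'   (default FALSE).
#' @return An `nb_risk_call`: list with `sample_id`,
#'   `telomere_maintenance`, `tmm_markers`, `pathway_hits` (names of
#'   pathways hit), `pathway_genes` (genes responsible), `risk_class`,
#'   `caveat`.
#' @export
classify_risk <- function(profile, pathway_gene_sets = default_pathway_gene_sets(),
                          include_germline = FALSE) {
  if (length(pathway_gene_sets) == 0) stop("pathway gene sets must not be empty")
  tmm <- telomere_maintenance_status(profile)

  hit_genes <- character(0)
  snv <- profile$snv_calls
  if (!is.null(snv) && nrow(snv) > 0 && "gene" %in% names(snv)) {
    keep <- !is.na(snv$gene)
    if (!include_germline && "possible_germline" %in% names(snv)) {
      keep <- keep & !snv$possible_germline
    }
    hit_genes <- c(hit_genes, snv$gene[keep])
  }
  cc <- profile$cnv_calls
  if (!is.null(cc) && nrow(cc) > 0) {
    amp <- cc[cc$call & cc$category == "amplification", , drop = FALSE]
    hit_genes <- c(hit_genes, amp$region)
  }
  pathway_hits <- names(pathway_gene_sets)[
    vapply(pathway_gene_sets, function(g) any(hit_genes %in% g), TRUE)]
  pathway_genes <- sort(unique(hit_genes[hit_genes %in% unlist(pathway_gene_sets)]))

  risk_class <- if (tmm != "none" && length(pathway_hits) > 0) {
    "ultra_high_risk"
  } else if (tmm != "none") {
    "high_risk_tmm"
  } else {
    "tmm_negative"
  }
  structure(list(
    sample_id = profile$sample_id,
    telomere_maintenance = tmm,
    tmm_markers = tmm_markers(profile),
    pathway_hits = pathway_hits,
    pathway_genes = pathway_genes,
    risk_class = risk_class,
    caveat = if (risk_class == "tmm_negative")
      "ALT and telomerase expression unassessed; tmm_negative is not a low-risk assertion"
    else NA_character_
  ), class = "nb_risk_call")
}

#' @export
print.nb_risk_call <- function(x, ...) {
  cat(sprintf("nb_risk_call [%s]: %s (TMM: %s; pathways: %s)\n",
              x$sample_id, x$risk_class, x$telomere_maintenance,
              if (length(x$pathway_hits)) paste(x$pathway_hits, collapse = "+") else "none"))
  invisible(x)
}

#' Aggregate subclonal FISH fractions
#'
#' FISH reports a deletion or gain per ratio class (e.g. 2:1 in 14% of
#' cells, 3:1 in 10%, 4:1 in 2%); the total fraction of aberrant cells
#' is the sum of the class fractions. Low totals explain why a
#' subclonal aberration seen by FISH can fall below the depth-ratio
#' detection limit of bulk sequencing.
#'
#' @param fractions numeric vector of per-ratio-class percentages, or a
#'   data.frame with a `percent` column.
#' @return total percent of aberrant cells.
#' @export
aggregate_fish_fraction <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- fractions$percent
  if (length(fractions) == 0) return(0)
  if (any(fractions < 0)) stop("FISH class fractions must be non-negative")
  total <- sum(fractions)
  if (total > 100) stop("FISH class fractions sum above 100%")
  total
}

#' Marker-level concordance between the panel and a reference method
#'
#' @param panel_calls data.frame(`sample_id`, `marker`, `call`
#'   logical) from the panel assay.
#' @param reference_calls same schema from the reference method (FISH,
#'   WES/WGS).
#' @return An `nb_concordance`: per-marker 2x2 counts
#'   (`both_positive`, `panel_only`, `reference_only`,
#'   `both_negative`) and a `discordant` data.frame listing each
#'   disagreeing sample with both values.
#' @export
concordance <- function(panel_calls, reference_calls) {
  key_p <- paste(panel_calls$sample_id, panel_calls$marker)
  key_r <- paste(reference_calls$sample_id, reference_calls$marker)
  missing <- c(setdiff(key_p, key_r), setdiff(key_r, key_p))
  if (length(missing)) {
    stop("sample/marker entries absent from one table: ",
         paste(missing, collapse = "; "))
  }
  m <- match(key_p, key_r)
  p <- panel_calls$call
  r <- reference_calls$call[m]
  per_marker <- do.call(rbind, lapply(split(seq_along(p), panel_calls$marker), function(i) {
    data.frame(marker = panel_calls$marker[i[1]],
               both_positive = sum(p[i] & r[i]),
               panel_only = sum(p[i] & !r[i]),
               reference_only = sum(!p[i] & r[i]),
               both_negative = sum(!p[i] & !r[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(per_marker) <- NULL
  disc <- which(p != r)
  discordant <- data.frame(
    sample_id = panel_calls$sample_id[disc],
    marker = panel_calls$marker[disc],
    panel_call = p[disc],
    reference_call = r[disc],
    reason = ifelse(p[disc], "panel_only", "reference_only"),
    stringsAsFactors = FALSE
  )
  structure(list(per_marker = per_marker, discordant = discordant,
                 n_samples = length(unique(panel_calls$sample_id))),
            class = "nb_concordance")
}

#' @export
print.nb_concordance <- function(x, ...) {
  cat("nb_concordance over", x$n_samples, "samples\n")
  print(x$per_marker)
  if (nrow(x$discordant)) {
    cat("discordant:\n")
    print(x$discordant)
  }
  invisible(x)
}

MARKER_ROWS <- c("MYCN", "1p36", "11q", "17q", "TERT", "ATRX")

profile_matrix_column <- function(profile) {
  cells <- character(0)
  for (mk in c("MYCN", "1p36", "11q", "17q")) {
    row <- cnv_call_for(profile, mk)
    cells[mk] <- if (is.null(row)) "none" else row$category[1]
  }
  sv <- profile$sv_calls
  cells["TERT"] <- if (!is.null(sv) && nrow(sv) > 0 &&
                         any(grepl("^tert_", sv$annotation))) "rearrangement" else "none"
  atrx <- "none"
  if ("atrx_alteration" %in% tmm_markers(profile)) atrx <- "alteration"
  cells["ATRX"] <- atrx
  snv <- profile$snv_calls
  genes <- character(0)
  if (!is.null(snv) && nrow(snv) > 0 && "gene" %in% names(snv)) {
    genes <- sort(unique(stats::na.omit(snv$gene)))
  }
  list(cells = cells, snv_genes = genes)
}

#' Build an oncoplot-style alteration matrix for a cohort
#'
#' Rows are the diagnostic markers (MYCN, 1p36, 11q, 17q, TERT, ATRX)
#' followed by every gene with an SNV in the cohort; columns are
#' samples ordered by risk class (ultra-high-risk first) and then by
#' marker burden. Cells carry the alteration category
#' (`amplification`, `gain`, `loss`, `deep_loss`, `rearrangement`,
#' `alteration`, `SNV`, `none`). Covariate rows record timepoint,
#' material and risk class.
#'
#' @param profiles list of `nb_tumor_profile`s.
#' @param pathway_gene_sets passed to `classify_risk()` for column
#'   ordering.
#' @return list with `matrix` (character, rows x samples) and
#'   `covariates` (data.frame).
#' @export
build_oncoplot_matrix <- function(profiles,
                                  pathway_gene_sets = default_pathway_gene_sets()) {
  if (length(profiles) == 0) {
    return(list(matrix = matrix(character(0), nrow = length(MARKER_ROWS), ncol = 0,
                                dimnames = list(MARKER_ROWS, NULL)),
                covariates = data.frame(sample_id = character(),
                                        timepoint = character(),
                                        material = character(),
                                        risk_class = character(),
                                        stringsAsFactors = FALSE)))
  }
  cols <- lapply(profiles, profile_matrix_column)
  risks <- vapply(profiles, function(p)
    classify_risk(p, pathway_gene_sets)$risk_class, "")
  snv_genes <- sort(unique(unlist(lapply(cols, `[[`, "snv_genes"))))
  rows <- c(MARKER_ROWS, snv_genes)
  mat <- matrix("none", nrow = length(rows), ncol = length(profiles),
                dimnames = list(rows, vapply(profiles, `[[`, "", "sample_id")))
  for (j in seq_along(profiles)) {
    mat[MARKER_ROWS, j] <- cols[[j]]$cells[MARKER_ROWS]
    if (length(cols[[j]]$snv_genes)) mat[cols[[j]]$snv_genes, j] <- "SNV"
  }
  burden <- colSums(mat != "none")
  rank <- match(risks, c("ultra_high_risk", "high_risk_tmm", "tmm_negative"))
  ord <- order(rank, -burden, colnames(mat))
  mat <- mat[, ord, drop = FALSE]
  covariates <- data.frame(
    sample_id = colnames(mat),
    timepoint = vapply(profiles[ord], `[[`, "", "timepoint"),
    material = vapply(profiles[ord], `[[`, "", "material"),
    risk_class = risks[ord],
    stringsAsFactors = FALSE
  )
  list(matrix = mat, covariates = covariates)
}

#' Write an oncoplot matrix as TSV
#'
#' @param oncoplot list from `build_oncoplot_matrix()`.
#' @param path output path; covariate rows are prefixed with `#`.
#' @export
write_oncoplot_tsv <- function(oncoplot, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cv in c("timepoint", "material", "risk_class")) {
    writeLines(paste(c(paste0("#", cv), oncoplot$covariates[[cv]]),
                     collapse = "\t"), con)
  }
  writeLines(paste(c("row", colnames(oncoplot$matrix)), collapse = "\t"), con)
  for (i in seq_len(nrow(oncoplot$matrix))) {
    writeLines(paste(c(rownames(oncoplot$matrix)[i], oncoplot$matrix[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Plot an oncoplot matrix
#'
#' Minimal base-graphics rendering of the alteration matrix: one tile
#' per (row, sample), colored by alteration category.
#'
#' @param oncoplot list from `build_oncoplot_matrix()`.
#' @param ... passed to `graphics::image`.
#' @export
plot_oncoplot <- function(oncoplot, ...) {
  mat <- oncoplot$matrix
  cats <- c("none", "SNV", "gain", "loss", "deep_loss", "amplification",
            "rearrangement", "alteration")
  cols <- c("grey95", "forestgreen", "salmon", "steelblue", "navy",
            "firebrick", "orange", "purple")
  z <- matrix(match(mat, cats), nrow = nrow(mat))
  graphics::image(x = seq_len(ncol(mat)), y = seq_len(nrow(mat)),
                  z = t(z[rev(seq_len(nrow(mat))), , drop = FALSE]),
                  col = cols, zlim = c(1, length(cats)),
                  xlab = "sample", ylab = "", axes = FALSE, ...)
  graphics::axis(2, at = seq_len(nrow(mat)), labels = rev(rownames(mat)),
                 las = 2, cex.axis = 0.7)
  graphics::axis(1, at = seq_len(ncol(mat)), labels = colnames(mat),
                 las = 2, cex.axis = 0.7)
  invisible(oncoplot)
}
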