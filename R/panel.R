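#' @import GenomicRanges IRanges S4Vectors
#' @importFrom methods is
NULL

REGION_CLASSES <- c("gene_target", "chromosomal_region", "reference_probe")
CHROM_REGION_LABELS <- c("1p36", "11q", "17q")

#' Construct a panel object
#'
#' A panel is the target universe of a hybrid-capture assay: gene target
#' regions, larger chromosomal regions tiled for copy-number assessment
#' (1p36, 11q, 17q), and genome-wide reference probes that anchor
#' copy-number normalization. Regions are stored as a `GRanges` with
#' 0-based half-open coordinates translated to the 1-based closed
#' convention `IRanges` uses; all exported coordinates (BED) stay 0-based
#' half-open.
#'
#' @param regions `GRanges` with metadata columns `gene` (character, `NA`
#'   when not gene-associated) and `region_class` (one of `gene_target`,
#'   `chromosomal_region`, `reference_probe`).
#' @return An object of class `nb_panel` with elements `regions`,
#'   `genes` (sorted unique gene symbols of gene targets) and
#'   `total_target_bp` (bp covered by the union of all regions).
#' @export
new_panel <- function(regions) {
  stopifnot(is(regions, "GRanges"))
  mc <- S4Vectors::mcols(regions)
  if (!all(c("gene", "region_class") %in% names(mc))) {
    stop("panel regions need 'gene' and 'region_class' metadata columns")
  }
  bad <- !mc$region_class %in% REGION_CLASSES
  if (any(bad)) {
    stop("unknown region_class: ", paste(unique(mc$region_class[bad]), collapse = ", "))
  }
  if (any(mc$region_class == "reference_probe" & !is.na(mc$gene))) {
    stop("reference_probe regions must not carry a gene symbol")
  }
  regions <- GenomicRanges::sort(regions, ignore.strand = TRUE)
  # same-class regions must be disjoint after loading
  for (cl in unique(mc$region_class)) {
    sub <- regions[S4Vectors::mcols(regions)$region_class == cl]
    if (length(GenomicRanges::reduce(sub, ignore.strand = TRUE,
                                     min.gapwidth = 0L)) != length(sub)) {
      stop("overlapping ", cl, " regions after merge; panel invariant violated")
    }
  }
  genes <- sort(unique(stats::na.omit(
    S4Vectors::mcols(regions)$gene[S4Vectors::mcols(regions)$region_class == "gene_target"]
  )))
  structure(
    list(
      regions = regions,
      genes = as.character(genes),
      total_target_bp = sum(GenomicRanges::width(
        GenomicRanges::reduce(regions, ignore.strand = TRUE)
      ))
    ),
    class = "nb_panel"
  )
}

#' Load a panel from a BED file and optional gene annotation table
#'
#' The BED file is 0-based half-open with at least three columns; an
#' optional fourth column carries a label. Labels `1p36`, `11q` and `17q`
#' become `chromosomal_region` records, labels matching `^REF`
#' (case-insensitive) become `reference_probe` records, and any other
#' label becomes a `gene_target` with `gene` set to the label. Records
#' without a label (or with label `.`) are annotated by overlap with the
#' gene table when one is given, otherwise remain unlabeled gene targets.
#' Overlapping records of the same class are merged.
#'
#' @param bed path to a BED file (or a character vector of BED lines).
#' @param gene_table optional path to a tab-separated table with columns
#'   `gene`, `chrom`, `start`, `end` (0-based half-open) and optionally
#'   `class`; used to label unlabeled records and to look up gene
#'   intervals (e.g. the TERT gene body for rearrangement classification).
#' @return An `nb_panel` object.
#' @export
load_panel <- function(bed, gene_table = NULL) {
  lines <- if (length(bed) == 1 && file.exists(bed)) readLines(bed) else bed
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("BED input contains no records")
  fields <- strsplit(lines[idx], "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", idx[which(nf < 3)[1]], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", idx[which(is.na(start) | is.na(end))[1]],
         ": non-numeric coordinates")
  }
  if (any(end <= start)) {
    stop("invalid interval at BED line ", idx[which(end <= start)[1]],
         ": end must exceed start")
  }
  label <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".", ""), ".")
  label[label == "."] <- NA_character_

  gt <- NULL
  if (!is.null(gene_table)) {
    gt <- read_gene_table(gene_table)
    miss <- is.na(label)
    if (any(miss)) {
      q <- GenomicRanges::GRanges(chrom[miss], IRanges::IRanges(start[miss] + 1, end[miss]))
      hit <- GenomicRanges::findOverlaps(q, gt$gr, select = "first")
      label[miss][!is.na(hit)] <- gt$table$gene[hit[!is.na(hit)]]
    }
  }

  region_class <- rep("gene_target", length(chrom))
  region_class[!is.na(label) & label %in% CHROM_REGION_LABELS] <- "chromosomal_region"
  region_class[!is.na(label) & grepl("^ref", label, ignore.case = TRUE)] <- "reference_probe"
  if (!is.null(gt) && "class" %in% names(gt$table)) {
    m <- match(label, gt$table$gene)
    cls <- gt$table$class[m]
    region_class[!is.na(cls)] <- cls[!is.na(cls)]
  }
  gene <- ifelse(region_class == "gene_target" | region_class == "chromosomal_region",
                 label, NA_character_)

  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               gene = gene, region_class = region_class)
  merged <- lapply(split(gr, S4Vectors::mcols(gr)$region_class), function(sub) {
    # merge true overlaps only; records that merely touch stay separate
    red <- GenomicRanges::reduce(sub, ignore.strand = TRUE, with.revmap = TRUE,
                                 min.gapwidth = 0L)
    genes <- vapply(S4Vectors::mcols(red)$revmap, function(i) {
      g <- unique(stats::na.omit(S4Vectors::mcols(sub)$gene[i]))
      if (length(g) == 0) NA_character_ else paste(g, collapse = ",")
    }, "")
    S4Vectors::mcols(red) <- S4Vectors::DataFrame(
      gene = genes,
      region_class = rep(unique(S4Vectors::mcols(sub)$region_class), length(red))
    )
    red
  })
  out <- GenomicRanges::sort(do.call(c, unname(merged)), ignore.strand = TRUE)
  new_panel(out)
}

read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start + 1, tab$end))
  list(table = tab, gr = gr)
}

#' Write a panel back to BED
#'
#' Emits 0-based half-open records with the gene symbol (or region-class
#' label) in the fourth column; `load_panel()` on the output reconstructs
#' an identical panel.
#'
#' @param panel an `nb_panel`.
#' @param path output file path.
#' @export
write_panel <- function(panel, path) {
  gr <- panel$regions
  mc <- S4Vectors::mcols(gr)
  label <- ifelse(mc$region_class == "reference_probe",
                  paste0("REF_", seq_along(gr)),
                  ifelse(is.na(mc$gene), ".", mc$gene))
  writeLines(paste(GenomicRanges::seqnames(gr),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   label, sep = "\t"), path)
  invisible(path)
}

#' Tile panel regions into fixed-size analysis bins
#'
#' Each region is subdivided into consecutive bins of `bin_size` bp; the
#' last bin of a region may be shorter. Bins tile their parent region
#' exactly, with no gaps or overlap.
#'
#' @param panel an `nb_panel`.
#' @param bin_size bin width in bp (default 100, minimum 10).
#' @return `GRanges` of bins with metadata columns `region_idx` (index of
#'   the parent region in `panel$regions`), `bin_idx` (1-based within the
#'   region), `gene` and `region_class` inherited from the parent.
#' @export
make_bins <- function(panel, bin_size = 100) {
  if (!is.numeric(bin_size) || bin_size < 10) {
    stop("bin_size must be at least 10 bp")
  }
  gr <- panel$regions
  # GenomicRanges::tile balances widths; bins here are fixed-size from the
  # region start, with only the last bin short
  starts <- unlist(lapply(seq_along(gr), function(i) {
    seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i], by = bin_size)
  }))
  region_idx <- rep(seq_along(gr), ceiling(GenomicRanges::width(gr) / bin_size))
  ends <- pmin(starts + bin_size - 1, GenomicRanges::end(gr)[region_idx])
  bins <- GenomicRanges::GRanges(
    rep(GenomicRanges::seqnames(gr), ceiling(GenomicRanges::width(gr) / bin_size)),
    IRanges::IRanges(starts, ends)
  )
  S4Vectors::mcols(bins) <- S4Vectors::DataFrame(
    region_idx = region_idx,
    bin_idx = unlist(lapply(ceiling(GenomicRanges::width(gr) / bin_size), seq_len)),
    gene = S4Vectors::mcols(gr)$gene[region_idx],
    region_class = S4Vectors::mcols(gr)$region_class[region_idx]
  )
  bins
}

#' Summarize a panel
#'
#' @param panel an `nb_panel`.
#' @return list with `n_regions`, `n_genes`, `n_reference_probes` and
#'   `total_target_bp`.
#' @export
panel_summary <- function(panel) {
  mc <- S4Vectors::mcols(panel$regions)
  list(
    n_regions = length(panel$regions),
    n_genes = length(panel$genes),
    n_reference_probes = sum(mc$region_class == "reference_probe"),
    total_target_bp = panel$total_target_bp
  )
}

#' @export
print.nb_panel <- function(x, ...) {
  s <- panel_summary(x)
  cat(sprintf("nb_panel: %d regions (%d genes, %d reference probes), %d target bp\n",
              s$n_regions, s$n_genes, s$n_reference_probes, s$total_target_bp))
  invisible(x)
}

#' Interval of a named gene on the panel
#'
#' @param panel an `nb_panel`.
#' @param gene gene symbol.
#' @return `GRanges` spanning the gene's target regions.
#' @export
gene_interval <- function(panel, gene) {
  mc <- S4Vectors::mcols(panel$regions)
  hit <- !is.na(mc$gene) & mc$gene == gene
  if (!any(hit)) stop("gene not on panel: ", gene)
  GenomicRanges::reduce(panel$regions[hit], ignore.strand = TRUE)
}

#' Bundled miniature example panel
#'
#' A small synthetic stand-in for a diagnostic neuroblastoma panel, on
#' synthetic contigs: gene targets for MYCN, ALK, TERT and ATRX,
#' chromosomal-region tiles for 1p36, 11q and 17q, and 65 reference
#' probes spread across the contigs. Coordinates are synthetic and match
#' the simulator's default contigs; they carry no relation to any genome
#' build.
#'
#' @return An `nb_panel`.
#' @export
example_panel <- function() {
  load_panel(system.file("extdata", "mini_panel_synthetic.bed", package = "nbpanel"),
             system.file("extdata", "mini_panel_genes_synthetic.tsv", package = "nbpanel"))
}

#' Synthetic contigs matching the example panel
#'
#' @return data.frame with columns `name` and `length` suitable for
#'   `sim_config()` together with `example_panel()`.
#' @export
example_contigs <- function() {
  data.frame(
    name = c("chr1s", "chr2s", "chr5s", "chr11s", "chr17s", "chrXs"),
    length = c(120000L, 120000L, 120000L, 60000L, 60000L, 60000L),
    stringsAsFactors = FALSE
  )
}
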