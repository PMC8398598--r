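#' Merge structural-variant call sets from multiple callers
#'
#' Consensus rule used for multi-caller SV integration: calls whose two
#' breakpoints both lie within `window` bp of one another (and whose
#' types are compatible) are collapsed by single-linkage; the merged
#' call takes the median position per breakpoint side and the union of
#' supporting caller names; merged calls supported by fewer than
#' `min_callers` distinct callers are discarded. With `window = 0` only
#' exactly coincident calls collapse; with `min_callers = 1` nothing is
#' discarded.
#'
#' @param callsets named list of data.frames (one per caller, name =
#'   caller) with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`,
#'   `type`; or a single data.frame with a `caller` column.
#' @param window breakpoint collapse window in bp (default 500).
#' @param min_callers minimum distinct supporting callers (default 2).
#' @return data.frame of consensus calls: `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, `type`, `n_callers`, `callers` (comma-joined,
#'   sorted), `n_calls`.
#' @export
merge_sv_callsets <- function(callsets, window = 500, min_callers = 2) {
  if (window < 0) stop("window must be non-negative")
  if (min_callers < 1) stop("min_callers must be at least 1")
  if (is.data.frame(callsets)) {
    stopifnot("caller" %in% names(callsets))
    calls <- callsets
  } else {
    calls <- do.call(rbind, lapply(names(callsets), function(nm) {
      df <- callsets[[nm]]
      df$caller <- if (nrow(df)) nm else character(0)
      df
    }))
  }
  if (is.null(calls) || nrow(calls) == 0) {
    return(empty_consensus())
  }
  # canonical side order so identical junctions written either way match
  swap <- (calls$chrom_a > calls$chrom_b) |
    (calls$chrom_a == calls$chrom_b & calls$pos_a > calls$pos_b)
  tmp_c <- calls$chrom_a[swap]; tmp_p <- calls$pos_a[swap]
  calls$chrom_a[swap] <- calls$chrom_b[swap]; calls$pos_a[swap] <- calls$pos_b[swap]
  calls$chrom_b[swap] <- tmp_c; calls$pos_b[swap] <- tmp_p
  calls <- calls[order(calls$chrom_a, calls$pos_a, calls$chrom_b,
                       calls$pos_b, calls$caller), , drop = FALSE]

  grp <- paste(calls$chrom_a, calls$chrom_b, calls$type, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    sub <- calls[idx, , drop = FALSE]
    n <- nrow(sub)
    edges <- which(outer(sub$pos_a, sub$pos_a, function(x, y) abs(x - y) <= window) &
                     outer(sub$pos_b, sub$pos_b, function(x, y) abs(x - y) <= window),
                   arr.ind = TRUE)
    edges <- edges[edges[, 1] < edges[, 2], , drop = FALSE]
    comp <- components_from_edges(n, edges)
    for (cc in unique(comp)) {
      mem <- comp == cc
      callers <- sort(unique(sub$caller[mem]))
      if (length(callers) < min_callers) next
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = sub$chrom_a[1],
        pos_a = as.integer(round(stats::median(sub$pos_a[mem]))),
        chrom_b = sub$chrom_b[1],
        pos_b = as.integer(round(stats::median(sub$pos_b[mem]))),
        type = sub$type[1],
        n_callers = length(callers),
        callers = paste(callers, collapse = ","),
        n_calls = sum(mem),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty_consensus())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom_a, res$pos_a, res$chrom_b, res$pos_b, res$type), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_consensus <- function() {
  data.frame(chrom_a = character(), pos_a = integer(), chrom_b = character(),
             pos_b = integer(), type = character(), n_callers = integer(),
             callers = character(), n_calls = integer(), stringsAsFactors = FALSE)
}

#' Read one caller's SV call set from TSV or VCF
#'
#' TSV input is the 6-column breakpoint table
#' `chrom_a pos_a chrom_b pos_b type caller` (header optional). VCF
#' input is parsed for BND records: each breakend's mate coordinates are
#' taken from the bracketed ALT notation, and junctions are
#' deduplicated so a mate pair yields one call.
#'
#' @param path input file.
#' @param caller caller name to stamp on the calls; defaults to the
#'   file name stem (TSV caller column wins when present).
#' @return data.frame with columns `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`, `type`, `caller`.
#' @export
read_sv_callset <- function(path, caller = NULL) {
  if (is.null(caller)) caller <- sub("\\.[^.]*$", "", basename(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^##fileformat=VCF", first)) {
    lines <- readLines(path, warn = FALSE)
    body <- lines[!grepl("^#", lines)]
    if (length(body) == 0) return(empty_callset(caller))
    f <- strsplit(body, "\t")
    chrom <- vapply(f, `[[`, "", 1L)
    pos <- as.integer(vapply(f, `[[`, "", 2L))
    alt <- vapply(f, `[[`, "", 5L)
    m <- regmatches(alt, regexec("[][]([^:]+):([0-9]+)[][]", alt))
    is_bnd <- lengths(m) == 3
    if (!any(is_bnd)) return(empty_callset(caller))
    out <- data.frame(
      chrom_a = chrom[is_bnd], pos_a = pos[is_bnd],
      chrom_b = vapply(m[is_bnd], `[[`, "", 2L),
      pos_b = as.integer(vapply(m[is_bnd], `[[`, "", 3L)),
      type = "BND", caller = caller, stringsAsFactors = FALSE
    )
    out$type <- ifelse(out$chrom_a == out$chrom_b, "intrachromosomal", "translocation")
    # collapse the two records describing the same junction
    swap <- (out$chrom_a > out$chrom_b) |
      (out$chrom_a == out$chrom_b & out$pos_a > out$pos_b)
    key <- ifelse(swap,
                  paste(out$chrom_b, out$pos_b, out$chrom_a, out$pos_a),
                  paste(out$chrom_a, out$pos_a, out$chrom_b, out$pos_b))
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  tab <- utils::read.delim(path, header = grepl("chrom", first),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("breakpoint TSV needs at least 5 columns")
  names(tab)[1:5] <- c("chrom_a", "pos_a", "chrom_b", "pos_b", "type")
  if (ncol(tab) >= 6) names(tab)[6] <- "caller" else tab$caller <- caller
  tab[, c("chrom_a", "pos_a", "chrom_b", "pos_b", "type", "caller")]
}

empty_callset <- function(caller) {
  data.frame(chrom_a = character(), pos_a = integer(), chrom_b = character(),
             pos_b = integer(), type = character(), caller = caller[0],
             stringsAsFactors = FALSE)
}

#' Write SV calls as a VCF with breakend records
#'
#' Each junction is emitted as a pair of BND records linked by MATEID,
#' with support counts and annotation in INFO.
#'
#' @param calls data.frame from `call_svs()` or `merge_sv_callsets()`.
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @export
write_sv_vcf <- function(calls, path, sample_id = "sample") {
  hdr <- c("##fileformat=VCFv4.2",
           "##ALT=<ID=BND,Description=\"Breakend\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend\">",
           "##INFO=<ID=DP_PAIRS,Number=1,Type=Integer,Description=\"Discordant pair support\">",
           "##INFO=<ID=CLIP,Number=1,Type=Integer,Description=\"Clipped read support\">",
           "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Annotation\">",
           paste0("##SAMPLE=<ID=", sample_id, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  for (i in seq_len(nrow(calls))) {
    id1 <- sprintf("bnd_%d_1", i); id2 <- sprintf("bnd_%d_2", i)
    info_common <- sprintf("SVTYPE=BND;DP_PAIRS=%d;CLIP=%d;ANN=%s",
                           if ("n_discordant_pairs" %in% names(calls)) calls$n_discordant_pairs[i] else NA_integer_,
                           if ("n_clipped_reads" %in% names(calls)) calls$n_clipped_reads[i] else 0L,
                           if ("annotation" %in% names(calls)) calls$annotation[i] else ".")
    alt1 <- sprintf("N[%s:%d[", calls$chrom_b[i], calls$pos_b[i])
    alt2 <- sprintf("]%s:%d]N", calls$chrom_a[i], calls$pos_a[i])
    rows <- c(rows,
              paste(calls$chrom_a[i], calls$pos_a[i], id1, "N", alt1, ".", "PASS",
                    paste0(info_common, ";MATEID=", id2), sep = "\t"),
              paste(calls$chrom_b[i], calls$pos_b[i], id2, "N", alt2, ".", "PASS",
                    paste0(info_common, ";MATEID=", id1), sep = "\t"))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
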