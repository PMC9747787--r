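#' Fit a sample-specific internal-standard line
#'
#' Zero-intercept least-squares regression of standard reads on known copy
#' numbers: slope = sum(x*y) / sum(x^2), the reads-per-copy conversion
#' factor for the sample. R-squared uses the uncentered (through-origin)
#' definition 1 - SSE / sum(y^2); the p-value tests slope = 0 by a t
#' statistic with n - 1 degrees of freedom.
#'
#' @param copies Known standard copies per reaction (strictly positive).
#' @param reads Observed standard read counts (non-negative integers).
#' @param sample_id Identifier carried into diagnostics.
#' @return An object of class `standard_line` with elements `sample_id`,
#'   `slope`, `r2_uncentered`, `p_value`, `n_points`, `valid` and, when
#'   invalid, a `reason` code (`"no_amplification"`,
#'   `"too_few_nonzero_standards"` or `"nonpositive_slope"`).
#' @export
fit_standard_line <- function(copies, reads, sample_id = "") {
  if (length(copies) != length(reads)) stop("copies and reads lengths differ", call. = FALSE)
  if (length(copies) < 2) stop("need at least 2 standard points", call. = FALSE)
  if (any(copies <= 0)) stop("standard copies must be strictly positive", call. = FALSE)
  if (any(reads < 0)) stop("reads must be non-negative", call. = FALSE)

  n <- length(copies)
  slope <- sum(copies * reads) / sum(copies^2)
  fitted <- slope * copies
  sse <- sum((reads - fitted)^2)
  ssy <- sum(reads^2)
  r2 <- if (ssy == 0) 0 else min(max(1 - sse / ssy, 0), 1)
  se <- sqrt(sse / (n - 1) / sum(copies^2))
  p <- if (se == 0) {
    if (slope == 0) 1 else 0  # perfect fit: p degenerate
  } else {
    2 * stats::pt(-abs(slope / se), df = n - 1)
  }

  n_nonzero <- sum(reads > 0)
  reason <- NA_character_
  valid <- TRUE
  if (n_nonzero == 0) {
    valid <- FALSE; reason <- "no_amplification"
  } else if (n_nonzero < 2) {
    valid <- FALSE; reason <- "too_few_nonzero_standards"
  } else if (slope <= 0) {
    valid <- FALSE; reason <- "nonpositive_slope"
  }

  structure(list(sample_id = sample_id, slope = slope, r2_uncentered = r2,
                 p_value = p, n_points = n, valid = valid, reason = reason),
            class = "standard_line")
}

#' @export
print.standard_line <- function(x, ...) {
  cat(sprintf("standard line [%s]: slope = %.4g reads/copy, R2 = %.4f, p = %.3g, n = %d%s\n",
              x$sample_id, x$slope, x$r2_uncentered, x$p_value, x$n_points,
              if (x$valid) "" else paste0(" (INVALID: ", x$reason, ")")))
  invisible(x)
}

#' Convert reads to copies per reaction using a standard line
#'
#' The core conversion: copies = reads / slope. Returns `NA` for an invalid
#' standard line (absence of calibration is not absence of DNA).
#'
#' @param reads Non-negative read counts.
#' @param line A `standard_line`.
#' @return Copies per reaction (same length as `reads`); `NA` if `line` is
#'   invalid.
#' @export
reads_to_copies <- function(reads, line) {
  stopifnot(inherits(line, "standard_line"))
  if (any(reads < 0)) stop("reads must be non-negative", call. = FALSE)
  if (!line$valid) return(rep(NA_real_, length(reads)))
  reads / line$slope
}

#' Scale copies per reaction to copies per litre
#'
#' copies/L = copies/reaction * (elution_volume_uL / template_volume_uL) /
#' water_volume_L. The factor makes explicit how much of the eluate entered
#' one PCR reaction and how much water it represents.
#'
#' @param copies_per_reaction Non-negative copies per PCR reaction.
#' @param water_volume_L Filtered water volume (L), default 1.
#' @param elution_volume_uL DNA elution volume (uL), default 100.
#' @param template_volume_uL Template volume per reaction (uL), default 2.
#' @return Copies per litre.
#' @export
scale_to_per_litre <- function(copies_per_reaction, water_volume_L = 1,
                               elution_volume_uL = 100, template_volume_uL = 2) {
  if (water_volume_L <= 0 || elution_volume_uL <= 0 || template_volume_uL <= 0) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  copies_per_reaction * (elution_volume_uL / template_volume_uL) / water_volume_L
}

#' Subtract cooler-blank copy numbers from a field sample
#'
#' Per taxon, field minus blank, floored at zero (negative concentrations
#' are meaningless). Taxa absent from the blank vector are unchanged.
#'
#' @param field Named numeric vector of field copy concentrations.
#' @param blank Named numeric vector of blank copy concentrations.
#' @return List with `values` (corrected vector) and `floored` (logical,
#'   which cells were floored to zero).
#' @export
subtract_blank <- function(field, blank) {
  stopifnot(!is.null(names(field)))
  adj <- field
  common <- intersect(names(field), names(blank))
  b <- blank[common]
  b[is.na(b)] <- 0
  adj[common] <- field[common] - b
  floored <- !is.na(adj) & adj < 0
  adj[floored] <- 0
  list(values = adj, floored = floored)
}

#' Apply taxon exclusion, merging and per-cell read filters
#'
#' Excluded taxa (e.g. saltwater fishes detected in a freshwater survey)
#' are dropped; merged taxa (e.g. two congeners treated as one taxon) are
#' summed into a new row; for read tables, cells below
#' `min_reads_per_cell` are zeroed. Row order is lexicographic on output.
#'
#' @param table Numeric matrix, taxa x samples (reads or copies).
#' @param filters Filter list as in [run_manifest()].
#' @param is_read_table If `TRUE`, apply the per-cell read threshold.
#' @return Filtered matrix of the same kind.
#' @export
apply_taxon_filters <- function(table, filters, is_read_table = FALSE) {
  stopifnot(is.matrix(table))
  excl <- filters$excluded_taxa %||% character()
  merged <- filters$merged_taxa %||% list()
  unknown <- setdiff(c(excl, unlist(merged)), rownames(table))
  if (length(unknown) > 0) {
    warning(sprintf("filter references unknown taxa: %s",
                    paste(unknown, collapse = ", ")))
  }
  table <- table[!rownames(table) %in% excl, , drop = FALSE]
  for (new_id in names(merged)) {
    src <- intersect(merged[[new_id]], rownames(table))
    if (length(src) == 0) next
    if (new_id %in% setdiff(rownames(table), src)) {
      stop(sprintf("merge target '%s' collides with an existing taxon", new_id),
           call. = FALSE)
    }
    merged_row <- colSums(table[src, , drop = FALSE])
    table <- table[!rownames(table) %in% src, , drop = FALSE]
    table <- rbind(table, matrix(merged_row, nrow = 1,
                                 dimnames = list(new_id, colnames(table))))
  }
  if (is_read_table && (filters$min_reads_per_cell %||% 0) > 0) {
    table[table < filters$min_reads_per_cell] <- 0
  }
  table[order(rownames(table)), , drop = FALSE]
}

#' Calibrate a full metabarcoding run to copy concentrations
#'
#' The quantitative-metabarcoding core: per field sample and cooler blank,
#' fits the sample-specific standard line from the spiked internal-standard
#' rows, converts biological-taxon reads to copies per reaction, scales to
#' copies per litre, subtracts the matched cooler blank (floored at zero)
#' and applies taxon filters. PCR negatives carry no standards and are
#' never calibrated; their reads are summarized in the QC report and
#' flagged when they exceed `negative_control_warn_reads`.
#'
#' @param counts Integer matrix from [read_count_table()], including the
#'   standard rows named in `manifest$standards`.
#' @param manifest A `run_manifest`.
#' @return Object of class `qmiseq_calibration` with elements:
#'   \describe{
#'     \item{copies}{taxa x field-sample matrix of copies/L (`NA` where the
#'       sample is uncalibratable).}
#'     \item{provenance}{character matrix of per-cell flags (`raw`,
#'       `blank_corrected`, `floored_to_zero`, `uncalibratable`).}
#'     \item{standard_lines}{data.frame of per-sample slope, uncentered R2,
#'       p-value and validity.}
#'     \item{qc}{QC report: the same diagnostics plus negative-control read
#'       summaries and warnings.}
#'     \item{manifest}{the input manifest.}
#'   }
#' @export
calibrate_run <- function(counts, manifest) {
  stopifnot(is.matrix(counts), inherits(manifest, "run_manifest"))
  smp <- manifest$samples
  missing_cols <- setdiff(smp$sample_id, colnames(counts))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest sample '%s' missing from count table", missing_cols[1]),
         call. = FALSE)
  }
  std_ids <- manifest$standards$standard_id
  missing_std <- setdiff(std_ids, rownames(counts))
  if (length(missing_std) > 0) {
    stop(sprintf("standard row '%s' missing from count table", missing_std[1]),
         call. = FALSE)
  }
  bio_taxa <- setdiff(rownames(counts), std_ids)
  warnings_out <- character()

  calibrated <- smp$sample_id[smp$role %in% c("field", "cooler_blank")]
  lines <- lapply(calibrated, function(sid) {
    fit_standard_line(manifest$standards$copies_per_reaction,
                      counts[std_ids, sid], sample_id = sid)
  })
  names(lines) <- calibrated

  # copies/L per calibrated sample (fields and blanks alike)
  copies_L <- matrix(NA_real_, length(bio_taxa), length(calibrated),
                     dimnames = list(bio_taxa, calibrated))
  for (sid in calibrated) {
    ln <- lines[[sid]]
    meta <- smp[smp$sample_id == sid, ]
    if (!ln$valid) {
      warnings_out <- c(warnings_out,
                        sprintf("sample %s uncalibratable (%s)", sid, ln$reason))
      next
    }
    cpr <- reads_to_copies(counts[bio_taxa, sid], ln)
    copies_L[, sid] <- scale_to_per_litre(cpr, meta$water_volume_L,
                                          meta$elution_volume_uL,
                                          meta$template_volume_uL)
  }

  field_ids <- smp$sample_id[smp$role == "field"]
  copies <- copies_L[, field_ids, drop = FALSE]
  provenance <- matrix("raw", nrow(copies), ncol(copies), dimnames = dimnames(copies))
  provenance[is.na(copies)] <- "uncalibratable"

  for (sid in field_ids) {
    if (all(is.na(copies[, sid]))) next
    bid <- manifest$blank_map[[sid]]
    if (is.null(bid)) next
    if (!lines[[bid]]$valid) {
      warnings_out <- c(warnings_out,
                        sprintf("blank %s for field sample %s uncalibratable; no subtraction",
                                bid, sid))
      next
    }
    blank_col <- copies_L[, bid]
    detected <- !is.na(blank_col) & blank_col > 0
    if (!any(detected)) next
    adj <- subtract_blank(copies[, sid], blank_col[detected])
    changed <- names(adj$values)[adj$values != copies[, sid] | adj$floored]
    copies[, sid] <- adj$values
    provenance[changed, sid] <- "blank_corrected"
    provenance[names(adj$floored)[adj$floored], sid] <- "floored_to_zero"
  }

  copies <- apply_taxon_filters(copies, manifest$filters, is_read_table = FALSE)
  keep <- rownames(copies)
  prov_keep <- intersect(keep, rownames(provenance))
  prov <- matrix("raw", nrow(copies), ncol(copies), dimnames = dimnames(copies))
  prov[prov_keep, ] <- provenance[prov_keep, colnames(copies)]
  prov[is.na(copies)] <- "uncalibratable"

  # negative controls: summarized, never calibrated or subtracted
  neg_ids <- smp$sample_id[smp$role == "pcr_negative"]
  neg_summary <- data.frame(
    sample_id = neg_ids,
    total_reads = vapply(neg_ids, function(s) sum(counts[bio_taxa, s]), 0),
    max_taxon_reads = vapply(neg_ids, function(s)
      if (length(bio_taxa)) max(counts[bio_taxa, s]) else 0, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  warn_thr <- manifest$filters$negative_control_warn_reads %||% 100L
  hot <- neg_summary$sample_id[neg_summary$max_taxon_reads > warn_thr]
  if (length(hot) > 0) {
    warnings_out <- c(warnings_out,
                      sprintf("PCR negative %s exceeds %d reads for a taxon", hot, warn_thr))
  }

  line_df <- do.call(rbind, lapply(lines, function(l)
    data.frame(sample_id = l$sample_id, slope = l$slope,
               r2_uncentered = l$r2_uncentered, p_value = l$p_value,
               n_points = l$n_points, valid = l$valid, reason = l$reason,
               stringsAsFactors = FALSE)))
  rownames(line_df) <- NULL

  structure(list(copies = copies, provenance = prov,
                 standard_lines = line_df, lines = lines,
                 qc = list(standard_lines = line_df,
                           negative_controls = neg_summary,
                           warnings = warnings_out),
                 manifest = manifest),
            class = "qmiseq_calibration")
}

#' @export
print.qmiseq_calibration <- function(x, ...) {
  cat("qMiSeq calibration:", nrow(x$copies), "taxa x", ncol(x$copies),
      "field samples (copies/L)\n")
  ok <- x$standard_lines$valid
  cat(sprintf("standard lines: %d/%d valid; slopes %.1f-%.1f reads/copy\n",
              sum(ok), length(ok),
              min(x$standard_lines$slope[ok]), max(x$standard_lines$slope[ok])))
  if (length(x$qc$warnings)) cat("QC warnings:", length(x$qc$warnings), "\n")
  invisible(x)
}

#' @export
summary.qmiseq_calibration <- function(object, ...) {
  out <- list(
    n_taxa = nrow(object$copies),
    n_samples = ncol(object$copies),
    standard_lines = object$standard_lines,
    negative_controls = object$qc$negative_controls,
    warnings = object$qc$warnings,
    copies_quartiles = stats::quantile(object$copies[object$copies > 0],
                                       na.rm = TRUE)
  )
  class(out) <- "summary.qmiseq_calibration"
  out
}

#' @export
print.summary.qmiseq_calibration <- function(x, ...) {
  cat("qMiSeq calibration summary\n")
  cat(sprintf("  %d taxa x %d field samples\n", x$n_taxa, x$n_samples))
  cat("  standard lines:\n")
  print(x$standard_lines, digits = 4)
  cat("  PCR negative controls:\n")
  print(x$negative_controls)
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Extract the copy-concentration matrix
#' @param object A `qmiseq_calibration`.
#' @param ... Unused.
#' @return Numeric matrix of copies/L, taxa x field samples.
#' @export
coef.qmiseq_calibration <- function(object, ...) object$copies

#' Plot sample-specific standard lines
#'
#' One panel: standard copies vs reads for every calibrated sample, with
#' the fitted through-origin lines.
#'
#' @param x A `qmiseq_calibration`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qmiseq_calibration <- function(x, ...) {
  std <- x$manifest$standards
  lines_ok <- x$standard_lines[x$standard_lines$valid, ]
  xs <- std$copies_per_reaction
  ymax <- max(lines_ok$slope) * max(xs)
  graphics::plot(NA, xlim = c(0, max(xs)), ylim = c(0, ymax),
                 xlab = "standard copies / reaction", ylab = "reads",
                 main = "Sample-specific standard lines", ...)
  for (i in seq_len(nrow(lines_ok))) {
    graphics::abline(0, lines_ok$slope[i], col = grDevices::grey(0.4))
  }
  invisible(x)
}

#' Collapse field-sample columns to site columns
#'
#' Field samples map to sites via the manifest; with one sample per site
#' this is a rename, with replicates the mean is taken.
#'
#' @param calibration A `qmiseq_calibration`.
#' @return Numeric matrix of copies/L, taxa x sites.
#' @export
copies_by_site <- function(calibration) {
  stopifnot(inherits(calibration, "qmiseq_calibration"))
  smp <- calibration$manifest$samples
  field <- smp[smp$role == "field", ]
  sites <- unique(field$site_id)
  out <- sapply(sites, function(s) {
    cols <- field$sample_id[field$site_id == s]
    rowMeans(calibration$copies[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(sites),
                                       dimnames = list(rownames(calibration$copies), sites))
  colnames(out) <- sites
  out
}
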