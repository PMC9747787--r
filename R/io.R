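#' Read a taxon-by-sample read-count table
#'
#' Parses a wide TSV whose first column is the taxon id (header `taxon`) and
#' whose remaining columns are samples. Cells must be non-negative integers;
#' rows for spiked internal-standard DNAs sit alongside biological taxa.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix with taxa as rownames and samples as colnames.
#' @export
read_count_table <- function(path) {
  mat <- .read_wide_table(path)
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "read_count_table: cell [taxon '%s', sample '%s'] is not a non-negative integer",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), call. = FALSE)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Read a taxon-by-sample copy-concentration table
#'
#' Like [read_count_table()] but for real-valued copies/L tables written by
#' [write_copy_table()]. Missing cells (uncalibratable samples) are `NA`.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, taxa as rownames, samples as colnames.
#' @export
read_copy_table <- function(path) {
  mat <- .read_wide_table(path, allow_na = TRUE)
  if (any(mat < 0, na.rm = TRUE)) {
    stop("read_copy_table: negative copy concentration", call. = FALSE)
  }
  mat
}

.read_wide_table <- function(path, allow_na = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 1 || names(df)[1] != "taxon") {
    stop("malformed table: first header field must be 'taxon'", call. = FALSE)
  }
  taxa <- df[[1]]
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon id '%s'", taxa[duplicated(taxa)][1]), call. = FALSE)
  }
  body <- df[, -1, drop = FALSE]
  mat <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                dimnames = list(taxa, names(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) & !(allow_na & (cell == "NA" | cell == "")))
    if (length(bad) > 0) {
      stop(sprintf("parse error at row '%s', column '%s': '%s' is not numeric",
                   taxa[bad[1]], names(body)[j], cell[bad[1]]), call. = FALSE)
    }
    mat[, j] <- val
  }
  mat
}

#' Write a copy-concentration table to TSV
#'
#' Rows and columns are sorted lexicographically so that two writes of the
#' same table are byte-identical; values are written at full double
#' precision (17 significant digits) so that a read-back reproduces the
#' table exactly.
#'
#' @param table Numeric matrix (taxa x samples), values >= 0 or `NA`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_copy_table <- function(table, path) {
  stopifnot(is.matrix(table))
  if (any(table < 0, na.rm = TRUE)) stop("copy table must be non-negative", call. = FALSE)
  if (nrow(table) > 0) table <- table[order(rownames(table)), , drop = FALSE]
  table <- table[, order(colnames(table)), drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("taxon", colnames(table)), collapse = "\t"), con)
  for (i in seq_len(nrow(table))) {
    cells <- ifelse(is.na(table[i, ]), "NA", sprintf("%.17g", table[i, ]))
    writeLines(paste(c(rownames(table)[i], cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a read-count table to TSV
#'
#' @param table Integer matrix (taxa x samples).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_count_table <- function(table, path) {
  stopifnot(is.matrix(table))
  table <- table[order(rownames(table)), order(colnames(table)), drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("taxon", colnames(table)), collapse = "\t"), con)
  for (i in seq_len(nrow(table))) {
    writeLines(paste(c(rownames(table)[i], format(table[i, ], scientific = FALSE, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a site-by-taxon capture-survey table
#'
#' Long-format TSV with columns `site_id`, `taxon`, `abundance` (integer
#' count of captured individuals) and `biomass_g` (total wet mass in grams).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with one row per (site, taxon) record.
#' @export
read_capture_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  need <- c("site_id", "taxon", "abundance", "biomass_g")
  if (!all(need %in% names(df))) {
    stop("capture table must have columns site_id, taxon, abundance, biomass_g",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("capture table has no records")
    return(data.frame(site_id = character(), taxon = character(),
                      abundance = integer(), biomass_g = numeric(),
                      stringsAsFactors = FALSE))
  }
  ab <- suppressWarnings(as.numeric(df$abundance))
  bm <- suppressWarnings(as.numeric(df$biomass_g))
  if (any(is.na(ab)) || any(ab < 0) || any(ab != round(ab))) {
    stop("capture abundance must be non-negative integers", call. = FALSE)
  }
  if (any(is.na(bm)) || any(bm < 0)) {
    stop("capture biomass_g must be non-negative reals", call. = FALSE)
  }
  key <- paste(df$site_id, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (site, taxon) record: %s / %s",
                 df$site_id[duplicated(key)][1], df$taxon[duplicated(key)][1]),
         call. = FALSE)
  }
  if (any((ab == 0) != (bm == 0))) {
    warning("records where exactly one of abundance/biomass is zero (weighing error tolerated)")
  }
  data.frame(site_id = df$site_id, taxon = df$taxon,
             abundance = as.integer(ab), biomass_g = bm,
             stringsAsFactors = FALSE)
}

#' Write a capture table to TSV
#' @param capture data.frame as returned by [read_capture_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_capture_table <- function(capture, path) {
  capture <- capture[order(capture$site_id, capture$taxon), , drop = FALSE]
  utils::write.table(capture, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- manifest -------------------------------------------------------------

.default_standards <- function() {
  data.frame(standard_id = c("std1", "std2", "std3"),
             copies_per_reaction = c(5, 25, 50),
             stringsAsFactors = FALSE)
}

.default_filters <- function() {
  list(min_reads_per_cell = 0L, excluded_taxa = character(),
       merged_taxa = list(), negative_control_warn_reads = 100L)
}

#' Construct a validated run manifest
#'
#' The manifest binds samples to sites, field samples to their cooler
#' blanks, and carries the internal-standard specification and taxon
#' filters. Defaults follow the field protocol: 1 L water per sample,
#' 100 uL elution, 2 uL template per PCR reaction, standards at 5/25/50
#' copies per reaction.
#'
#' @param samples data.frame with columns `sample_id`, `site_id`,
#'   `river_id`, `role` (one of `"field"`, `"cooler_blank"`,
#'   `"pcr_negative"`) and optionally `water_volume_L`,
#'   `elution_volume_uL`, `template_volume_uL`.
#' @param blank_map Named character vector or list mapping each field
#'   sample id to the id of its cooler blank.
#' @param standards data.frame with columns `standard_id`,
#'   `copies_per_reaction`; defaults to 5/25/50.
#' @param filters List with elements `min_reads_per_cell`,
#'   `excluded_taxa`, `merged_taxa`, `negative_control_warn_reads`.
#' @param seed Integer seed recorded with the run.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(samples, blank_map, standards = .default_standards(),
                         filters = .default_filters(), seed = 1L) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "site_id", "role")
  if (!all(need %in% names(samples))) {
    stop("samples need columns sample_id, site_id, role", call. = FALSE)
  }
  if (!"river_id" %in% names(samples)) samples$river_id <- samples$site_id
  if (anyDuplicated(samples$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  roles <- c("field", "cooler_blank", "pcr_negative")
  if (!all(samples$role %in% roles)) {
    stop(sprintf("unknown sample role '%s'", setdiff(samples$role, roles)[1]),
         call. = FALSE)
  }
  for (vcol in c("water_volume_L", "elution_volume_uL", "template_volume_uL")) {
    if (!vcol %in% names(samples)) samples[[vcol]] <- NA_real_
    samples[[vcol]] <- as.numeric(samples[[vcol]])
  }
  samples$water_volume_L[is.na(samples$water_volume_L)] <- 1.0
  samples$elution_volume_uL[is.na(samples$elution_volume_uL)] <- 100
  samples$template_volume_uL[is.na(samples$template_volume_uL)] <- 2
  for (vcol in c("water_volume_L", "elution_volume_uL", "template_volume_uL")) {
    if (any(samples[[vcol]] <= 0)) {
      stop(sprintf("%s must be strictly positive", vcol), call. = FALSE)
    }
  }

  blank_map <- unlist(blank_map)
  field_ids <- samples$sample_id[samples$role == "field"]
  blank_ids <- samples$sample_id[samples$role == "cooler_blank"]
  missing_blank <- setdiff(field_ids, names(blank_map))
  if (length(missing_blank) > 0) {
    stop(sprintf("field sample '%s' has no cooler blank in blank_map",
                 missing_blank[1]), call. = FALSE)
  }
  if (!all(names(blank_map) %in% field_ids)) {
    stop("blank_map keys must be field sample ids", call. = FALSE)
  }
  if (!all(blank_map %in% blank_ids)) {
    stop(sprintf("blank_map target '%s' is not a cooler_blank sample",
                 setdiff(blank_map, blank_ids)[1]), call. = FALSE)
  }

  standards <- as.data.frame(standards, stringsAsFactors = FALSE)
  if (nrow(standards) < 2) stop("need at least 2 internal standards", call. = FALSE)
  if (anyDuplicated(standards$standard_id)) {
    stop("standard ids must be unique", call. = FALSE)
  }
  if (any(standards$copies_per_reaction <= 0)) {
    stop("standard copies per reaction must be > 0", call. = FALSE)
  }

  filters <- utils::modifyList(.default_filters(), filters)
  merged_sources <- unlist(filters$merged_taxa, use.names = FALSE)
  if (anyDuplicated(merged_sources)) {
    stop("merged_taxa source sets must be disjoint", call. = FALSE)
  }
  if (length(intersect(merged_sources, filters$excluded_taxa)) > 0) {
    stop("excluded and merged taxon sets must be disjoint", call. = FALSE)
  }

  structure(list(samples = samples, blank_map = blank_map,
                 standards = standards, filters = filters,
                 seed = as.integer(seed)),
            class = "run_manifest")
}

#' Read a run manifest from YAML or JSON
#'
#' Missing volumes and standards are filled with protocol defaults
#' (1 L water, 100 uL elution, 2 uL template; standards 5/25/50 copies).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` manifest.
#' @return A validated `run_manifest`.
#' @export
read_manifest <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  samples <- do.call(rbind, lapply(raw$samples, function(s) {
    as.data.frame(s[lengths(s) == 1], stringsAsFactors = FALSE)
  }))
  standards <- if (is.null(raw$standards)) .default_standards() else {
    do.call(rbind, lapply(raw$standards, function(s)
      data.frame(standard_id = s$standard_id,
                 copies_per_reaction = as.numeric(s$copies_per_reaction),
                 stringsAsFactors = FALSE)))
  }
  filters <- if (is.null(raw$filters)) .default_filters() else raw$filters
  if (!is.null(filters$merged_taxa)) {
    filters$merged_taxa <- lapply(filters$merged_taxa, unlist)
  }
  run_manifest(samples = samples,
               blank_map = raw$blank_map %||% character(),
               standards = standards, filters = filters,
               seed = raw$seed %||% 1L)
}

#' Write a run manifest to YAML
#' @param manifest A `run_manifest`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_manifest <- function(manifest, path) {
  out <- list(
    samples = lapply(seq_len(nrow(manifest$samples)), function(i)
      as.list(manifest$samples[i, , drop = FALSE])),
    blank_map = as.list(manifest$blank_map),
    standards = lapply(seq_len(nrow(manifest$standards)), function(i)
      as.list(manifest$standards[i, , drop = FALSE])),
    filters = manifest$filters,
    seed = manifest$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_manifest <- function(x, ...) {
  tab <- table(x$samples$role)
  cat("qMiSeq run manifest:", nrow(x$samples), "samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  cat("standards:", paste(sprintf("%s=%g", x$standards$standard_id,
                                  x$standards$copies_per_reaction),
                          collapse = ", "), "copies/reaction\n")
  invisible(x)
}
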