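#' Read a beta-value matrix from disk
#'
#' Reads a probes x samples methylation table in either of two dialects:
#'
#' * `"plain-tsv"` — tab-separated, first column probe id, header row of
#'   sample ids;
#' * `"geo-series-matrix"` — the GEO series-matrix layout: `!`-prefixed
#'   metadata lines, with the data table between the
#'   `!series_matrix_table_begin` and `!series_matrix_table_end` sentinel
#'   lines.  Metadata lines are retained as a key-value list in the
#'   `"geo_metadata"` attribute.
#'
#' Ragged rows, duplicate ids and values outside \[0, 1\] are rejected with
#' the offending line or cell identified.
#'
#' @param path File path.
#' @param dialect `"plain-tsv"` (default) or `"geo-series-matrix"`.
#' @param detection_p_path Optional path to an aligned detection p-value
#'   table in the same plain-tsv layout.
#' @return A [beta_matrix()] on the fraction scale.
#' @export
read_beta_matrix <- function(path,
                             dialect = c("plain-tsv", "geo-series-matrix"),
                             detection_p_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    .pm_stop(paste("no such file:", path), "pm_io_error")
  meta <- NULL
  if (dialect == "geo-series-matrix") {
    lines <- readLines(path)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg)
      .pm_stop("missing or malformed series-matrix table sentinels",
               "pm_format_error")
    mlines <- grep("^!", lines[seq_len(beg - 1L)], value = TRUE)
    kv <- regmatches(mlines, regexec("^!([^\t]+)\t?(.*)$", mlines))
    meta <- stats::setNames(lapply(kv, function(m) gsub('"', '', m[3])),
                            vapply(kv, function(m) m[2], ""))
    tab <- .read_matrix_lines(lines[(beg + 1L):(end - 1L)], offset = beg)
  } else {
    tab <- .read_matrix_lines(readLines(path), offset = 0L)
  }
  bm <- beta_matrix(tab)
  if (!is.null(detection_p_path)) {
    dp <- .read_matrix_lines(readLines(detection_p_path), offset = 0L)
    bm <- beta_matrix(tab, dp)
  }
  if (!is.null(meta)) attr(bm, "geo_metadata") <- meta
  bm
}

# parse header + data lines of a tab-separated numeric matrix, reporting
# problems with 1-based file line numbers (offset = lines before the table)
.read_matrix_lines <- function(lines, offset = 0L) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) .pm_stop("empty table", "pm_format_error")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  ncol_expect <- length(hdr)
  sample_ids <- gsub('^"|"$', '', hdr[-1L])
  rows <- fields[-1L]
  n <- vapply(rows, length, 0L)
  if (any(n != ncol_expect))
    .pm_stop(sprintf("ragged row at line %d: %d fields, expected %d",
                     offset + 1L + which(n != ncol_expect)[1L],
                     n[n != ncol_expect][1L], ncol_expect),
             "pm_format_error")
  ids <- vapply(rows, function(r) gsub('^"|"$', '', r[1L]), "")
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(replace(r[-1L], r[-1L] %in%
                                                  c("", "NA", "null"), NA)),
           numeric(ncol_expect - 1L)))
  m <- t(matrix(vals, nrow = ncol_expect - 1L))
  dimnames(m) <- list(ids, sample_ids)
  m
}

#' Write a beta-value matrix as plain TSV
#'
#' Inverse of [read_beta_matrix()]'s plain-tsv dialect; full double
#' precision so that a write/read round trip is value-identical.
#'
#' @param x A `BetaMatrix` or plain matrix with dimnames.
#' @param path Output path.
#' @param what For a `BetaMatrix`, write the `"beta"` (default) or
#'   `"detection_p"` component.
#' @export
write_beta_matrix <- function(x, path, what = c("beta", "detection_p")) {
  what <- match.arg(what)
  m <- if (inherits(x, "BetaMatrix")) x[[what]] else x
  if (is.null(m)) .pm_stop("requested component is absent", "pm_invalid_input")
  df <- data.frame(probe_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# closed vocabularies of the probe annotation, with accepted aliases
.cpg_types <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                "OpenSea")
.cpg_type_alias <- stats::setNames(
  c("OpenSea", "OpenSea", "OpenSea", "OpenSea"),
  c("Open sea", "open sea", "", "None"))
.gene_regions <- c("TSS1500", "TSS200", "5'UTR", "FirstExon", "FirstIntron",
                   "GeneBody", "Intergenic")
.gene_region_alias <- stats::setNames(
  c("GeneBody", "GeneBody", "FirstExon", "FirstExon", "FirstIntron",
    "FirstIntron", "5'UTR", "5'UTR", "Intergenic", "Intergenic"),
  c("Body", "Gene body", "1stExon", "First exon", "1stIntron",
    "First intron", "5'UTR", "5UTR", "Intergenic region", ""))

.normalize_vocab <- function(x, vocab, alias, what) {
  x <- trimws(as.character(x))
  hit <- match(x, names(alias))
  x[!is.na(hit)] <- alias[hit[!is.na(hit)]]
  bad <- setdiff(unique(x), vocab)
  if (length(bad))
    .pm_stop(sprintf("unknown %s token(s): %s", what,
                     paste(bad, collapse = ", ")),
             "pm_format_error")
  x
}

#' Read an Illumina-manifest-style probe annotation CSV
#'
#' Expects columns `IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`,
#' `Relation_to_UCSC_CpG_Island`, `UCSC_RefGene_Group` (case-sensitive).
#' CpG-island relations are normalised to
#' Island / N_Shore / S_Shore / N_Shelf / S_Shelf / OpenSea (shores are the
#' 2-kb regions flanking an island, shelves the 2-kb regions flanking a
#' shore) and gene regions to
#' TSS1500 / TSS200 / 5'UTR / FirstExon / FirstIntron / GeneBody /
#' Intergenic.  Unknown chromosome or vocabulary tokens are rejected.
#'
#' @param path CSV file path.
#' @return `data.frame` with columns `probe_id`, `chromosome` (character,
#'   "1".."22", "X", "Y"), `position`, `gene_symbol` (`NA` when not
#'   annotated), `cpg_type`, `gene_region`.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) .pm_stop(paste("no such file:", path), "pm_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
            "Relation_to_UCSC_CpG_Island", "UCSC_RefGene_Group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .pm_stop(paste("missing manifest column(s):", paste(miss, collapse = ", ")),
             "pm_format_error")
  chrom <- sub("^chr", "", trimws(df$CHR))
  bad <- setdiff(unique(chrom), c(as.character(1:22), "X", "Y"))
  if (length(bad))
    .pm_stop(paste("unknown chromosome token(s):", paste(bad, collapse = ", ")),
             "pm_format_error")
  pos <- suppressWarnings(as.numeric(df$MAPINFO))
  if (any(is.na(pos) | pos <= 0))
    .pm_stop("MAPINFO must be a positive integer position", "pm_format_error")
  gene <- trimws(df$UCSC_RefGene_Name)
  gene[gene %in% c("", "NA")] <- NA_character_
  ann <- data.frame(
    probe_id = trimws(df$IlmnID),
    chromosome = chrom,
    position = pos,
    gene_symbol = gene,
    cpg_type = .normalize_vocab(df$Relation_to_UCSC_CpG_Island,
                                .cpg_types, .cpg_type_alias, "CpG-type"),
    gene_region = .normalize_vocab(df$UCSC_RefGene_Group,
                                   .gene_regions, .gene_region_alias,
                                   "gene-region"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$probe_id))
    .pm_stop("duplicate probe ids in annotation", "pm_format_error")
  ann
}

#' Read a clinical sample sheet CSV
#'
#' Expected columns: `sample_id`, `patient_id`, `tissue_group` (C = normal
#' control pancreas, N = non-cancerous tissue from a cancer patient,
#' T = tumour), `recurrence` (logical), `rfs_days`, `os_days`, `dead`.
#' Survival fields may be empty (recorded as `NA`); extra columns are kept
#' as covariates.  Validated invariants: a recurrence requires an RFS time,
#' and RFS cannot exceed OS.
#'
#' @param path CSV file path.
#' @return `data.frame` of clinical records, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) .pm_stop(paste("no such file:", path), "pm_io_error")
  # tissue_group must stay character: a column of all "T" would
  # otherwise be type-converted to logical
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tissue_group = "character"))
  need <- c("sample_id", "patient_id", "tissue_group", "recurrence",
            "rfs_days", "os_days", "dead")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .pm_stop(paste("missing sample-sheet column(s):",
                   paste(miss, collapse = ", ")), "pm_format_error")
  df$recurrence <- as.logical(df$recurrence)
  df$dead <- as.logical(df$dead)
  df$rfs_days <- as.numeric(df$rfs_days)
  df$os_days <- as.numeric(df$os_days)
  validate_clinical(df)
}

#' Validate a clinical record table
#'
#' @param df Clinical `data.frame` as produced by [read_sample_sheet()] or
#'   [simulate_cohort()].
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id))
    .pm_stop("duplicate sample ids in sample sheet", "pm_format_error")
  bad <- setdiff(unique(df$tissue_group), c("C", "N", "T"))
  if (length(bad))
    .pm_stop(paste("unknown tissue group:", paste(bad, collapse = ", ")),
             "pm_format_error")
  if (any(df$recurrence & is.na(df$rfs_days), na.rm = TRUE))
    .pm_stop("recurrence = TRUE requires rfs_days", "pm_validation_error")
  both <- !is.na(df$rfs_days) & !is.na(df$os_days)
  if (any(df$rfs_days[both] > df$os_days[both]))
    .pm_stop("rfs_days exceeds os_days", "pm_validation_error")
  if (any(c(df$rfs_days, df$os_days) < 0, na.rm = TRUE))
    .pm_stop("negative survival time", "pm_validation_error")
  df
}

#' Assemble and cross-validate a cohort dataset
#'
#' Binds a beta matrix, probe annotation and clinical table into one
#' object, checking that every sample has a clinical record and every
#' probe an annotation row.
#'
#' @param beta A `BetaMatrix`.
#' @param annotation Probe annotation `data.frame` ([read_probe_annotation()]).
#' @param clinical Clinical `data.frame` ([read_sample_sheet()]).
#' @return Object of class `"CohortDataset"` (list of the three parts, with
#'   annotation re-ordered to match the probe order of `beta`).
#' @export
cohort_dataset <- function(beta, annotation, clinical) {
  stopifnot(inherits(beta, "BetaMatrix"))
  ms <- setdiff(sample_ids(beta), clinical$sample_id)
  if (length(ms))
    .pm_stop(paste("samples without clinical record:",
                   paste(utils::head(ms, 5), collapse = ", ")),
             "pm_validation_error")
  mp <- setdiff(probe_ids(beta), annotation$probe_id)
  if (length(mp))
    .pm_stop(paste("probes without annotation:",
                   paste(utils::head(mp, 5), collapse = ", ")),
             "pm_validation_error")
  validate_clinical(clinical)
  annotation <- annotation[match(probe_ids(beta), annotation$probe_id), ]
  rownames(annotation) <- NULL
  structure(list(beta = beta, annotation = annotation, clinical = clinical),
            class = "CohortDataset")
}

#' @export
print.CohortDataset <- function(x, ...) {
  tg <- table(factor(x$clinical$tissue_group, c("C", "N", "T")))
  cat("CohortDataset:", nrow(x$beta$beta), "probes,",
      ncol(x$beta$beta), "samples",
      sprintf("(C=%d, N=%d, T=%d)\n", tg["C"], tg["N"], tg["T"]))
  invisible(x)
}

#' Write a results table as TSV
#'
#' Deterministic tabular output used for QC reports, screen results and
#' panel evaluations: tab-separated with a header, columns in the order
#' given, p-value/AUC/beta-like columns fixed to 4 decimals and percent
#' columns to 1 decimal (column classes are inferred from names:
#' `*_pct`/`*percent*` are percents; `p`, `p_*`, `*_p`, `auc`, `*beta*`,
#' `*proportion*` are probabilities/fractions).
#'
#' @param records A `data.frame`.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (grepl("_pct$|percent", nm)) {
      out[[nm]] <- sprintf("%.1f", out[[nm]])
    } else if (grepl("^p$|^p_|_p$|auc|beta|proportion", nm)) {
      out[[nm]] <- sprintf("%.4f", out[[nm]])
    }
  }
  ok <- tryCatch(suppressWarnings({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }), error = function(e) FALSE)
  if (!ok) .pm_stop(paste("cannot write", path), "pm_io_error")
  invisible(path)
}
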