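# Readers/writers for the tabular dialects the pipeline touches:
# MAGeCK-layout guide count matrices (TSV: guide, gene, samples), sample
# sheets (CSV), GMT gene-set collections, per-cell high-content tables (CSV).

#' Construct a guide count matrix
#'
#' @param counts Integer matrix, guides x samples, rownames = guide ids.
#' @param guide_to_gene Named character vector mapping guide id -> gene
#'   symbol, covering every row of `counts`.
#' @return An object of class `guide_counts`.
#' @export
guide_counts <- function(counts, guide_to_gene) {
  sk_assert(is.matrix(counts) && is.numeric(counts), "counts must be a numeric matrix")
  sk_assert(!is.null(rownames(counts)) && !is.null(colnames(counts)),
            "counts must have guide rownames and sample colnames")
  sk_assert(!anyDuplicated(rownames(counts)), "duplicate guide ids")
  sk_assert(!anyDuplicated(colnames(counts)), "duplicate sample names")
  sk_assert(all(is.finite(counts)) && all(counts >= 0) &&
              all(counts == floor(counts)),
            "counts must be non-negative integers")
  sk_assert(all(rownames(counts) %in% names(guide_to_gene)),
            "guide_to_gene must cover every guide")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 guide_to_gene = guide_to_gene[rownames(counts)]),
            class = "guide_counts")
}

#' @export
print.guide_counts <- function(x, ...) {
  cat(sprintf("Guide count matrix: %d guides, %d genes, %d samples\n",
              nrow(x$counts), length(unique(x$guide_to_gene)), ncol(x$counts)))
  invisible(x)
}

#' Read a guide count matrix (MAGeCK layout)
#'
#' Tab-separated with a header row; column 1 = guide id, column 2 = gene
#' symbol, remaining columns = integer counts per sample.
#'
#' @param path Path to the TSV file.
#' @return A `guide_counts` object.
#' @export
read_count_matrix <- function(path) {
  sk_assert(file.exists(path), sprintf("count matrix not found: %s", path))
  lines <- readLines(path)
  sk_assert(length(lines) >= 2L, "count matrix needs a header and >=1 guide row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sk_assert(length(header) >= 3L, "header must list guide, gene and >=1 sample")
  width <- length(header)
  for (i in seq_along(fields)[-1L]) {
    if (length(fields[[i]]) != width)
      stop(sprintf("malformed row at line %d: %d fields, expected %d",
                   i, length(fields[[i]]), width), call. = FALSE)
  }
  body <- do.call(rbind, fields[-1L])
  guides <- body[, 1L]
  dup <- guides[duplicated(guides)]
  sk_assert(length(dup) == 0L,
            sprintf("duplicate guide id(s): %s", paste(unique(dup), collapse = ", ")))
  raw <- body[, -(1:2), drop = FALSE]
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count '%s' at line %d, sample '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L] + 1L,
                 header[bad[1L, 2L] + 2L]), call. = FALSE)
  }
  dimnames(num) <- list(guides, header[-(1:2)])
  guide_counts(num, stats::setNames(body[, 2L], guides))
}

#' Write a guide count matrix in the MAGeCK layout
#'
#' @param x A `guide_counts` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  sk_assert(inherits(x, "guide_counts"), "not a guide_counts object")
  df <- data.frame(sgRNA = rownames(x$counts),
                   gene = unname(x$guide_to_gene),
                   x$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a sample sheet
#'
#' @param sample_id Character vector of unique sample ids.
#' @param cell_line Character vector.
#' @param arm One of "plasmid", "vehicle", "drug" per sample.
#' @param replicate Positive integer per sample.
#' @param drug_name Optional character (NA for plasmid/vehicle samples).
#' @return A data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, cell_line, arm, replicate,
                         drug_name = NA_character_) {
  sk_assert(!anyDuplicated(sample_id), "sample_ids must be unique")
  sk_assert(all(arm %in% c("plasmid", "vehicle", "drug")),
            "arm must be one of plasmid, vehicle, drug")
  sk_assert(all(replicate >= 1 & replicate == floor(replicate)),
            "replicate must be a positive integer")
  df <- data.frame(sample_id = as.character(sample_id),
                   cell_line = as.character(cell_line),
                   arm = as.character(arm),
                   replicate = as.integer(replicate),
                   drug_name = as.character(drug_name),
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet CSV
#' @param path CSV with columns sample_id, cell_line, arm, replicate and
#'   optionally drug_name.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  sk_assert(file.exists(path), sprintf("sample sheet not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "arm", "replicate")
  miss <- setdiff(need, names(df))
  sk_assert(length(miss) == 0L,
            sprintf("sample sheet missing column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(df$drug_name)) df$drug_name <- NA_character_
  sample_sheet(df$sample_id, df$cell_line, df$arm, df$replicate, df$drug_name)
}

#' Write a sample sheet CSV
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Check that a count matrix and sample sheet describe the same samples and
# that a drug-vs-vehicle comparison is possible.
validate_screen_inputs <- function(x, sheet) {
  sk_assert(inherits(x, "guide_counts"), "not a guide_counts object")
  cols <- colnames(x$counts)
  sk_assert(setequal(cols, sheet$sample_id) &&
              length(cols) == nrow(sheet),
            "count-matrix samples and sample sheet disagree")
  sk_assert(any(sheet$arm == "vehicle") && any(sheet$arm == "drug"),
            "need at least one vehicle and one drug sample")
  invisible(TRUE)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then member genes. Members are deduplicated; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of class `gene_sets`.
#' @export
read_gmt <- function(path) {
  sk_assert(file.exists(path), sprintf("GMT not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) < 3L)
      stop(sprintf("GMT line %d has %d fields; need name, description, >=1 gene",
                   i, length(fields[[i]])), call. = FALSE)
  }
  nms <- vapply(fields, `[[`, "", 1L)
  dup <- nms[duplicated(nms)]
  sk_assert(length(dup) == 0L,
            sprintf("duplicate gene-set name(s): %s", paste(unique(dup), collapse = ", ")))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  structure(sets, class = c("gene_sets", "list"))
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  sk_assert(length(names(sets)) == length(sets) && !anyDuplicated(names(sets)),
            "sets must be a uniquely named list")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(n, d, members) {
    paste(c(n, d, unique(members)), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-cell high-content table
#'
#' CSV with columns plate, well, perturbation, treatment, area, is_border and
#' per channel `nuclear_mean.<channel>` / `cytoplasm_mean.<channel>`.
#'
#' @param path CSV path.
#' @return A data.frame of cell records.
#' @export
read_cell_table <- function(path) {
  sk_assert(file.exists(path), sprintf("cell table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate", "well", "perturbation", "treatment", "area", "is_border")
  miss <- setdiff(need, names(df))
  sk_assert(length(miss) == 0L,
            sprintf("cell table missing column(s): %s", paste(miss, collapse = ", ")))
  sk_assert(any(grepl("^nuclear_mean\\.", names(df))) &&
              any(grepl("^cytoplasm_mean\\.", names(df))),
            "cell table needs nuclear_mean.<channel> and cytoplasm_mean.<channel> columns")
  df$is_border <- as.logical(df$is_border)
  df
}

#' Write a per-cell high-content table
#' @param cells Cell-record data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Channel names present in a cell table.
cell_channels <- function(cells) {
  sub("^nuclear_mean\\.", "", grep("^nuclear_mean\\.", names(cells), value = TRUE))
}
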