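#' Validate a genes x samples expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix with unique
#' gene ids as row names and unique sample ids as column names, holding
#' log-scale expression with no missing values.
#'
#' @param x numeric matrix with dimnames.
#' @return `x`, invisibly classed as `expression_matrix`.
#' @export
as_expression_matrix <- function(x) {
  assert_that(is.matrix(x) && is.numeric(x), "expression matrix must be a numeric matrix")
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "expression matrix needs gene ids (rownames) and sample ids (colnames)")
  assert_that(!anyNA(x), "expression matrix contains missing values")
  assert_that(!anyDuplicated(rownames(x)), "duplicate gene ids")
  assert_that(!anyDuplicated(colnames(x)), "duplicate sample ids")
  class(x) <- c("expression_matrix", class(x)[class(x) != "expression_matrix"])
  x
}

#' Read a genes x samples expression TSV
#'
#' First column holds gene ids, the header row holds sample ids, the body is
#' numeric. Duplicate gene rows (e.g. several probes mapping to one gene) are
#' collapsed by their mean, with a message naming how many were merged.
#'
#' @param path path to a tab-separated file.
#' @return an [as_expression_matrix()]-validated matrix.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  assert_that(ncol(df) >= 2L, "expression TSV needs a gene-id column plus samples")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  assert_that(!anyDuplicated(sample_ids),
              sprintf("duplicate sample id: %s",
                      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_(sprintf("non-numeric value at gene '%s', sample '%s'",
                  gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (anyDuplicated(gene_ids)) {
    n_dup <- sum(duplicated(gene_ids))
    message(sprintf("collapsing %d duplicate gene row(s) by mean", n_dup))
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }
  as_expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; round-trips values at full double
#' precision. A sidecar JSON (`<path>.json`) records the schema.
#'
#' @param x expression matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(format = "expression_tsv", genes = nrow(x), samples = ncol(x)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read gene genomic annotation
#'
#' Expects columns `gene_id`, `chromosome`, `start`, `end` (1-based inclusive;
#' only gene order within a chromosome is consumed downstream).
#'
#' @param path TSV path.
#' @return data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer", "integer"))
  names(df) <- c("gene_id", "chromosome", "start", "end")
  assert_that(!anyDuplicated(df$gene_id), "duplicate gene_id in annotation")
  assert_that(all(df$start <= df$end), "annotation has start > end")
  df
}

#' @rdname read_gene_annotation
#' @param annotation annotation data.frame.
#' @export
write_gene_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Empty lines are skipped.
#'
#' @param path GMT path.
#' @return named list of character vectors (set name -> member gene ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                    i, length(f)))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    assert_that(length(members) > 0L, sprintf("GMT line %d has no members", i))
    sets[[f[[1L]]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of member vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

stage_from_roman <- function(x) {
  # "IIIB" -> 3; leading roman numeral decides the ordinal stage
  roman <- regmatches(x, regexpr("^[IVXivx]+", x))
  out <- rep(NA_integer_, length(x))
  has <- lengths(regmatches(x, gregexpr("^[IVXivx]+", x))) > 0 & nzchar(x)
  out[has] <- suppressWarnings(as.integer(utils::as.roman(toupper(
    regmatches(x, regexpr("^[IVXivx]+", x))))))
  out
}

#' Read a clinical table
#'
#' Columns: `sample_id`, `os_time` (months), `os_event` (0/1), `age` (years),
#' `stage` (ordinal 1-4, roman numerals like "IIIB" accepted when
#' `roman_stage = TRUE`), `grade`, `debulking` (complete/incomplete),
#' `platinum_treated` (0/1). Values in `missing_codes` become `NA`; rows with
#' missing outcome are retained but flagged unusable for survival
#' (`surv_usable` column).
#'
#' @param path TSV path.
#' @param missing_codes character values treated as missing.
#' @param roman_stage map roman-numeral stages to 1-4.
#' @return data.frame of typed records.
#' @export
read_clinical <- function(path, missing_codes = c("", "NA", "unknown"),
                          roman_stage = TRUE) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("sample_id", "os_time", "os_event", "age", "stage")
  assert_that(all(need %in% names(df)),
              paste("clinical table missing column(s):",
                    paste(setdiff(need, names(df)), collapse = ", ")))
  df[df == "NA"] <- NA
  for (cc in missing_codes) df[!is.na(df) & df == cc] <- NA
  as_clinical(data.frame(
    sample_id = df$sample_id,
    os_time = suppressWarnings(as.numeric(df$os_time)),
    os_event = suppressWarnings(as.integer(df$os_event)),
    age = suppressWarnings(as.numeric(df$age)),
    stage = if (roman_stage && any(grepl("^[IVXivx]", df$stage))) {
      stage_from_roman(df$stage)
    } else suppressWarnings(as.integer(df$stage)),
    grade = if ("grade" %in% names(df)) suppressWarnings(as.integer(df$grade)) else NA_integer_,
    debulking = if ("debulking" %in% names(df)) df$debulking else NA_character_,
    platinum_treated = if ("platinum_treated" %in% names(df)) {
      suppressWarnings(as.integer(df$platinum_treated))
    } else NA_integer_,
    stringsAsFactors = FALSE))
}

#' Validate a clinical table
#'
#' @param df data.frame with at least sample_id, os_time, os_event.
#' @return the table with a `surv_usable` logical column appended.
#' @export
as_clinical <- function(df) {
  assert_that(!anyDuplicated(df$sample_id), "duplicate sample_id in clinical table")
  bad_t <- !is.na(df$os_time) & df$os_time <= 0
  assert_that(!any(bad_t),
              sprintf("os_time <= 0 for sample(s): %s",
                      paste(df$sample_id[bad_t], collapse = ", ")))
  assert_that(all(is.na(df$os_event) | df$os_event %in% c(0L, 1L)),
              "os_event must be 0/1")
  df$surv_usable <- !is.na(df$os_time) & !is.na(df$os_event)
  df
}

#' @rdname read_clinical
#' @param clinical clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  clinical$surv_usable <- NULL
  write.table(clinical, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a Visium-like spatial dataset
#'
#' Loads a MatrixMarket triple (`matrix.mtx`, `barcodes.tsv`, `features.tsv`)
#' plus a tissue-positions CSV (`barcode,in_tissue,array_row,array_col`).
#' Spots flagged out of tissue are dropped.
#'
#' @param matrix_dir directory containing the MTX triple.
#' @param positions_path tissue positions CSV.
#' @return list with `counts` (genes x spots integer matrix), `barcodes`,
#'   `gene_ids`, `positions` (data.frame barcode/array_row/array_col).
#' @export
read_visium <- function(matrix_dir, positions_path) {
  counts <- as.matrix(Matrix::readMM(file.path(matrix_dir, "matrix.mtx")))
  barcodes <- readLines(file.path(matrix_dir, "barcodes.tsv"))
  feat <- read.delim(file.path(matrix_dir, "features.tsv"), header = FALSE,
                     colClasses = "character")
  gene_ids <- feat[[1L]]
  assert_that(ncol(counts) == length(barcodes), "matrix columns != barcodes")
  assert_that(nrow(counts) == length(gene_ids), "matrix rows != features")
  pos <- utils::read.csv(positions_path, colClasses = c("character", "integer",
                                                        "integer", "integer"))
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col")
  missing <- setdiff(barcodes, pos$barcode)
  assert_that(length(missing) == 0L,
              paste("barcodes missing from positions:",
                    paste(missing, collapse = ", ")))
  keep <- barcodes %in% pos$barcode[pos$in_tissue == 1L]
  counts <- counts[, keep, drop = FALSE]
  barcodes <- barcodes[keep]
  dimnames(counts) <- list(gene_ids, barcodes)
  pos <- pos[match(barcodes, pos$barcode), c("barcode", "array_row", "array_col")]
  rownames(pos) <- NULL
  list(counts = counts, barcodes = barcodes, gene_ids = gene_ids, positions = pos)
}

#' Write a Visium-like spatial dataset
#'
#' Inverse of [read_visium()]; all files are plain text.
#'
#' @param sd spatial dataset list (see [read_visium()]).
#' @param matrix_dir output directory for the MTX triple.
#' @param positions_path output CSV.
#' @export
write_visium <- function(sd, matrix_dir, positions_path) {
  dir.create(matrix_dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(sd$counts, sparse = TRUE),
                  file.path(matrix_dir, "matrix.mtx"))
  writeLines(sd$barcodes, file.path(matrix_dir, "barcodes.tsv"))
  write.table(data.frame(sd$gene_ids, sd$gene_ids, "Gene Expression"),
              file.path(matrix_dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  pos <- data.frame(barcode = sd$positions$barcode, in_tissue = 1L,
                    array_row = sd$positions$array_row,
                    array_col = sd$positions$array_col)
  utils::write.csv(pos, positions_path, row.names = FALSE, quote = FALSE)
  invisible(matrix_dir)
}

#' Library-size normalize and log-transform spatial counts
#'
#' Each spot's counts are scaled to a fixed library size then log1p
#' transformed, so the output is invariant to per-spot sequencing depth.
#' All-zero spots are dropped with a warning.
#'
#' @param sd spatial dataset (see [read_visium()]).
#' @param library_size target total per spot (default 1e4).
#' @return genes x spots [as_expression_matrix()] matrix.
#' @export
normalize_counts <- function(sd, library_size = 1e4) {
  counts <- sd$counts
  assert_that(all(counts >= 0), "counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping %d all-zero spot(s)", sum(totals == 0)))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  out <- log1p(sweep(counts, 2L, totals / library_size, "/"))
  as_expression_matrix(out)
}
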