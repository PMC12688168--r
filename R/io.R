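#' Validate a raw count matrix
#'
#' Checks the invariants of the in-memory count container: unique gene and
#' sample ids, non-negative integer-valued counts, consistent dimensions.
#'
#' @param counts numeric matrix with gene rownames and sample colnames.
#' @return The matrix, invisibly, with storage mode integer.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames")
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate gene id(s): ",
                        paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stop("duplicate sample id(s): ",
                        paste(unique(dup), collapse = ", "))
  if (any(!is.finite(counts))) stop("non-finite count entries")
  if (any(counts < 0)) stop("negative count entries")
  if (any(counts != round(counts))) stop("non-integer count entries")
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a gene x sample count matrix
#'
#' `tsv` expects a header row of sample ids and gene ids in the first column.
#' `mtx` expects a MatrixMarket file with companion row (`<path>.genes.txt`)
#' and column (`<path>.samples.txt`) index files, one id per line.
#'
#' @param path file path (for `mtx`, the `.mtx` file).
#' @param format `"tsv"` or `"mtx"`.
#' @return Validated integer matrix, genes x samples, in file order.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
    dup <- unique(hdr[duplicated(hdr)])
    if (length(dup)) stop("duplicate sample id(s): ",
                          paste(dup, collapse = ", "))
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    colnames(m) <- hdr
  } else {
    mm <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes.txt"))
    smpls <- readLines(paste0(path, ".samples.txt"))
    m <- as.matrix(mm)
    dimnames(m) <- list(genes, smpls)
  }
  validate_count_matrix(m)
}

#' Write a count matrix
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (MatrixMarket plus `.genes.txt` /
#'   `.samples.txt` index files).
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- validate_count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".genes.txt"))
    writeLines(colnames(counts), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read / write the sample metadata table
#'
#' Columns: `sample_id`, `patient_id`, `timepoint` (one of `normal`, `pre`,
#' `post`), optional `cellularity` in `[0, 1]`. Each (patient, timepoint)
#' pair may appear at most once.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param samples sample table to write.
#' @export
write_sample_table <- function(samples, path) {
  validate_sample_table(samples)
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_table
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "patient_id", "timepoint")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(samples$timepoint), c("normal", "pre", "post"))
  if (length(bad)) stop("invalid timepoint value(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(samples$patient_id, samples$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicated (patient, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (!is.null(samples$cellularity)) {
    cc <- samples$cellularity
    if (any(cc < 0 | cc > 1, na.rm = TRUE)) stop("cellularity outside [0, 1]")
  }
  samples
}

#' Read / write the patient metadata table
#'
#' Columns: `patient_id`, `mp_score` (integer Miller-Payne grade 1-5),
#' optional `rcb_class`, `subtype`, `regimen`, `rfs_years`,
#' `recurrence_event`.
#'
#' @param path TSV path.
#' @return Validated data frame.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_patient_table(df)
}

#' @rdname read_patient_table
#' @param patients patient table to write.
#' @export
write_patient_table <- function(patients, path) {
  validate_patient_table(patients)
  utils::write.table(patients, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_patient_table
#' @export
validate_patient_table <- function(patients) {
  need <- c("patient_id", "mp_score")
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("patient table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(patients$patient_id)) stop("duplicate patient id")
  mp <- patients$mp_score
  if (any(!is.na(mp) & (mp < 1 | mp > 5 | mp != round(mp)))) {
    stop("mp_score must be an integer grade in 1..5")
  }
  if (!is.null(patients$rfs_years) &&
      any(patients$rfs_years < 0, na.rm = TRUE)) {
    stop("rfs_years must be non-negative")
  }
  patients
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are collapsed; lines with an empty gene list
#' are skipped with a warning.
#'
#' @param path GMT path.
#' @return Named list of gene-id character vectors, with a `description`
#'   attribute (named character vector).
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("PW1\tdesc\tA\tB\tC", f)
#' read_gmt(f)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      if (length(fields) == 2) {
        warning("GMT line ", i, " (", fields[1], ") has no genes; skipped")
        next
      }
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      warning("GMT line ", i, " (", fields[1], ") has no genes; skipped")
      next
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  if (anyDuplicated(names(sets))) stop("duplicate pathway id in GMT")
  attr(sets, "description") <- desc
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of gene-id vectors; an optional `description`
#'   attribute supplies the second field (defaults to `"NA"`).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[id] else "NA"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build the matched-triplet table
#'
#' Returns one row per patient possessing all three timepoints among the
#' columns of `counts`, with the sample ids of its normal, pre- and
#' posttreatment samples. Patients missing any timepoint are excluded and
#' reported in the `"excluded"` attribute (patient id plus missing
#' timepoints), mirroring the cohort funnel from enrolled patients down to
#' complete triplets.
#'
#' @param counts count matrix (defines which samples are available).
#' @param samples sample metadata table.
#' @return Data frame sorted by `patient_id` with columns `patient_id`,
#'   `normal`, `pre`, `post`; attribute `excluded` holds the side report.
#' @export
build_triplets <- function(counts, samples) {
  samples <- validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% colnames(counts), , drop = FALSE]
  patients <- sort(unique(samples$patient_id))
  rows <- list(); excl <- list()
  for (p in patients) {
    sub <- samples[samples$patient_id == p, , drop = FALSE]
    ids <- stats::setNames(sub$sample_id, sub$timepoint)
    missing <- setdiff(c("normal", "pre", "post"), names(ids))
    if (length(missing)) {
      excl[[p]] <- data.frame(patient_id = p,
                              missing = paste(missing, collapse = ","),
                              stringsAsFactors = FALSE)
    } else {
      rows[[p]] <- data.frame(patient_id = p, normal = ids[["normal"]],
                              pre = ids[["pre"]], post = ids[["post"]],
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), normal = character(),
               pre = character(), post = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = character(), missing = character(),
               stringsAsFactors = FALSE)
  if (nrow(attr(out, "excluded"))) {
    message(nrow(attr(out, "excluded")), " patient(s) lack a complete ",
            "triplet and were excluded; see attr(, 'excluded')")
  }
  out
}

#' Write ground truth (or any result list) as JSON
#' @param x list to serialize (matrices are written as nested arrays).
#' @param path output path.
#' @keywords internal
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       matrix = "rowmajor", force = TRUE)
  invisible(path)
}
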