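#' Read a labeled numeric matrix from TSV
#'
#' Expects a header of region/column ids and optional row names in the
#' first column; validates rectangularity, numeric cells, duplicates, and
#' (optionally) the expected shape. Region columns are canonicalized to
#' sorted id order so all modules operate on one ordering.
#'
#' @param path TSV file.
#' @param expected_shape optional `c(nrow, ncol)`.
#' @param canonicalize sort columns by id (default TRUE).
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, expected_shape = NULL, canonicalize = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  widths <- lengths(fields[-1])
  body_w <- unique(widths)
  if (length(body_w) != 1)
    stop(sprintf("ragged TSV %s: row %d has %d fields, expected %d",
                 path, which(widths != widths[1])[1] + 1L,
                 widths[widths != widths[1]][1], widths[1]))
  has_rownames <- body_w == length(header) + 1L ||
    (body_w == length(header) && header[1] %in% c("", "row", "id", "region_id"))
  dat <- utils::read.delim(path, check.names = FALSE,
                           row.names = if (has_rownames) 1L else NULL)
  M <- as.matrix(dat)
  if (!is.numeric(M)) {
    bad <- which(!vapply(dat, is.numeric, TRUE))[1]
    stop(sprintf("non-numeric cells in column '%s' of %s",
                 names(dat)[bad], path))
  }
  if (anyDuplicated(colnames(M)))
    stop("duplicate region ids in header of ", path)
  if (canonicalize && !is.null(colnames(M)))
    M <- M[, order(colnames(M)), drop = FALSE]
  if (!is.null(expected_shape) && !all(dim(M) == expected_shape))
    stop(sprintf("%s has shape %dx%d, expected %dx%d", path,
                 nrow(M), ncol(M), expected_shape[1], expected_shape[2]))
  M
}

#' Write a labeled numeric matrix as TSV
#' @param m matrix with column names.
#' @param path output file.
#' @param rownames include row names as a leading `id` column.
#' @export
write_matrix_tsv <- function(m, path, rownames = FALSE) {
  if (rownames) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' One TSV per scan (frames x regions, header = region ids) plus a JSON
#' manifest recording subject, condition, TR, seed, and the motion
#' covariates.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$scans, function(s) {
    f <- file.path(dir, paste0(s$scan_id, ".tsv"))
    write_matrix_tsv(s$values, f)
    list(scan_id = s$scan_id, subject_id = s$subject_id,
         condition = s$condition, tr_seconds = s$tr_seconds,
         file = basename(f))
  })
  manifest <- list(seed = cohort$spec$seed,
                   k_states = cohort$spec$k_states,
                   scans = unname(entries),
                   motion = cohort$motion)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing scan TSVs and `manifest.json`.
#' @return list with `scans` (list of [parc_ts()]) and `motion` data.frame.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  scans <- lapply(seq_len(nrow(manifest$scans)), function(i) {
    e <- manifest$scans[i, ]
    parc_ts(read_matrix_tsv(file.path(dir, e$file)),
            tr_seconds = e$tr_seconds, subject_id = e$subject_id,
            condition = e$condition, scan_id = e$scan_id)
  })
  names(scans) <- manifest$scans$scan_id
  list(scans = scans, motion = manifest$motion, seed = manifest$seed,
       k_states = manifest$k_states)
}
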