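#' Read an expression matrix
#'
#' Reads a genes x samples expression table from TSV/CSV (first column =
#' gene id, header = sample ids) or a MatrixMarket triplet (`.mtx` plus
#' `<stem>.genes.tsv` / `<stem>.samples.tsv` index files, one id per line).
#' Values must be non-negative; duplicated gene ids are collapsed by
#' per-sample maximum (with a message); gene and sample order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @return Numeric genes x samples matrix.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    genes <- readLines(paste0(stem, ".genes.tsv"))
    samples <- readLines(paste0(stem, ".samples.tsv"))
    if (length(genes) != nrow(m) || length(samples) != ncol(m))
      stop("MTX index files do not match matrix dimensions")
    dimnames(m) <- list(genes, samples)
  } else {
    sep <- if (format == "csv") "," else "\t"
    hdr <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]][-1]
    if (anyDuplicated(hdr))                    # read.table would uniquify them
      stop("duplicated sample ids: ",
           paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 2,
                         function(v) any(is.na(suppressWarnings(as.numeric(v))))))
      stop("non-numeric expression values in column(s): ",
           paste(names(bad), collapse = ", "))
    }
    rownames(m) <- genes
  }
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", rownames(m)[idx[1]],
         "', sample '", colnames(m)[idx[2]], "'")
  }
  if (anyDuplicated(rownames(m))) {
    message("collapsing ", sum(duplicated(rownames(m))),
            " duplicated gene id(s) by per-sample maximum")
    keep_order <- unique(rownames(m))
    m <- do.call(rbind, lapply(keep_order, function(g) {
      apply(m[rownames(m) == g, , drop = FALSE], 2, max)
    }))
    rownames(m) <- keep_order
  }
  m
}

#' Write an expression matrix as TSV
#'
#' Genes x samples, first column `gene`.
#'
#' @param m genes x samples matrix.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `patient_id`, `tissue` (tumor/normal).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  meta
}

#' Read per-sample somatic variants (long-form TSV)
#'
#' Columns `sample_id`, `chrom`, `pos`, `ref`, `alt`; variants are
#' canonicalized as `chrom:pos:ref:alt` keys.
#'
#' @param path file path.
#' @return Named list of variant-key character vectors, one per sample.
#' @export
read_variants <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variant table must have columns: ", paste(need, collapse = ", "))
  keys <- sprintf("%s:%s:%s:%s", v$chrom, v$pos, v$ref, v$alt)
  split(keys, v$sample_id)
}

#' Read a patient survival table
#'
#' TSV with columns `patient_id`, `time` (> 0), `event` (0/1).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  if (!all(need %in% names(s)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (any(s$time <= 0)) stop("survival times must be > 0")
  if (!all(s$event %in% c(0, 1))) stop("events must be 0/1")
  s
}

#' Validate a cohort bundle
#'
#' Cross-checks expression, metadata and (optionally) coordinates, variants
#' and survival: every expression sample needs metadata; tissue labels must
#' be tumor/normal; when spatial analyses are requested every tumor sample
#' needs coordinates; patients with fewer than 3 regions draw a warning
#' (reliable ITH estimation needs at least three). Hard failures are
#' reported as errors, soft issues as warnings; both are enumerated.
#'
#' @param expr genes x samples matrix.
#' @param meta sample metadata.
#' @param coords optional coordinate table.
#' @param variants optional per-sample variant list.
#' @param survival optional survival table.
#' @param spatial whether spatial analyses are requested (coordinates then
#'   mandatory for all tumor samples).
#' @return List `errors`, `warnings` (character vectors; both empty for a
#'   consistent bundle).
#' @export
validate_bundle <- function(expr, meta, coords = NULL, variants = NULL,
                            survival = NULL, spatial = !is.null(coords)) {
  errors <- character(0); warnings <- character(0)
  miss_meta <- setdiff(colnames(expr), meta$sample_id)
  if (length(miss_meta))
    errors <- c(errors, paste0("samples without metadata: ",
                               paste(miss_meta, collapse = ", ")))
  bad_tissue <- setdiff(unique(meta$tissue), c("tumor", "normal"))
  if (length(bad_tissue))
    errors <- c(errors, paste0("unknown tissue label(s): ",
                               paste(bad_tissue, collapse = ", ")))
  tum <- meta$sample_id[meta$tissue == "tumor"]
  if (spatial) {
    if (is.null(coords)) {
      errors <- c(errors, "spatial analyses requested but no coordinates")
    } else {
      miss_co <- setdiff(intersect(tum, colnames(expr)), coords$sample_id)
      if (length(miss_co))
        errors <- c(errors, paste0("tumor samples without coordinates: ",
                                   paste(miss_co, collapse = ", ")))
    }
  }
  counts <- table(meta$patient_id[meta$tissue == "tumor"])
  few <- names(counts)[counts < 3]
  if (length(few))
    warnings <- c(warnings,
                  paste0("patients with < 3 regions (ITH estimates may be ",
                         "unreliable): ", paste(few, collapse = ", ")))
  if (!is.null(survival)) {
    miss_surv <- setdiff(unique(meta$patient_id[meta$tissue == "tumor"]),
                         survival$patient_id)
    if (length(miss_surv))
      warnings <- c(warnings, paste0("patients without survival: ",
                                     paste(miss_surv, collapse = ", ")))
  }
  if (!is.null(variants)) {
    extra <- setdiff(names(variants), meta$sample_id)
    if (length(extra))
      warnings <- c(warnings, paste0("variant sets for unknown samples: ",
                                     paste(extra, collapse = ", ")))
  }
  list(errors = errors, warnings = warnings)
}
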