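#' Read a sampling-coordinate table
#'
#' Expects a TSV with columns `sample_id`, `x_cm`, `y_cm` (a `patient_id`
#' column is kept when present, otherwise joined from `meta`). Coordinates
#' are in cm; non-numeric or missing coordinates are rejected, never
#' coerced.
#'
#' @param path path to the TSV file.
#' @param meta optional sample metadata (`sample_id`, `patient_id`) to join.
#' @return Data frame `sample_id`, `patient_id` (if available), `x_cm`,
#'   `y_cm`.
#' @export
read_coordinates <- function(path, meta = NULL) {
  co <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "x_cm", "y_cm")
  if (!all(need %in% names(co)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  for (cl in c("x_cm", "y_cm")) {
    v <- suppressWarnings(as.numeric(co[[cl]]))
    bad <- is.na(v) & !is.na(co[[cl]])
    if (any(bad) || anyNA(co[[cl]]))
      stop("non-numeric or missing '", cl, "' for sample(s): ",
           paste(co$sample_id[bad | is.na(co[[cl]])], collapse = ", "))
    co[[cl]] <- v
  }
  if (anyDuplicated(co$sample_id))
    stop("duplicated sample_id in coordinate table")
  if (!is.null(meta) && !"patient_id" %in% names(co)) {
    idx <- match(co$sample_id, meta$sample_id)
    co$patient_id <- meta$patient_id[idx]
  }
  co
}

coords_for_patient <- function(coords, patient) {
  if (!"patient_id" %in% names(coords))
    stop("coordinates carry no patient_id; join metadata first")
  sub <- coords[coords$patient_id == patient, , drop = FALSE]
  if (nrow(sub) < 2)
    stop("patient '", patient, "' has fewer than 2 samples with coordinates")
  if (anyNA(sub$x_cm) || anyNA(sub$y_cm))
    stop("missing coordinates for sample(s): ",
         paste(sub$sample_id[is.na(sub$x_cm) | is.na(sub$y_cm)],
               collapse = ", "))
  sub
}

#' Pairwise physical distances within a tumor
#'
#' Euclidean distances (cm) between the 2D sampling sites of one patient's
#' regions, computed directly from the recorded coordinates.
#'
#' @param coords coordinate table with `sample_id`, `patient_id`, `x_cm`,
#'   `y_cm`.
#' @param patient patient identifier.
#' @return Symmetric matrix (cm) with zero diagonal, dimnames = sample ids.
#' @export
pairwise_physical_distance <- function(coords, patient) {
  sub <- coords_for_patient(coords, patient)
  d <- as.matrix(stats::dist(sub[, c("x_cm", "y_cm")]))
  dimnames(d) <- list(sub$sample_id, sub$sample_id)
  d
}

#' Physical diversity of a tumor's sampling sites
#'
#' Mean Euclidean distance (cm) from each sampling point to the arithmetic
#' centroid of the tumor's points. Larger values indicate more dispersed
#' sampling; used as the denominator of the normalized diversity score.
#'
#' @inheritParams pairwise_physical_distance
#' @return Non-negative scalar, cm.
#' @export
physical_diversity <- function(coords, patient) {
  sub <- coords_for_patient(coords, patient)
  xy <- as.matrix(sub[, c("x_cm", "y_cm")])
  ctr <- colMeans(xy)
  mean(sqrt(rowSums(sweep(xy, 2, ctr)^2)))
}

#' Pooled within-tumor pairwise distance summary
#'
#' Concatenates every tumor's pairwise sampling-site distances (within-tumor
#' pairs only; coordinate frames are not comparable between tumors) and
#' summarizes them.
#'
#' @param coords coordinate table covering >= 1 patient with >= 2 samples.
#' @return List with `distances` (all pooled pairwise distances, cm),
#'   `median`, `min`, `max` and `n_pairs`.
#' @export
pooled_distance_summary <- function(coords) {
  patients <- unique(coords$patient_id)
  dd <- unlist(lapply(patients, function(p) {
    sub <- coords[coords$patient_id == p, , drop = FALSE]
    if (nrow(sub) < 2) return(numeric(0))
    as.numeric(stats::dist(sub[, c("x_cm", "y_cm")]))
  }))
  if (!length(dd)) stop("no patient has >= 2 samples with coordinates")
  list(distances = dd, median = stats::median(dd),
       min = min(dd), max = max(dd), n_pairs = length(dd))
}
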