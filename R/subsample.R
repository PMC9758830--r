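#' Enumerate all k-subsets of m regions
#'
#' Exhaustive, deterministic lexicographic enumeration.
#'
#' @param m number of regions (>= k).
#' @param k subset size (2 <= k <= m).
#' @return k x C(m, k) integer matrix, one subset per column.
#' @export
enumerate_subsets <- function(m, k) {
  if (k < 2) stop("subset size k must be >= 2")
  if (k > m) stop("subset size k must be <= m")
  utils::combn(m, k)
}

#' Coefficient of variation
#'
#' Population (1/N) standard deviation of subsampled diversity scores
#' divided by their mean: a measure of how much the score varies across
#' sampling combinations (representativeness).
#'
#' @param x numeric scores (N >= 2, mean != 0).
#' @return Non-negative scalar.
#' @export
cv <- function(x) {
  if (length(x) < 2) stop("need >= 2 scores")
  mu <- mean(x)
  if (mu == 0) stop("mean of scores is zero; CV undefined")
  sqrt(mean((x - mu)^2)) / mu
}

#' Coefficient of deviation from the gold standard
#'
#' Root-mean-square deviation of subsampled scores from the all-region
#' "gold standard" score alpha, divided by the mean of the scores: a
#' measure of accuracy. Equals [cv()] when `alpha == mean(x)`.
#'
#' @param x numeric scores (N >= 2, mean != 0).
#' @param alpha gold-standard score computed from all regions.
#' @return Non-negative scalar.
#' @export
cd <- function(x, alpha) {
  if (length(x) < 2) stop("need >= 2 scores")
  mu <- mean(x)
  if (mu == 0) stop("mean of scores is zero; CD undefined")
  sqrt(mean((x - alpha)^2)) / mu
}

#' Subsampling experiment for one tumor
#'
#' For each subsample size k, recomputes the raw (Div(t)) and normalized
#' (Div(t)/Div(p)) diversity scores over every k-subset of the tumor's
#' regions and summarizes their dispersion (CV) and deviation from the
#' all-region gold standard (CD). The PCA basis is fit once on the full
#' cohort and held fixed across subsets, so only the within-tumor mean and
#' membership change; the gold standard uses all m regions on the same
#' basis.
#'
#' @param emb full-cohort [fit_pca()] embedding with patient labels.
#' @param coords coordinate table covering the tumor's regions.
#' @param patient patient identifier with m >= max(k_range) regions.
#' @param k_range integer vector of subsample sizes (default `2:(m-1)`).
#' @param max_exhaustive enumerate exhaustively while `choose(m, k)` is at
#'   most this cap, otherwise draw `n_random` seeded distinct subsets.
#' @param n_random number of random subsets beyond the cap.
#' @param seed seed for random mode.
#' @return Data frame, one row per k: `k`, `n_combos`, `cv_raw`, `cv_norm`,
#'   `cd_raw`, `cd_norm`, `alpha_raw`, `alpha_norm`; per-subset scores in
#'   attribute `"scores"` (list by k).
#' @export
subsample_experiment <- function(emb, coords, patient, k_range = NULL,
                                 max_exhaustive = 5000, n_random = 1000,
                                 seed = 1) {
  x <- embedding_block(emb, patient)
  sub <- coords_for_patient(coords, patient)
  ids <- rownames(x)
  sub <- sub[match(ids, sub$sample_id), , drop = FALSE]
  if (anyNA(sub$x_cm))
    stop("missing coordinates for region(s) of patient '", patient, "'")
  xy <- as.matrix(sub[, c("x_cm", "y_cm")])
  m <- nrow(x)
  if (is.null(k_range)) k_range <- 2:(m - 1)
  if (max(k_range) > m) stop("k exceeds the number of regions (", m, ")")

  div_p_of <- function(rows) {
    p <- xy[rows, , drop = FALSE]
    mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  }
  div_t_of <- function(rows) div_t_from_scores(x[rows, , drop = FALSE])

  alpha_raw <- div_t_of(seq_len(m))
  alpha_norm <- alpha_raw / div_p_of(seq_len(m))

  score_list <- list()
  rows <- lapply(k_range, function(k) {
    nc <- choose(m, k)
    if (nc <= max_exhaustive) {
      subsets <- enumerate_subsets(m, k)
    } else {
      set.seed(seed + k)
      seen <- character(0)
      subsets <- matrix(0L, k, 0)
      while (ncol(subsets) < n_random) {
        cand <- sort(sample.int(m, k))
        key <- paste(cand, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          subsets <- cbind(subsets, cand)
        }
      }
    }
    raw <- apply(subsets, 2, div_t_of)
    dp <- apply(subsets, 2, div_p_of)
    if (any(dp == 0))
      stop("a subset has coincident sampling points (Div(p) = 0)")
    norm <- raw / dp
    score_list[[as.character(k)]] <<- data.frame(raw = raw, norm = norm)
    # k = m gives the single all-region subset: CV is undefined (one score)
    # and CD measures that subset against itself, so it is exactly 0.
    one <- length(raw) < 2
    rms_cd <- function(s, a) sqrt(mean((s - a)^2)) / mean(s)
    data.frame(k = k, n_combos = ncol(subsets),
               cv_raw = if (one) NA_real_ else cv(raw),
               cv_norm = if (one) NA_real_ else cv(norm),
               cd_raw = if (one) rms_cd(raw, alpha_raw) else cd(raw, alpha_raw),
               cd_norm = if (one) rms_cd(norm, alpha_norm) else cd(norm, alpha_norm),
               alpha_raw = alpha_raw, alpha_norm = alpha_norm)
  })
  out <- do.call(rbind, rows)
  attr(out, "scores") <- score_list
  out
}
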