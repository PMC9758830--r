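#' PCA embedding of tumor expression profiles
#'
#' Fits a principal component analysis jointly on all tumor samples of a
#' cohort and returns per-sample scores on the first `n_pcs` components
#' (ranked by eigenvalue). By default the expression matrix is transformed
#' to `log2(TPM + 1)`, genes with TPM >= 1 in fewer than 20% of tumor
#' samples are dropped, and genes are centered (no scaling) before the
#' decomposition.
#'
#' @param expr genes x samples non-negative expression matrix (TPM scale
#'   under the default transform).
#' @param meta sample metadata with `sample_id`, `patient_id`, `tissue`;
#'   only `tissue == "tumor"` samples enter the fit. `NULL` treats every
#'   column as a tumor sample (a `patient_id` is then required at scoring
#'   time).
#' @param n_pcs number of components to keep (default 15); clipped with a
#'   warning when the cohort is too small.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @param min_tpm,min_frac gene filter: keep genes with expression >=
#'   `min_tpm` in at least `min_frac` of tumor samples. Set `min_frac = 0`
#'   to disable.
#' @return A `pca_embedding`: list with `scores` (samples x n_pcs matrix),
#'   `explained` (variance per component, non-increasing), `patient`
#'   (per-row patient id), `n_pcs`, `genes` (genes used).
#' @export
fit_pca <- function(expr, meta = NULL, n_pcs = 15, transform = c("log2p1", "none"),
                    min_tpm = 1, min_frac = 0.2) {
  transform <- match.arg(transform)
  if (is.null(meta)) {
    samples <- colnames(expr)
    patient <- NULL
  } else {
    tum <- meta$sample_id[meta$tissue == "tumor"]
    samples <- intersect(colnames(expr), tum)
    patient <- meta$patient_id[match(samples, meta$sample_id)]
  }
  x <- expr[, samples, drop = FALSE]
  if (min_frac > 0) {
    keep <- rowMeans(x >= min_tpm) >= min_frac
    x <- x[keep, , drop = FALSE]
  }
  if (transform == "log2p1") x <- log2(x + 1)
  n <- ncol(x)
  max_pcs <- min(n - 1L, nrow(x))
  if (n_pcs > max_pcs) {
    if (max_pcs < 1)
      stop("need at least ", n_pcs + 1, " tumor samples; got ", n,
           " - reduce 'n_pcs'")
    warning("n_pcs reduced from ", n_pcs, " to ", max_pcs,
            " (cohort has ", n, " tumor samples)")
    n_pcs <- max_pcs
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  structure(list(scores = scores,
                 explained = pc$sdev[seq_len(n_pcs)]^2,
                 patient = patient,
                 n_pcs = n_pcs,
                 genes = rownames(x)),
            class = "pca_embedding")
}

embedding_block <- function(emb, patient, samples = NULL) {
  stopifnot(inherits(emb, "pca_embedding"))
  if (is.null(emb$patient))
    stop("embedding carries no patient labels; fit with metadata")
  sel <- emb$patient == patient
  x <- emb$scores[sel, , drop = FALSE]
  if (!is.null(samples)) x <- x[samples, , drop = FALSE]
  x
}

div_t_from_scores <- function(x) {
  mu <- colMeans(x)
  mean(sqrt(rowSums(sweep(x, 2, mu)^2)))
}

#' Transcriptomic diversity of a tumor
#'
#' Patient-wise ITH score: the mean Euclidean distance of a tumor's
#' multi-region PC-score vectors to their arithmetic mean,
#' \deqn{Div(t) = \frac{1}{m} \sum_{i=1}^{m}
#'   \sqrt{\sum_{j=1}^{n} (x_{ij} - \mu_j)^2}.}
#' Higher values indicate greater patient-wise transcriptomic ITH.
#'
#' @param emb a [fit_pca()] embedding carrying patient labels.
#' @param patient patient identifier with m >= 2 regions in the embedding.
#' @return Non-negative scalar in PC-space units.
#' @export
transcriptomic_diversity <- function(emb, patient) {
  x <- embedding_block(emb, patient)
  if (nrow(x) < 2)
    stop("patient '", patient, "' has fewer than 2 regions in the embedding")
  div_t_from_scores(x)
}

#' Pairwise transcriptomic distance between two profiles
#'
#' `1 - Spearman rank correlation` between two expression profiles on a
#' shared gene set (average ranks for ties), computed on
#' `log2(TPM + 1)`-transformed values by default.
#'
#' @param a,b numeric expression profiles over the same genes (>= 3 genes).
#' @param transform `"log2p1"` or `"none"`.
#' @return Distance in \[0, 2\].
#' @export
transcriptomic_distance <- function(a, b, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (length(a) != length(b) || length(a) < 3)
    stop("profiles must share >= 3 genes")
  if (transform == "log2p1") { a <- log2(a + 1); b <- log2(b + 1) }
  if (stats::sd(rank(a)) == 0 || stats::sd(rank(b)) == 0)
    stop("constant profile: Spearman correlation undefined")
  1 - stats::cor(a, b, method = "spearman")
}

#' Pairwise transcriptomic distance matrix within a tumor
#'
#' @param expr genes x samples expression matrix (TPM scale).
#' @param samples sample ids of the tumor's regions (>= 2).
#' @inheritParams transcriptomic_distance
#' @return Symmetric distance matrix over `samples`.
#' @export
pairwise_transcriptomic_distance <- function(expr, samples,
                                             transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  x <- expr[, samples, drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  rho <- stats::cor(x, method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Jaccard genomic distance between two variant sets
#'
#' `1 - |A intersect B| / |A union B|` over canonical `chrom:pos:ref:alt`
#' variant keys. Two empty sets give 0 with a warning.
#'
#' @param a,b character vectors of variant keys.
#' @return Distance in \[0, 1\].
#' @export
genomic_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both variant sets empty; distance defined as 0")
    return(0)
  }
  1 - length(intersect(a, b)) / u
}

#' Pairwise genomic distance matrix within a tumor
#'
#' @param variants named list of variant-key sets (one per region, >= 2).
#' @return Symmetric Jaccard distance matrix.
#' @export
pairwise_genomic_distance <- function(variants) {
  m <- length(variants)
  if (m < 2) stop("need >= 2 regions with variant sets")
  d <- matrix(0, m, m, dimnames = list(names(variants), names(variants)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    d[i, j] <- d[j, i] <- genomic_distance(variants[[i]], variants[[j]])
  d
}

#' Genomic diversity of a tumor
#'
#' Median of all within-tumor pairwise Jaccard distances.
#'
#' @param variants named list of per-region variant-key sets (>= 2 regions).
#' @return Scalar in \[0, 1\].
#' @export
genomic_diversity <- function(variants) {
  d <- pairwise_genomic_distance(variants)
  stats::median(d[upper.tri(d)])
}

#' Correlation between physical and molecular distance
#'
#' Spearman rank correlation between matched within-tumor pairwise physical
#' and molecular (transcriptomic or genomic) distances, either separately
#' per tumor or pooled across tumors (within-tumor pairs only; pairs are
#' never formed between tumors).
#'
#' @param phys named list of per-tumor physical distance matrices.
#' @param mol named list of per-tumor molecular distance matrices with
#'   matching dimnames.
#' @param scope `"per-tumor"` or `"pooled"`.
#' @param strong_cutoff per-tumor rho above which the trend is flagged
#'   strong (default 0.30).
#' @return For `"per-tumor"`: data frame `patient_id`, `n_pairs`, `rho`,
#'   `p`, `strong_trend` (rho is `NA` below 3 pairs). For `"pooled"`: list
#'   with `rho`, `p`, `n_pairs`.
#' @export
distance_correlation <- function(phys, mol, scope = c("per-tumor", "pooled"),
                                 strong_cutoff = 0.30) {
  scope <- match.arg(scope)
  stopifnot(identical(names(phys), names(mol)))
  pairs <- lapply(names(phys), function(p) {
    dp <- phys[[p]]; dm <- mol[[p]]
    stopifnot(identical(dimnames(dp)[[1]], dimnames(dm)[[1]]))
    ut <- upper.tri(dp)
    data.frame(patient_id = p, phys = dp[ut], mol = dm[ut],
               stringsAsFactors = FALSE)
  })
  if (scope == "pooled") {
    all <- do.call(rbind, pairs)
    ct <- suppressWarnings(
      stats::cor.test(all$phys, all$mol, method = "spearman"))
    return(list(rho = unname(ct$estimate), p = ct$p.value,
                n_pairs = nrow(all)))
  }
  out <- lapply(pairs, function(df) {
    n <- nrow(df)
    if (n < 3)
      return(data.frame(patient_id = df$patient_id[1], n_pairs = n,
                        rho = NA_real_, p = NA_real_, strong_trend = NA,
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(df$phys, df$mol, method = "spearman"))
    data.frame(patient_id = df$patient_id[1], n_pairs = n,
               rho = unname(ct$estimate), p = ct$p.value,
               strong_trend = unname(ct$estimate) > strong_cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalized diversity score
#'
#' `Div(t) / Div(p)`: transcriptomic diversity divided by the physical
#' dispersion of the sampling sites, removing sampling-location bias from
#' the patient-wise ITH estimate. Higher normalized scores indicate greater
#' patient-wise ITH.
#'
#' @param div_t transcriptomic diversity (>= 0).
#' @param div_p physical diversity, cm (> 0).
#' @return Scalar, units 1/cm of PC-space distance.
#' @export
normalized_diversity <- function(div_t, div_p) {
  if (any(div_p <= 0))
    stop("physical diversity must be > 0 (coincident sampling points?)")
  div_t / div_p
}

#' Patient-wise diversity table for a cohort
#'
#' Convenience wrapper: fits (or reuses) the cohort PCA, then computes
#' Div(t), Div(p), the normalized score, optional genomic diversity, and the
#' median-split ITH class for every patient with >= 2 regions.
#'
#' @param expr genes x samples TPM matrix.
#' @param meta sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @param coords coordinate table.
#' @param variants optional named list of per-sample variant sets.
#' @param emb optional pre-fit [fit_pca()] embedding.
#' @param ... passed to [fit_pca()].
#' @return Data frame `patient_id`, `m`, `div_t`, `div_p`, `normalized`,
#'   `genomic_div`, `ith_class`.
#' @export
diversity_scores <- function(expr, meta, coords, variants = NULL,
                             emb = NULL, ...) {
  if (is.null(emb)) emb <- fit_pca(expr, meta, ...)
  if (!"patient_id" %in% names(coords))
    coords$patient_id <- meta$patient_id[match(coords$sample_id,
                                               meta$sample_id)]
  patients <- unique(emb$patient)
  patients <- patients[vapply(patients, function(p)
    sum(emb$patient == p) >= 2, logical(1))]
  div_t <- vapply(patients, function(p) transcriptomic_diversity(emb, p),
                  numeric(1))
  div_p <- vapply(patients, function(p) physical_diversity(coords, p),
                  numeric(1))
  gdiv <- rep(NA_real_, length(patients))
  if (!is.null(variants)) {
    gdiv <- vapply(patients, function(p) {
      ids <- meta$sample_id[meta$patient_id == p & meta$tissue == "tumor"]
      ids <- intersect(ids, names(variants))
      if (length(ids) < 2) return(NA_real_)
      genomic_diversity(variants[ids])
    }, numeric(1))
  }
  norm <- normalized_diversity(div_t, div_p)
  data.frame(patient_id = patients,
             m = vapply(patients, function(p) sum(emb$patient == p),
                        integer(1)),
             div_t = div_t, div_p = div_p, normalized = norm,
             genomic_div = gdiv,
             ith_class = classify_ith(norm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-split ITH classification
#'
#' Assigns each patient to the low- or high-ITH class by the cohort median
#' of the scores. Scores strictly above the median are `"high"`; scores at
#' or below it are `"low"` (documented tie rule).
#'
#' @param scores numeric vector of per-patient scores (>= 2).
#' @return Character vector `"low"` / `"high"` aligned with `scores`.
#' @export
classify_ith <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 patients to classify")
  med <- stats::median(scores)
  if (all(scores == scores[1])) {
    warning("all scores identical; every patient classified low")
    return(rep("low", length(scores)))
  }
  ifelse(scores > med, "high", "low")
}

#' Per-tumor concordance classification of region-level scores
#'
#' Splits all region-level scores at the cohort median; a tumor whose
#' regions all fall below (above) the split is uniformly low (high), and a
#' tumor with regions on both sides is discordant.
#'
#' @param scores numeric vector of per-sample scores.
#' @param patients patient label per sample.
#' @return List with `classes` (data frame `patient_id`, `class` in
#'   `uniformly_low` / `uniformly_high` / `discordant`) and
#'   `discordant_prop`.
#' @export
concordance_classify <- function(scores, patients) {
  stopifnot(length(scores) == length(patients))
  lab <- ifelse(scores > stats::median(scores), "high", "low")
  cls <- vapply(split(lab, patients), function(v) {
    if (all(v == "low")) "uniformly_low"
    else if (all(v == "high")) "uniformly_high"
    else "discordant"
  }, "")
  list(classes = data.frame(patient_id = names(cls), class = unname(cls),
                            stringsAsFactors = FALSE),
       discordant_prop = mean(cls == "discordant"))
}
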