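#' Intra-tumor variability score (ITVS)
#'
#' Decomposes a per-sample feature into within-tumor variance W and
#' between-patient variance B with a random-intercept model
#' `value ~ 1 + (1 | patient)` fit by REML, and returns
#' \deqn{ITVS = W / (W + B).}
#' Lower ITVS means lower gene-wise ITH. Patients with a single sample are
#' dropped. When the mixed-model fit fails, a balanced one-way ANOVA
#' method-of-moments estimator is used instead
#' (`B = max(0, (MSB - MSW)/n0)`, `W = MSW`) and flagged.
#'
#' @param values numeric feature values, one per sample.
#' @param patients patient label per sample (>= 2 patients with >= 2
#'   samples each).
#' @param method `"reml"` (default) or `"moments"`.
#' @return List `W`, `B`, `itvs` (NA when total variance is 0), `method`
#'   (estimator actually used).
#' @export
itvs <- function(values, patients, method = c("reml", "moments")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(patients))
  ok <- is.finite(values)
  if (!all(ok)) stop("non-finite feature values")
  keep <- patients %in% names(which(table(patients) >= 2))
  values <- values[keep]; patients <- patients[keep]
  if (length(unique(patients)) < 2)
    stop("need >= 2 patients with >= 2 samples each")
  if (stats::var(values) == 0)
    return(list(W = 0, B = 0, itvs = NA_real_, method = "degenerate"))

  mom <- function() {
    n_i <- table(patients)
    N <- length(values); P <- length(n_i)
    gm <- mean(values)
    means <- tapply(values, patients, mean)
    ssw <- sum((values - means[patients])^2)
    msw <- ssw / (N - P)
    msb <- sum(n_i * (means - gm)^2) / (P - 1)
    n0 <- (N - sum(n_i^2) / N) / (P - 1)
    W <- msw
    B <- max(0, (msb - msw) / n0)
    list(W = W, B = B, method = "moments")
  }

  est <- if (method == "moments") mom() else tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(v ~ 1 + (1 | p),
                 data = data.frame(v = values, p = patients),
                 REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    list(W = vc$vcov[vc$grp == "Residual"],
         B = vc$vcov[vc$grp == "p"],
         method = "reml")
  }, error = function(e) mom())

  tot <- est$W + est$B
  list(W = max(0, est$W), B = max(0, est$B),
       itvs = if (tot > 0) max(0, est$W) / tot else NA_real_,
       method = est$method)
}

#' Patient group overall ratio (PGOR) curve
#'
#' Clusters samples by hierarchical agglomerative clustering (complete
#' linkage, Euclidean dissimilarity; absolute difference for a single
#' feature, Euclidean distance on per-feature z-scored columns for a
#' multi-feature signature) and, for each cut into k = 1..P clusters,
#' reports the fraction of patients whose samples all share one cluster
#' label. A feature/signature with low ITH co-clusters each patient's
#' samples, giving a high curve. Patients with a single sample are excluded
#' (numerator and denominator) with a warning.
#'
#' @param x numeric vector (single feature per sample) or samples x features
#'   matrix.
#' @param patients patient label per sample.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return Numeric vector `pgor` of length P (number of retained patients),
#'   with `pgor[1] == 1`; attribute `"P"` carries P.
#' @export
pgor_curve <- function(x, patients, linkage = "complete") {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    stopifnot(nrow(x) == length(patients))
  } else {
    stopifnot(length(x) == length(patients))
    x <- matrix(x, ncol = 1)
  }
  keep <- patients %in% names(which(table(patients) >= 2))
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) from single-sample patients excluded",
            " from PGOR")
    x <- x[keep, , drop = FALSE]
    patients <- patients[keep]
  }
  P <- length(unique(patients))
  if (P < 2) stop("need >= 2 patients with >= 2 samples")
  if (ncol(x) > 1) {
    x <- scale(x)
    x[is.nan(x)] <- 0     # constant feature columns carry no signal
  }
  hc <- stats::hclust(stats::dist(x), method = linkage)
  pg <- vapply(seq_len(P), function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(vapply(split(cl, patients),
                function(v) length(unique(v)) == 1L, logical(1)))
  }, numeric(1))
  attr(pg, "P") <- P
  pg
}

# Trapezoidal integral over unit steps in k.
trapezoid_auc <- function(y) sum((y[-1] + y[-length(y)]) / 2)

#' Clustering concordance score (CCS)
#'
#' \deqn{CCS = 1 - AUC(PGOR) / (P - 1)} with the area under the PGOR curve
#' obtained by trapezoidal integration over unit steps in the cluster count
#' k. CCS is 0 exactly when the curve is identically 1 (every patient's
#' samples co-cluster at every cut level).
#'
#' @param pgor PGOR vector over k = 1..P.
#' @param P number of patients (defaults to `length(pgor)`).
#' @return List `auc`, `ccs` (in \[0, 1\]).
#' @export
ccs <- function(pgor, P = length(pgor)) {
  if (P < 2) stop("need >= 2 patients")
  stopifnot(length(pgor) == P)
  auc <- trapezoid_auc(pgor)
  list(auc = auc, ccs = 1 - auc / (P - 1))
}

#' Integrated heterogeneity score (IHS)
#'
#' Geometric mean of ITVS and CCS; ranges 0 to 1, low values meaning low
#' gene-wise (feature-wise) ITH.
#'
#' @param itvs,ccs component scores in \[0, 1\].
#' @return `sqrt(itvs * ccs)`.
#' @export
ihs <- function(itvs, ccs) {
  if (any(!is.na(itvs) & (itvs < 0 | itvs > 1)) ||
      any(!is.na(ccs) & (ccs < 0 | ccs > 1)))
    stop("ITVS and CCS must lie in [0, 1]")
  sqrt(itvs * ccs)
}

#' Bin IHS values into the four ITH groups
#'
#' Half-open bins: low \[0, 0.25), median \[0.25, 0.50), high \[0.50, 0.75),
#' very-high \[0.75, 1.00\].
#'
#' @param x IHS values in \[0, 1\] (NA allowed, propagated).
#' @return Factor with levels `low`, `median`, `high`, `very-high`.
#' @export
bin_ihs <- function(x) {
  if (any(!is.na(x) & (x < 0 | x > 1))) stop("IHS must lie in [0, 1]")
  b <- cut(x, breaks = c(0, 0.25, 0.50, 0.75, 1.00),
           labels = c("low", "median", "high", "very-high"),
           right = FALSE, include.lowest = FALSE)
  b[!is.na(x) & x == 1] <- "very-high"  # top bin closed at 1.0
  b
}

#' Feature-wise IHS table
#'
#' Computes W, B, ITVS, the PGOR curve AUC, CCS, IHS and the ITH bin for
#' every row of a feature x sample matrix (genes, immune-cell fractions,
#' protein activities, ...). Results are independent of feature order and
#' batching.
#'
#' @param features features x samples numeric matrix with rownames.
#' @param patients patient label per sample (column).
#' @param transform `"log2p1"` (default, for TPM-scale expression) or
#'   `"none"` (for features already on an analysis scale).
#' @param method ITVS estimator, see [itvs()].
#' @param linkage clustering linkage, see [pgor_curve()].
#' @return Data frame `feature`, `W`, `B`, `itvs`, `auc_pgor`, `ccs`,
#'   `ihs`, `bin`; features with zero total variance have NA scores.
#' @export
ihs_table <- function(features, patients,
                      transform = c("log2p1", "none"),
                      method = c("reml", "moments"),
                      linkage = "complete") {
  transform <- match.arg(transform)
  method <- match.arg(method)
  x <- as.matrix(features)
  stopifnot(ncol(x) == length(patients))
  if (transform == "log2p1") x <- log2(x + 1)

  keep <- patients %in% names(which(table(patients) >= 2))
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) from single-sample patients excluded")
    x <- x[, keep, drop = FALSE]
    patients <- patients[keep]
  }
  rows <- lapply(seq_len(nrow(x)), function(i) {
    v <- x[i, ]
    if (stats::var(v) == 0)
      return(data.frame(feature = rownames(x)[i], W = 0, B = 0,
                        itvs = NA_real_, auc_pgor = NA_real_,
                        ccs = NA_real_, ihs = NA_real_,
                        stringsAsFactors = FALSE))
    iv <- itvs(v, patients, method = method)
    pg <- pgor_curve(v, patients, linkage = linkage)
    cc <- ccs(pg)
    data.frame(feature = rownames(x)[i], W = iv$W, B = iv$B,
               itvs = iv$itvs, auc_pgor = cc$auc, ccs = cc$ccs,
               ihs = ihs(iv$itvs, cc$ccs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bin <- bin_ihs(out$ihs)
  out
}

#' IHS null distribution for structure-free negative-binomial genes
#'
#' Draws genes i.i.d. per sample from a negative binomial distribution with
#' no patient structure, lays them over the given cohort shape and computes
#' the IHS of every simulated gene. Structure-free genes concentrate near
#' IHS = 1, giving a reference against which real (patient-structured)
#' genes can be contrasted.
#'
#' @param n_genes number of simulated genes.
#' @param mu,size negative binomial mean and dispersion (size) parameters.
#' @param n_patients,regions_per_patient cohort shape.
#' @param seed integer seed.
#' @param ... passed to [ihs_table()].
#' @return List `table` (per-gene IHS table) and `median_ihs`.
#' @export
nb_null_ihs <- function(n_genes = 200, mu = 100, size = 2,
                        n_patients = 10, regions_per_patient = 5,
                        seed = 1, ...) {
  set.seed(seed)
  n <- n_patients * regions_per_patient
  x <- matrix(stats::rnbinom(n_genes * n, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(sprintf("null_g%d", seq_len(n_genes)),
                              sprintf("S%d", seq_len(n))))
  patients <- rep(sprintf("P%02d", seq_len(n_patients)),
                  each = regions_per_patient)
  tab <- ihs_table(x, patients, ...)
  list(table = tab, median_ihs = stats::median(tab$ihs, na.rm = TRUE))
}

#' Enrichment of a feature set in an IHS ranking
#'
#' GSEA-style weighted Kolmogorov--Smirnov enrichment of a query feature
#' set within features ranked by IHS, with the low-IHS end at the head of
#' the ranking (positive enrichment score = query concentrated among
#' low-ITH features). Significance by seeded gene permutations.
#'
#' @param query character vector of feature ids (subset of the reference).
#' @param ihs_values named numeric vector of reference IHS values; ties are
#'   broken by feature id.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return List `es`, `nes`, `p`.
#' @export
ihs_enrichment_rank <- function(query, ihs_values, n_perm = 1000, seed = 1) {
  stopifnot(!is.null(names(ihs_values)))
  if (!all(query %in% names(ihs_values)))
    stop("query contains features absent from the reference ranking")
  if (length(query) < 5)
    warning("query has fewer than 5 features; enrichment is unstable")
  ord <- order(ihs_values, names(ihs_values))
  n <- length(ihs_values)
  # strictly decreasing stat along the ranking, centered at 0:
  # low-IHS head gets the largest values
  stats_vec <- stats::setNames(rev(seq_len(n)) - (n + 1) / 2,
                               names(ihs_values)[ord])
  set.seed(seed)
  res <- suppressWarnings(
    fgsea::fgseaSimple(pathways = list(query = query),
                       stats = stats_vec, nperm = n_perm))
  list(es = res$ES, nes = res$NES, p = res$pval)
}
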