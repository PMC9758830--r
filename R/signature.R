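#' Survival cohort container
#'
#' Bundles a gene x patient expression matrix with a patient survival table
#' for signature training/evaluation.
#'
#' @param expression genes x patients numeric matrix (one value per
#'   patient).
#' @param survival data frame `patient_id`, `time` (> 0), `event` (0/1).
#' @param name optional cohort label.
#' @return A `survival_cohort` list.
#' @export
survival_cohort <- function(expression, survival, name = "cohort") {
  stopifnot(is.matrix(expression),
            all(c("patient_id", "time", "event") %in% names(survival)))
  if (any(survival$time <= 0)) stop("survival times must be > 0")
  if (!all(survival$event %in% c(0, 1))) stop("events must be 0/1")
  common <- intersect(colnames(expression), survival$patient_id)
  if (!length(common)) stop("no overlapping patients")
  survival <- survival[match(common, survival$patient_id), , drop = FALSE]
  structure(list(expression = expression[, common, drop = FALSE],
                 survival = survival, name = name),
            class = "survival_cohort")
}

# Per-gene z-score across a cohort's patients; constant genes become NA rows.
zscore_genes <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / sd
  z[sd == 0, ] <- NA_real_
  z
}

#' Filter genes to the low-ITH group
#'
#' Keeps genes with IHS strictly below the threshold (default 0.25, the
#' low-ITH bin boundary).
#'
#' @param ihs_tab output of [ihs_table()].
#' @param threshold strict upper bound on IHS.
#' @return Character vector of gene ids.
#' @export
filter_low_ith <- function(ihs_tab, threshold = 0.25) {
  g <- ihs_tab$feature[!is.na(ihs_tab$ihs) & ihs_tab$ihs < threshold]
  if (!length(g))
    stop("no gene has IHS < ", threshold, "; consider relaxing the threshold")
  g
}

# Univariate Cox fit of one z-scored gene; NULL when non-estimable.
cox_one <- function(z, time, event) {
  if (anyNA(z)) return(NULL)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ z)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit))) return(NULL)
  s <- summary(fit)
  list(hr = unname(exp(stats::coef(fit))), p = s$coefficients[1, 5])
}

#' Multi-cohort univariate Cox screen
#'
#' Fits a univariate proportional-hazards model per gene per cohort on
#' within-cohort z-scored expression. A gene passes when p < `alpha` in
#' every cohort with the same hazard direction; protective (HR < 1) and
#' risk (HR > 1) sets are returned separately. Non-estimable fits (e.g.
#' constant expression) are flagged and excluded.
#'
#' @param cohorts list of [survival_cohort()] objects (training cohorts).
#' @param genes candidate gene ids.
#' @param alpha per-cohort significance level (default 0.05).
#' @return List `results` (long data frame gene x cohort with `hr`, `p`),
#'   `protective`, `risk`, `flagged`.
#' @export
cox_screen <- function(cohorts, genes, alpha = 0.05) {
  stopifnot(length(cohorts) >= 1)
  zs <- lapply(cohorts, function(co) {
    miss <- setdiff(genes, rownames(co$expression))
    if (length(miss))
      stop("genes missing from cohort '", co$name, "': ",
           paste(utils::head(miss, 5), collapse = ", "))
    zscore_genes(co$expression[genes, , drop = FALSE])
  })
  rows <- list(); flagged <- character(0)
  pass_dir <- matrix(NA_real_, length(genes), length(cohorts),
                     dimnames = list(genes, NULL))
  for (ci in seq_along(cohorts)) {
    co <- cohorts[[ci]]
    for (g in genes) {
      f <- cox_one(zs[[ci]][g, ], co$survival$time, co$survival$event)
      if (is.null(f)) {
        flagged <- union(flagged, g)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cohort = co$name, hr = f$hr, p = f$p,
        stringsAsFactors = FALSE)
      if (f$p < alpha) pass_dir[g, ci] <- sign(log(f$hr))
    }
  }
  ok <- !rownames(pass_dir) %in% flagged &
    apply(pass_dir, 1, function(d) !anyNA(d) && length(unique(d)) == 1)
  dir1 <- pass_dir[, 1]
  list(results = do.call(rbind, rows),
       protective = genes[ok & dir1 < 0],
       risk = genes[ok & dir1 > 0],
       flagged = flagged)
}

#' Bootstrap stability screen
#'
#' Per bootstrap iteration, patients are resampled with replacement within
#' each cohort and each gene is re-screened (univariate Cox, p < `alpha`
#' with a consistent hazard direction in every cohort). Genes are kept when
#' their pass count reaches `pass_fraction * n_boot`. Fit failures count as
#' non-passes.
#'
#' @param cohorts list of training [survival_cohort()]s.
#' @param genes genes from the primary screen.
#' @param n_boot bootstrap iterations (default 2500).
#' @param pass_fraction required pass share (default 0.8, i.e. 2000/2500).
#' @param alpha per-cohort significance level.
#' @param seed integer seed.
#' @return List `counts` (data frame `gene`, `passes`, `kept`) and
#'   `stable` (kept gene ids).
#' @export
bootstrap_stability <- function(cohorts, genes, n_boot = 2500,
                                pass_fraction = 0.8, alpha = 0.05,
                                seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  zs <- lapply(cohorts, function(co)
    zscore_genes(co$expression[genes, , drop = FALSE]))
  set.seed(seed)
  passes <- stats::setNames(integer(length(genes)), genes)
  for (b in seq_len(n_boot)) {
    dirs <- matrix(NA_real_, length(genes), length(cohorts),
                   dimnames = list(genes, NULL))
    for (ci in seq_along(cohorts)) {
      co <- cohorts[[ci]]
      n <- nrow(co$survival)
      idx <- sample.int(n, n, replace = TRUE)
      time <- co$survival$time[idx]; event <- co$survival$event[idx]
      for (g in genes) {
        f <- cox_one(zs[[ci]][g, idx], time, event)
        if (!is.null(f) && f$p < alpha) dirs[g, ci] <- sign(log(f$hr))
      }
    }
    hit <- apply(dirs, 1, function(d) !anyNA(d) && length(unique(d)) == 1)
    passes <- passes + hit
  }
  kept <- passes >= pass_fraction * n_boot
  list(counts = data.frame(gene = genes, passes = unname(passes),
                           kept = unname(kept), stringsAsFactors = FALSE),
       stable = genes[kept])
}

# Pool cohorts into one patients x (genes + survival) frame on
# within-cohort z-scored expression.
pool_cohorts <- function(cohorts, genes) {
  blocks <- lapply(cohorts, function(co) {
    z <- t(zscore_genes(co$expression[genes, , drop = FALSE]))
    df <- as.data.frame(z)
    names(df) <- genes
    df$time <- co$survival$time
    df$event <- co$survival$event
    df
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Random-survival-forest combination search
#'
#' Ranks stable genes by permutation variable importance averaged over
#' replicate survival forests fit on the pooled, within-cohort z-scored
#' training data, then evaluates nested top-j subsets (j = 2..`max_size`)
#' by mean out-of-bag concordance and returns the best-performing subset
#' (ties go to the smaller subset).
#'
#' @param cohorts list of training [survival_cohort()]s.
#' @param genes stable gene ids (>= 2).
#' @param n_replicates forests per evaluation (default 10; the full-scale
#'   analysis uses more).
#' @param num_trees trees per forest.
#' @param max_size largest subset evaluated (default 25).
#' @param seed integer seed.
#' @return List `genes` (selected subset, importance order), `concordance`
#'   (its mean OOB concordance), `importance` (named, sorted), `subset_scores`
#'   (data frame `size`, `concordance`), `low_confidence` (TRUE when the
#'   best concordance is below 0.55).
#' @export
forest_combination_search <- function(cohorts, genes, n_replicates = 10,
                                      num_trees = 500, max_size = 25,
                                      seed = 1) {
  if (length(genes) < 2) stop("need >= 2 stable genes")
  dat <- pool_cohorts(cohorts, genes)
  if (sum(dat$event) < 5) stop("too few events for forest fitting")

  fit_rf <- function(vars, s) {
    ranger::ranger(
      stats::as.formula(paste("survival::Surv(time, event) ~",
                              paste(sprintf("`%s`", vars), collapse = "+"))),
      data = dat[, c(vars, "time", "event")],
      num.trees = num_trees, importance = "permutation",
      seed = s, num.threads = 1)
  }
  imp <- Reduce(`+`, lapply(seq_len(n_replicates), function(r)
    fit_rf(genes, seed + r)$variable.importance)) / n_replicates
  ranked <- names(sort(imp, decreasing = TRUE))

  sizes <- 2:min(max_size, length(genes))
  conc <- vapply(sizes, function(j) {
    mean(vapply(seq_len(n_replicates), function(r)
      1 - fit_rf(ranked[seq_len(j)], seed + 1000 * j + r)$prediction.error,
      numeric(1)))
  }, numeric(1))
  best <- sizes[which.max(conc)]          # which.max takes the first maximum
  list(genes = ranked[seq_len(best)],
       concordance = max(conc),
       importance = sort(imp, decreasing = TRUE),
       subset_scores = data.frame(size = sizes, concordance = conc),
       low_confidence = max(conc) < 0.55)
}

#' Build a low-ITH prognostic signature
#'
#' End-to-end training chain: restrict to low-ITH genes (IHS < `threshold`),
#' univariate Cox screen with direction intersection across training
#' cohorts, bootstrap stability screen, survival-forest combination search,
#' then a multivariate Cox fit of the selected genes on the pooled training
#' data to obtain the scoring weights. The risk score of a sample is
#' \eqn{\sum_g w_g z(expr_g)} with z-scores computed within the evaluation
#' data.
#'
#' @param cohorts list of training [survival_cohort()]s.
#' @param ihs_tab multi-region [ihs_table()] for the candidate genes.
#' @param threshold IHS cutoff (default 0.25).
#' @param n_boot,pass_fraction bootstrap screen settings.
#' @param n_replicates,num_trees,max_size forest search settings.
#' @param seed integer seed for all stochastic stages.
#' @return A `signature_model`: `genes`, `weights` (named), `direction`
#'   (`risk`/`protective` per gene), `score_rule`, `training_meta`.
#' @export
build_signature <- function(cohorts, ihs_tab, threshold = 0.25,
                            n_boot = 2500, pass_fraction = 0.8,
                            n_replicates = 10, num_trees = 500,
                            max_size = 25, seed = 1) {
  cand <- filter_low_ith(ihs_tab, threshold)
  cand <- intersect(cand, Reduce(intersect,
                                 lapply(cohorts, function(co)
                                   rownames(co$expression))))
  if (!length(cand)) stop("no low-ITH gene is present in every cohort")
  scr <- cox_screen(cohorts, cand)
  hits <- c(scr$protective, scr$risk)
  if (length(hits) < 2) stop("fewer than 2 genes pass the Cox screen")
  bs <- bootstrap_stability(cohorts, hits, n_boot = n_boot,
                            pass_fraction = pass_fraction, seed = seed)
  if (length(bs$stable) < 2) stop("fewer than 2 genes pass the bootstrap screen")
  fs <- forest_combination_search(cohorts, bs$stable,
                                  n_replicates = n_replicates,
                                  num_trees = num_trees,
                                  max_size = max_size, seed = seed)
  dat <- pool_cohorts(cohorts, fs$genes)
  mv <- survival::coxph(
    survival::Surv(time, event) ~ .,
    data = stats::setNames(dat, make.names(names(dat))))
  w <- stats::setNames(unname(stats::coef(mv)), fs$genes)
  structure(list(
    genes = fs$genes,
    weights = w,
    direction = ifelse(w > 0, "risk", "protective"),
    score_rule = "sum_g weight_g * z(expr_g); z within evaluation cohort",
    training_meta = list(
      cohorts = vapply(cohorts, `[[`, "", "name"),
      ihs_threshold = threshold,
      n_candidates = length(cand),
      n_protective = length(scr$protective),
      n_risk = length(scr$risk),
      n_stable = length(bs$stable),
      n_boot = n_boot, pass_fraction = pass_fraction,
      forest_concordance = fs$concordance,
      low_confidence = fs$low_confidence,
      seed = seed)
  ), class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Prognostic signature:", length(x$genes), "genes (",
      sum(x$direction == "risk"), "risk /",
      sum(x$direction == "protective"), "protective )\n")
  invisible(x)
}

#' Save / load a signature model as JSON
#'
#' @param model a `signature_model`.
#' @param path JSON file path.
#' @return `read_signature` returns the reloaded `signature_model`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weights <- stats::setNames(as.numeric(x$weights), x$genes)
  x$direction <- stats::setNames(as.character(x$direction), x$genes)
  structure(x, class = "signature_model")
}

#' Signature risk score
#'
#' \eqn{\sum_g w_g z(expr_g)} with per-gene z-scores computed across the
#' supplied samples. The score is invariant to gene order and to unrelated
#' genes present in the matrix.
#'
#' @param model a `signature_model`.
#' @param expr genes x samples (or genes x patients) expression matrix, on
#'   the same scale as used in training (`log2(TPM + 1)` for expression via
#'   `transform`).
#' @param transform `"none"` (default: matrix already on analysis scale) or
#'   `"log2p1"` for TPM input.
#' @return Named numeric score per column of `expr`.
#' @export
signature_score <- function(model, expr, transform = c("none", "log2p1")) {
  transform <- match.arg(transform)
  miss <- setdiff(model$genes, rownames(expr))
  if (length(miss))
    stop("signature genes missing from expression: ",
         paste(miss, collapse = ", "))
  x <- expr[model$genes, , drop = FALSE]
  if (transform == "log2p1") x <- log2(x + 1)
  z <- zscore_genes(x)
  z[is.na(z)] <- 0
  colSums(z * model$weights[model$genes])
}

# Kaplan-Meier estimate of the censoring survival function G(t).
censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(t) {
    s <- summary(sf, times = pmax(t, 0), extend = TRUE)$surv
    pmax(s, 1e-8)
  }
}

#' Time-dependent AUC (IPCW cumulative/dynamic)
#'
#' Inverse-probability-of-censoring-weighted AUC at horizon t: cases are
#' patients with an event by t (weighted by 1/G(T-)), controls are patients
#' still at risk after t (weighted by 1/G(t)), with G the Kaplan--Meier
#' censoring survival function.
#'
#' @param score risk score per patient (higher = riskier).
#' @param time,event survival outcome.
#' @param times horizons.
#' @return Data frame `time`, `auc` (NA when a horizon has no cases or no
#'   controls).
#' @export
td_auc <- function(score, time, event, times) {
  G <- censoring_km(time, event)
  out <- vapply(times, function(t) {
    case <- which(time <= t & event == 1)
    ctrl <- which(time > t)
    if (!length(case) || !length(ctrl)) return(NA_real_)
    wi <- 1 / G(pmax(time[case] - 1e-8, 0))
    wj <- rep(1 / G(t), length(ctrl))
    cmp <- outer(score[case], score[ctrl],
                 function(a, b) (a > b) + 0.5 * (a == b))
    sum((wi %o% wj) * cmp) / (sum(wi) * sum(wj))
  }, numeric(1))
  data.frame(time = times, auc = out)
}

#' Prognostic evaluation of a signature
#'
#' Per cohort: scores every patient, splits at the within-cohort median,
#' and reports the Cox hazard ratio (high vs low) with 95% CI, the log-rank
#' p-value, and the IPCW time-dependent AUC at a time grid with its mean.
#'
#' @param model a `signature_model`.
#' @param cohorts list of [survival_cohort()]s.
#' @param times AUC horizons; default: five equally spaced points between
#'   the 10th and 90th percentile of each cohort's follow-up times.
#' @return Data frame, one row per cohort: `cohort`, `n`, `events`, `hr`,
#'   `hr_lo`, `hr_hi`, `logrank_p`, `mean_auc`.
#' @export
evaluate_prognosis <- function(model, cohorts, times = NULL) {
  rows <- lapply(cohorts, function(co) {
    s <- signature_score(model, co$expression)
    time <- co$survival$time; event <- co$survival$event
    if (sum(event) < 10)
      warning("cohort '", co$name, "' has < 10 events; estimates unstable")
    grp <- as.integer(s > stats::median(s))
    fit <- survival::coxph(survival::Surv(time, event) ~ grp)
    ci <- suppressMessages(stats::confint(fit))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    tt <- if (is.null(times))
      seq(stats::quantile(time, 0.1), stats::quantile(time, 0.9),
          length.out = 5) else times
    a <- td_auc(s, time, event, tt)
    data.frame(cohort = co$name, n = length(s), events = sum(event),
               hr = unname(exp(stats::coef(fit))),
               hr_lo = exp(ci[1]), hr_hi = exp(ci[2]),
               logrank_p = p, mean_auc = mean(a$auc, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ITH-robustness evaluation of a signature on multi-region data
#'
#' Three metrics of how stable a signature's risk calls are across regions
#' of the same tumor: (a) the median IHS of the signature genes; (b) the
#' fraction of tumors whose regions straddle the cohort-median score split
#' (discordant tumors); (c) the trapezoidal AUC of the PGOR curve from
#' clustering all regions on the z-scored signature sub-matrix (P - 1 for a
#' signature that co-clusters every patient's samples perfectly).
#'
#' @param model a `signature_model`.
#' @param expr multi-region genes x samples TPM matrix.
#' @param meta sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @param ihs_tab [ihs_table()] of the multi-region cohort.
#' @param linkage clustering linkage for the PGOR curve.
#' @return List `median_ihs`, `discordant_prop`, `classes`, `pgor`,
#'   `pgor_auc`, `P`.
#' @export
evaluate_ith_robustness <- function(model, expr, meta, ihs_tab,
                                    linkage = "complete") {
  tum <- meta$sample_id[meta$tissue == "tumor"]
  tum <- intersect(colnames(expr), tum)
  x <- expr[, tum, drop = FALSE]
  patients <- meta$patient_id[match(tum, meta$sample_id)]

  present <- intersect(model$genes, ihs_tab$feature)
  if (length(present) < length(model$genes))
    warning("IHS available for ", length(present), "/",
            length(model$genes), " signature genes")
  med_ihs <- stats::median(
    ihs_tab$ihs[match(present, ihs_tab$feature)], na.rm = TRUE)

  s <- signature_score(model, x, transform = "log2p1")
  cc <- concordance_classify(s, patients)

  sig_present <- intersect(model$genes, rownames(x))
  sub <- t(log2(x[sig_present, , drop = FALSE] + 1))
  pg <- pgor_curve(sub, patients, linkage = linkage)
  list(median_ihs = med_ihs,
       discordant_prop = cc$discordant_prop,
       classes = cc$classes,
       pgor = as.numeric(pg),
       pgor_auc = trapezoid_auc(pg),
       P = attr(pg, "P"))
}
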