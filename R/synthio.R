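#' Configuration for a synthetic multi-region cohort
#'
#' Builds a validated configuration object for [simulate_cohort()]. The
#' defaults emulate a liver-cancer multi-region study design: 14 patients
#' each contributing 3--10 spatially localized tumor regions (median around
#' 5), gene expression with patient-level structure plus a spatially
#' correlated within-tumor component, shared trunk and spatially clustered
#' private mutations, and proportional-hazards survival with independent
#' censoring.
#'
#' Expression for gene \eqn{g}, patient \eqn{p}, region \eqn{r} is generated
#' on the log2 scale as
#' \deqn{v = \mu_g + b_{p,g} + s_{p,r,g} + \epsilon_{p,r,g}}
#' with \eqn{b \sim N(0, \sigma^2_{between,g})}, a spatially correlated
#' Gaussian field \eqn{s} with covariance
#' \eqn{\sigma^2_{within,g} \cdot f \cdot k(d)} over the region coordinates,
#' and white noise with variance \eqn{\sigma^2_{within,g} (1-f)}, where
#' \eqn{f} is `spatial_fraction` and \eqn{k} the chosen kernel. Emitted
#' expression is `pmax(2^v - 1, 0)` (TPM scale), so the downstream default
#' `log2(TPM + 1)` transform recovers \eqn{v} exactly.
#'
#' @param n_patients number of patients (tumors).
#' @param regions_per_patient integer count, or length-2 range from which
#'   per-patient counts are drawn uniformly; must be >= 2.
#' @param n_genes number of genes.
#' @param baseline_log_mean per-gene baseline, log2 TPM units (scalar or
#'   length `n_genes`).
#' @param sigma_between per-gene between-patient SD (log2 scale); scalar or
#'   length `n_genes`, all >= 0.
#' @param sigma_within per-gene within-tumor SD (log2 scale); scalar or
#'   length `n_genes`, all >= 0.
#' @param spatial_range distance-decay length of the within-tumor covariance
#'   kernel, cm (> 0).
#' @param spatial_fraction share of within-tumor variance that is spatially
#'   structured, in \[0, 1\].
#' @param spatial_kernel `"exponential"` (`exp(-d/l)`) or `"gaussian"`
#'   (`exp(-(d/l)^2)`).
#' @param tumor_radius sampling disc radius, cm (> 0).
#' @param min_spacing minimum pairwise spacing between sampling sites, cm
#'   (enforced by rejection).
#' @param dispersion per-tumor multiplier on the sampling disc radius:
#'   a scalar, a vector of length `n_patients`, or a length-2 range from
#'   which multipliers are drawn uniformly. Creates tumors with different
#'   physical diversity.
#' @param n_trunk_mutations mutations shared by all regions of a tumor.
#' @param n_private_mutations private mutations anchored per region.
#' @param mutation_sharing_range distance-decay length (cm) of the kernel by
#'   which nearby regions share private mutations; 0 disables sharing.
#' @param baseline_hazard baseline event rate of the exponential
#'   proportional-hazards survival model (per time unit).
#' @param survival_beta named numeric vector of per-gene log hazard ratios
#'   (names must be gene ids `g1..gN`), or `NULL` for the default of five
#'   risk (`+0.5`) and five protective (`-0.5`) genes.
#' @param censoring_rate target fraction of censored patients, in \[0, 1\].
#' @param seed integer seed; identical config + seed gives identical cohorts.
#'
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 14,
                       regions_per_patient = c(3, 10),
                       n_genes = 500,
                       baseline_log_mean = 4,
                       sigma_between = 1,
                       sigma_within = 0.5,
                       spatial_range = 2,
                       spatial_fraction = 0.6,
                       spatial_kernel = c("exponential", "gaussian"),
                       tumor_radius = 3,
                       min_spacing = 0.5,
                       dispersion = 1,
                       n_trunk_mutations = 100,
                       n_private_mutations = 30,
                       mutation_sharing_range = 2,
                       baseline_hazard = 0.02,
                       survival_beta = NULL,
                       censoring_rate = 0.3,
                       seed = 1L) {
  spatial_kernel <- match.arg(spatial_kernel)
  stopifnot(is.numeric(n_patients), n_patients >= 1,
            is.numeric(n_genes), n_genes >= 1)
  if (!is.numeric(regions_per_patient) ||
      !(length(regions_per_patient) %in% c(1L, 2L)))
    stop("'regions_per_patient' must be a count or a length-2 range")
  if (any(regions_per_patient < 2))
    stop("'regions_per_patient' must be >= 2")
  if (any(sigma_between < 0) || any(sigma_within < 0))
    stop("standard deviations must be >= 0")
  if (spatial_fraction < 0 || spatial_fraction > 1)
    stop("'spatial_fraction' must be in [0, 1]")
  if (spatial_range <= 0) stop("'spatial_range' must be > 0")
  if (tumor_radius <= 0) stop("'tumor_radius' must be > 0")
  if (n_trunk_mutations < 0 || n_private_mutations < 0)
    stop("mutation counts must be >= 0")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("'censoring_rate' must be in [0, 1]")

  genes <- sprintf("g%d", seq_len(n_genes))
  sb <- rep_len(sigma_between, n_genes)
  sw <- rep_len(sigma_within, n_genes)
  mu <- rep_len(baseline_log_mean, n_genes)

  if (is.null(survival_beta)) {
    survival_beta <- numeric(0)
    if (n_genes >= 10) {
      survival_beta <- stats::setNames(
        c(rep(0.5, 5), rep(-0.5, 5)), genes[1:10])
    }
  }
  if (length(survival_beta) && !all(names(survival_beta) %in% genes))
    stop("'survival_beta' names must be gene ids present in the cohort")

  structure(list(
    n_patients = as.integer(n_patients),
    regions_per_patient = as.integer(regions_per_patient),
    n_genes = as.integer(n_genes),
    genes = genes,
    baseline_log_mean = mu,
    sigma_between = sb,
    sigma_within = sw,
    spatial_range = spatial_range,
    spatial_fraction = spatial_fraction,
    spatial_kernel = spatial_kernel,
    tumor_radius = tumor_radius,
    min_spacing = min_spacing,
    dispersion = dispersion,
    n_trunk_mutations = as.integer(n_trunk_mutations),
    n_private_mutations = as.integer(n_private_mutations),
    mutation_sharing_range = mutation_sharing_range,
    baseline_hazard = baseline_hazard,
    survival_beta = survival_beta,
    censoring_rate = censoring_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Named sub-seeds so each component (coords/expression/mutations/survival)
# is independently reproducible from the master seed.
sim_subseeds <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, 4),
                  c("coords", "expression", "mutations", "survival"))
}

spatial_kernel_fun <- function(kernel) {
  switch(kernel,
         exponential = function(d, l) exp(-d / l),
         gaussian = function(d, l) exp(-(d / l)^2),
         stop("unknown spatial kernel: ", kernel))
}

#' Generate sampling-site coordinates for a synthetic cohort
#'
#' Per tumor, points are drawn uniformly in a disc of radius
#' `tumor_radius * dispersion`, with a minimum pairwise spacing enforced by
#' rejection. A dispersion multiplier of 0 places all points at the disc
#' center (zero physical diversity).
#'
#' @param config a [sim_config()].
#' @return A data frame with columns `sample_id`, `patient_id`, `x_cm`,
#'   `y_cm`, plus attributes `regions` (per-patient region counts) and
#'   `dispersion` (per-patient multipliers).
#' @export
generate_coordinates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_subseeds(config$seed)[["coords"]])

  np <- config$n_patients
  rp <- config$regions_per_patient
  m <- if (length(rp) == 1L) rep(rp, np) else
    sample(seq(rp[1], rp[2]), np, replace = TRUE)
  disp <- config$dispersion
  if (length(disp) == 2L && np != 2L) {
    disp <- stats::runif(np, disp[1], disp[2])
  } else {
    disp <- rep_len(disp, np)
  }

  out <- vector("list", np)
  for (p in seq_len(np)) {
    r <- config$tumor_radius * disp[p]
    if (r == 0) {
      xy <- matrix(0, m[p], 2)
    } else {
      xy <- sample_disc_spaced(m[p], r, config$min_spacing)
    }
    out[[p]] <- data.frame(
      sample_id = sprintf("P%02d_R%d", p, seq_len(m[p])),
      patient_id = sprintf("P%02d", p),
      x_cm = xy[, 1], y_cm = xy[, 2],
      stringsAsFactors = FALSE)
  }
  coords <- do.call(rbind, out)
  rownames(coords) <- NULL
  attr(coords, "regions") <- m
  attr(coords, "dispersion") <- disp
  coords
}

# Uniform-in-disc sampling with pairwise spacing, bounded rejection.
sample_disc_spaced <- function(n, radius, spacing, max_restart = 50) {
  for (attempt in seq_len(max_restart)) {
    pts <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1000)) {
        th <- stats::runif(1, 0, 2 * pi)
        rr <- radius * sqrt(stats::runif(1))
        cand <- c(rr * cos(th), rr * sin(th))
        if (i == 1 ||
            all(sqrt(rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE],
                                   2, cand)^2)) >= spacing)) {
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  stop("could not place ", n, " points with spacing ", spacing,
       " cm in a disc of radius ", radius, " cm")
}

#' Generate synthetic multi-region expression
#'
#' Log2-scale values are the sum of a gene baseline, a patient random effect
#' (SD `sigma_between`), a spatially correlated within-tumor Gaussian field
#' (variance `sigma_within^2 * spatial_fraction`, kernel over the sampling
#' coordinates) and white noise (the remaining within-tumor variance).
#' Emitted expression is `2^value - 1`, clipped at 0 (TPM scale).
#'
#' @param config a [sim_config()].
#' @param coords output of [generate_coordinates()]; generated if missing.
#' @return List with `tpm` (genes x samples matrix), `log2` (the latent
#'   log2-scale matrix) and `meta` (sample_id, patient_id, tissue).
#' @export
generate_expression <- function(config, coords = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(coords)) coords <- generate_coordinates(config)
  set.seed(sim_subseeds(config$seed)[["expression"]])

  kern <- spatial_kernel_fun(config$spatial_kernel)
  genes <- config$genes
  ng <- config$n_genes
  sw <- config$sigma_within
  sb <- config$sigma_between
  f <- config$spatial_fraction

  patients <- unique(coords$patient_id)
  blocks <- vector("list", length(patients))
  for (pi in seq_along(patients)) {
    sel <- coords$patient_id == patients[pi]
    m <- sum(sel)
    xy <- as.matrix(coords[sel, c("x_cm", "y_cm")])
    b <- stats::rnorm(ng, 0, sb)                      # patient effect per gene
    eps <- matrix(stats::rnorm(m * ng), m, ng) *
      rep(sw * sqrt(1 - f), each = m)
    s <- matrix(0, m, ng)
    if (f > 0 && m >= 2) {
      d <- as.matrix(stats::dist(xy))
      K <- kern(d, config$spatial_range)
      L <- chol(K + diag(1e-8, m))
      z <- matrix(stats::rnorm(m * ng), m, ng)
      s <- crossprod(L, z) * rep(sw * sqrt(f), each = m)
    } else if (f > 0 && m == 1) {
      s <- matrix(stats::rnorm(ng, 0, sw * sqrt(f)), 1, ng)
    }
    v <- sweep(s + eps, 2, config$baseline_log_mean + b, "+")
    blocks[[pi]] <- t(v)                              # genes x regions
  }
  log2mat <- do.call(cbind, blocks)
  rownames(log2mat) <- genes
  colnames(log2mat) <- coords$sample_id
  tpm <- pmax(2^log2mat - 1, 0)

  meta <- data.frame(sample_id = coords$sample_id,
                     patient_id = coords$patient_id,
                     tissue = "tumor", stringsAsFactors = FALSE)
  list(tpm = tpm, log2 = log2mat, meta = meta)
}

#' Generate synthetic somatic mutation profiles
#'
#' Each tumor receives `n_trunk_mutations` variants shared by all of its
#' regions plus private variants anchored at individual regions. A private
#' variant anchored at region a is also carried by region r with probability
#' `exp(-d(a, r) / mutation_sharing_range)`, so that nearby regions share
#' more private variants and Jaccard distance increases with physical
#' distance. A sharing range of 0 keeps private sets disjoint.
#'
#' @param config a [sim_config()].
#' @param coords output of [generate_coordinates()]; generated if missing.
#' @return Named list (one element per sample) of canonical
#'   `chrom:pos:ref:alt` variant keys.
#' @export
generate_mutations <- function(config, coords = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(coords)) coords <- generate_coordinates(config)
  set.seed(sim_subseeds(config$seed)[["mutations"]])

  bases <- c("A", "C", "G", "T")
  make_keys <- function(n, block) {
    if (n == 0) return(character(0))
    pos <- block * 10^6 + seq_len(n)
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    sprintf("%d:%d:%s:%s", sample(1:22, n, replace = TRUE), pos, ref, alt)
  }

  patients <- unique(coords$patient_id)
  out <- stats::setNames(vector("list", nrow(coords)), coords$sample_id)
  block <- 0L
  for (pi in seq_along(patients)) {
    sel <- which(coords$patient_id == patients[pi])
    m <- length(sel)
    xy <- as.matrix(coords[sel, c("x_cm", "y_cm")])
    d <- as.matrix(stats::dist(xy))
    block <- block + 1L
    trunk <- make_keys(config$n_trunk_mutations, block)
    sets <- rep(list(trunk), m)
    if (config$n_private_mutations > 0) {
      for (a in seq_len(m)) {
        block <- block + 1L
        priv <- make_keys(config$n_private_mutations, block)
        for (r in seq_len(m)) {
          if (r == a) {
            sets[[r]] <- c(sets[[r]], priv)
          } else if (config$mutation_sharing_range > 0) {
            pshare <- exp(-d[a, r] / config$mutation_sharing_range)
            keep <- stats::runif(length(priv)) < pshare
            sets[[r]] <- c(sets[[r]], priv[keep])
          }
        }
      }
    }
    for (r in seq_len(m)) out[[sel[r]]] <- sets[[r]]
  }
  out
}

#' Generate synthetic patient survival
#'
#' Event times follow an exponential proportional-hazards model with linear
#' predictor \eqn{\sum_g \beta_g z_g}, where \eqn{z_g} is the patient's mean
#' tumor expression of gene g (log2(TPM + 1)), standardized across patients.
#' Censoring is independent exponential, with rate matched to the configured
#' censoring fraction. If a draw comes out all-censored the draw is repeated
#' with a fresh sub-seed up to 5 times, then returned with a warning.
#'
#' @param config a [sim_config()].
#' @param expression output of [generate_expression()].
#' @return Data frame `patient_id`, `time`, `event` (1 = event, 0 =
#'   censored).
#' @export
generate_survival <- function(config, expression) {
  stopifnot(inherits(config, "sim_config"))
  beta <- config$survival_beta
  meta <- expression$meta
  patients <- unique(meta$patient_id)
  np <- length(patients)

  lp <- rep(0, np)
  if (length(beta)) {
    lg <- log2(expression$tpm[names(beta), , drop = FALSE] + 1)
    pm <- vapply(patients, function(p)
      rowMeans(lg[, meta$patient_id == p, drop = FALSE]), numeric(length(beta)))
    pm <- matrix(pm, nrow = length(beta))          # genes x patients
    z <- t(scale(t(pm)))
    z[is.nan(z)] <- 0                              # constant gene across patients
    lp <- as.numeric(crossprod(z, beta))
  }
  h <- config$baseline_hazard * exp(lp)
  cr <- config$censoring_rate

  seed0 <- sim_subseeds(config$seed)[["survival"]]
  for (try in 0:5) {
    set.seed((seed0 + try) %% .Machine$integer.max)
    t_event <- stats::rexp(np, rate = h)
    if (cr >= 1) {
      time <- stats::rexp(np, rate = mean(h))      # observation window only
      event <- rep(0L, np)
    } else if (cr == 0) {
      time <- t_event
      event <- rep(1L, np)
    } else {
      c_rate <- mean(h) * cr / (1 - cr)
      t_cens <- stats::rexp(np, rate = c_rate)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    if (any(event == 1) || cr >= 1) break
  }
  if (all(event == 0))
    warning("all patients censored; check 'censoring_rate' and hazards")
  data.frame(patient_id = patients, time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic multi-region cohort
#'
#' Runs the coordinate, expression, mutation and survival generators under
#' one master seed (each component on its own named sub-stream) and bundles
#' the result with the generating ground truth.
#'
#' @param config a [sim_config()].
#' @return A `synthetic_cohort` list: `expression` (genes x samples TPM
#'   matrix), `meta`, `coordinates`, `mutations`, `survival`, and `truth`
#'   (per-gene `sigma_between`, `sigma_within`, within-ratio
#'   `r = s2w / (s2w + s2b)` and survival `beta`; per-patient dispersion
#'   multipliers).
#' @examples
#' cfg <- sim_config(n_patients = 4, regions_per_patient = 3, n_genes = 20,
#'                   seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$expression)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  coords <- generate_coordinates(config)
  expr <- generate_expression(config, coords)
  muts <- generate_mutations(config, coords)
  surv <- generate_survival(config, expr)

  s2b <- config$sigma_between^2
  s2w <- config$sigma_within^2
  r <- ifelse(s2b + s2w > 0, s2w / (s2w + s2b), NA_real_)
  beta <- stats::setNames(rep(0, config$n_genes), config$genes)
  beta[names(config$survival_beta)] <- config$survival_beta

  truth <- list(
    genes = data.frame(gene = config$genes,
                       sigma_between = config$sigma_between,
                       sigma_within = config$sigma_within,
                       within_ratio = r,
                       beta = beta,
                       stringsAsFactors = FALSE, row.names = NULL),
    patients = data.frame(patient_id = unique(coords$patient_id),
                          dispersion = attr(coords, "dispersion"),
                          stringsAsFactors = FALSE))
  structure(list(expression = expr$tpm,
                 log2_expression = expr$log2,
                 meta = expr$meta,
                 coordinates = coords,
                 mutations = muts,
                 survival = surv,
                 truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-region cohort:",
      length(unique(x$meta$patient_id)), "patients,",
      nrow(x$meta), "samples,", nrow(x$expression), "genes\n")
  invisible(x)
}

#' Write a synthetic cohort to plain-text tables
#'
#' Writes expression (genes x samples TSV), metadata, coordinates, long-form
#' variants, survival and the truth table into a directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$coordinates[, c("sample_id", "x_cm", "y_cm")],
                     file.path(dir, "coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vl <- lapply(names(cohort$mutations), function(s) {
    keys <- cohort$mutations[[s]]
    if (!length(keys)) return(NULL)
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    data.frame(sample_id = s, chrom = parts[, 1],
               pos = as.integer(parts[, 2]),
               ref = parts[, 3], alt = parts[, 4],
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, vl), file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
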