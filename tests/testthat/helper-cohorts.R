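# Shared fixtures, built in code and cached per test run.

# Small default-structure cohort for module-level checks.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config(
        n_patients = 6, regions_per_patient = 5, n_genes = 120, seed = 42))
    cache
  }
})

# Single-gene survival cohort generator: patient expression ~ N(0, 1),
# exponential proportional-hazards times, independent exponential censoring.
make_surv_cohort <- function(n, betas, seed, h0 = 0.05, cens = 0.2,
                             name = "train") {
  set.seed(seed)
  genes <- names(betas)
  x <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
              dimnames = list(genes, sprintf("%s_pt%d", name, seq_len(n))))
  lp <- as.numeric(crossprod(x, betas))
  t_ev <- stats::rexp(n, rate = h0 * exp(lp))
  if (cens > 0) {
    t_c <- stats::rexp(n, rate = h0 * cens / (1 - cens))
    ev <- as.integer(t_ev <= t_c)
    tt <- pmin(t_ev, t_c)
  } else {
    ev <- rep(1L, n); tt <- t_ev
  }
  survival_cohort(x, data.frame(patient_id = colnames(x), time = tt,
                                event = ev, stringsAsFactors = FALSE),
                  name = name)
}

# A feature matrix in which every patient's samples are identical and
# patient centroids are well separated: the perfect co-clustering case.
perfect_signature_matrix <- function(n_patients = 16, samples_each = 2,
                                     n_features = 5, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_patients * n_features, sd = 10),
                    n_patients, n_features)
  x <- centers[rep(seq_len(n_patients), each = samples_each), , drop = FALSE]
  list(x = x,
       patients = rep(sprintf("P%02d", seq_len(n_patients)),
                      each = samples_each))
}
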