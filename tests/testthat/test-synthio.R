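test_that("invalid configurations are rejected", {
  expect_error(sim_config(regions_per_patient = 1), ">= 2")
  expect_error(sim_config(sigma_within = -1), ">= 0")
  expect_error(sim_config(spatial_fraction = 1.5), "spatial_fraction")
  expect_error(sim_config(tumor_radius = 0), "tumor_radius")
})

test_that("identical config + seed gives bit-identical cohorts", {
  cfg <- sim_config(n_patients = 4, regions_per_patient = 4, n_genes = 40,
                    seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$coordinates, b$coordinates)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$survival, b$survival)
  d <- simulate_cohort(sim_config(n_patients = 4, regions_per_patient = 4,
                                  n_genes = 40, seed = 100))
  expect_false(identical(a$expression, d$expression))
})

test_that("zero-variance genes collapse as expected", {
  cfg <- sim_config(n_patients = 3, regions_per_patient = 4, n_genes = 5,
                    sigma_within = 0, sigma_between = 1, seed = 2)
  ex <- generate_expression(cfg)
  for (p in unique(ex$meta$patient_id)) {
    block <- ex$tpm[, ex$meta$patient_id == p, drop = FALSE]
    expect_equal(apply(block, 1, function(v) max(v) - min(v)), # all regions equal
                 setNames(rep(0, 5), rownames(block)))
  }
  cfg0 <- sim_config(n_patients = 3, regions_per_patient = 4, n_genes = 5,
                     sigma_within = 0, sigma_between = 0, seed = 2)
  ex0 <- generate_expression(cfg0)
  expect_equal(max(ex0$tpm) - min(ex0$tpm), 0)  # every sample identical
})

test_that("between/within variances recover configured values (moment oracle)", {
  sw <- c(0.4, 0.9); sb <- c(1.2, 0.3)
  cfg <- sim_config(n_patients = 220, regions_per_patient = 5, n_genes = 2,
                    sigma_within = sw, sigma_between = sb,
                    spatial_fraction = 0, seed = 7)
  ex <- generate_expression(cfg)
  lg <- log2(ex$tpm + 1)
  for (g in 1:2) {
    est <- itvs(lg[g, ], ex$meta$patient_id, method = "moments")
    expect_equal(est$W, sw[g]^2, tolerance = 0.12)
    expect_equal(est$B, sb[g]^2, tolerance = 0.15)
  }
})

test_that("with spatial_fraction = 0, coordinates do not shape expression", {
  cfg <- sim_config(n_patients = 4, regions_per_patient = 5, n_genes = 30,
                    spatial_fraction = 0, seed = 13)
  co <- generate_coordinates(cfg)
  perm <- co
  for (p in unique(co$patient_id)) {              # shuffle coords within tumor
    idx <- which(co$patient_id == p)
    sh <- sample(idx)
    perm[idx, c("x_cm", "y_cm")] <- co[sh, c("x_cm", "y_cm")]
  }
  expect_identical(generate_expression(cfg, co)$tpm,
                   generate_expression(cfg, perm)$tpm)
})

test_that("coordinates respect the disc radius, spacing and dispersion", {
  cfg <- sim_config(n_patients = 10, regions_per_patient = 10,
                    tumor_radius = 3, min_spacing = 0.5, seed = 21)
  co <- generate_coordinates(cfg)
  for (p in unique(co$patient_id)) {
    d <- pairwise_physical_distance(co, p)
    expect_lte(max(d), 6)                          # diameter bound
    expect_gte(min(d[upper.tri(d)]), 0.5)
  }
  cfg0 <- sim_config(n_patients = 2, regions_per_patient = 4,
                     dispersion = 0, seed = 21)
  co0 <- generate_coordinates(cfg0)
  expect_equal(max(abs(c(co0$x_cm, co0$y_cm))), 0)
  expect_equal(physical_diversity(co0, "P01"), 0)
  # infeasible spacing errors after bounded retries
  expect_error(generate_coordinates(
    sim_config(n_patients = 1, regions_per_patient = 10, tumor_radius = 0.1,
               min_spacing = 0.5, seed = 1)), "could not place")
})

test_that("mutation profiles follow the trunk/private clonal model", {
  cfg <- sim_config(n_patients = 3, regions_per_patient = 4,
                    n_trunk_mutations = 20, n_private_mutations = 0, seed = 5)
  mu <- generate_mutations(cfg)
  co <- generate_coordinates(cfg)
  ids <- co$sample_id[co$patient_id == "P01"]
  expect_equal(genomic_diversity(mu[ids]), 0)      # identical sets

  cfg2 <- sim_config(n_patients = 3, regions_per_patient = 4,
                     n_trunk_mutations = 0, n_private_mutations = 10,
                     mutation_sharing_range = 0, seed = 5)
  mu2 <- generate_mutations(cfg2)
  d2 <- pairwise_genomic_distance(mu2[ids])
  expect_equal(unname(d2[upper.tri(d2)]), rep(1, 6))  # disjoint private sets
})

test_that("Jaccard distance increases with physical distance within tumors", {
  cfg <- sim_config(n_patients = 10, regions_per_patient = 6,
                    n_trunk_mutations = 50, n_private_mutations = 40,
                    mutation_sharing_range = 1.5, seed = 31)
  co <- generate_coordinates(cfg)
  mu <- generate_mutations(cfg, co)
  pos <- vapply(unique(co$patient_id), function(p) {
    ids <- co$sample_id[co$patient_id == p]
    dp <- pairwise_physical_distance(co, p)
    dg <- pairwise_genomic_distance(mu[ids])
    cor(dp[upper.tri(dp)], dg[upper.tri(dg)], method = "spearman") > 0
  }, logical(1))
  expect_gte(sum(pos), 9)
})

test_that("survival generator recovers effect directions", {
  beta <- c(g1 = 0.8)
  cfg <- sim_config(n_patients = 300, regions_per_patient = 2, n_genes = 3,
                    survival_beta = beta, censoring_rate = 0.2, seed = 17)
  coh <- simulate_cohort(cfg)
  lg <- log2(coh$expression + 1)
  pm <- vapply(coh$survival$patient_id, function(p)
    mean(lg["g1", coh$meta$patient_id == p]), numeric(1))
  fit <- survival::coxph(
    survival::Surv(coh$survival$time, coh$survival$event) ~ scale(pm))
  expect_gt(exp(coef(fit)), 1)
  expect_lt(summary(fit)$coefficients[1, 5], 0.05)

  # null gene: HR close to 1 at large n
  cfg0 <- sim_config(n_patients = 300, regions_per_patient = 2, n_genes = 3,
                     survival_beta = c(g2 = 0), censoring_rate = 0.2,
                     seed = 18)
  coh0 <- simulate_cohort(cfg0)
  lg0 <- log2(coh0$expression + 1)
  pm0 <- vapply(coh0$survival$patient_id, function(p)
    mean(lg0["g3", coh0$meta$patient_id == p]), numeric(1))
  fit0 <- survival::coxph(
    survival::Surv(coh0$survival$time, coh0$survival$event) ~ scale(pm0))
  expect_lt(abs(coef(fit0)), 0.25)
})

test_that("censoring is near the configured rate; rate 1 warns", {
  cfg <- sim_config(n_patients = 400, regions_per_patient = 2, n_genes = 12,
                    censoring_rate = 0.3, seed = 23)
  coh <- simulate_cohort(cfg)
  expect_equal(mean(coh$survival$event == 0), 0.3, tolerance = 0.4)
  cfg1 <- sim_config(n_patients = 20, regions_per_patient = 2, n_genes = 12,
                     censoring_rate = 1, seed = 23)
  ex <- generate_expression(cfg1)
  expect_warning(s <- generate_survival(cfg1, ex), "censored")
  expect_true(all(s$event == 0))
})

test_that("cohort serialization round-trips through plain text", {
  coh <- simulate_cohort(sim_config(n_patients = 3, regions_per_patient = 3,
                                    n_genes = 15, seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ex <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(ex, coh$expression, tolerance = 1e-12)
  va <- read_variants(file.path(dir, "variants.tsv"))
  for (s in names(va))
    expect_setequal(va[[s]], coh$mutations[[s]])
  su <- read_survival(file.path(dir, "survival.tsv"))
  expect_equal(su$time, coh$survival$time, tolerance = 1e-12)
})
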