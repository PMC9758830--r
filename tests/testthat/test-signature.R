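test_that("low-ITH filter is strict at the boundary", {
  tab <- data.frame(feature = c("a", "b", "c", "d"),
                    ihs = c(0.10, 0.25, 0.249, NA))
  expect_equal(filter_low_ith(tab), c("a", "c"))   # 0.25 itself excluded
  tab2 <- data.frame(feature = "a", ihs = 0.5)
  expect_error(filter_low_ith(tab2), "relaxing")
})

test_that("the filter recovers genes simulated with low within-ratio", {
  r <- c(seq(0.02, 0.10, length.out = 60), seq(0.4, 0.95, length.out = 60))
  tot <- 1.5^2
  cfg <- sim_config(n_patients = 14, regions_per_patient = 8, n_genes = 120,
                    sigma_within = sqrt(r * tot),
                    sigma_between = sqrt((1 - r) * tot), seed = 88)
  coh <- simulate_cohort(cfg)
  tab <- ihs_table(coh$expression, coh$meta$patient_id)
  low <- coh$truth$genes$gene[coh$truth$genes$within_ratio < 0.1]
  flt <- filter_low_ith(tab, 0.25)
  expect_gte(mean(low %in% flt), 0.8)
})

test_that("Cox screen recovers directions and flags degenerate genes", {
  betas <- c(risky = 0.9, protect = -0.9, null1 = 0, flat = 0)
  co1 <- make_surv_cohort(250, betas, seed = 101, name = "c1")
  co2 <- make_surv_cohort(250, betas, seed = 102, name = "c2")
  co1$expression["flat", ] <- 1                   # constant expression
  co2$expression["flat", ] <- 1
  scr <- cox_screen(list(co1, co2), names(betas))
  expect_true("risky" %in% scr$risk)
  expect_true("protect" %in% scr$protective)
  expect_false("null1" %in% c(scr$risk, scr$protective))
  expect_true("flat" %in% scr$flagged)
})

test_that("Cox screen null calibration: pass rate near alpha per cohort", {
  betas <- setNames(rep(0, 200), sprintf("n%03d", 1:200))
  co <- make_surv_cohort(300, betas, seed = 201, name = "null")
  scr <- cox_screen(list(co), names(betas))
  rate <- (length(scr$risk) + length(scr$protective)) / 200
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
})

test_that("bootstrap screen saturates strong genes, drops null genes", {
  betas <- c(strong = 1.6, weak0 = 0)
  co <- make_surv_cohort(400, betas, seed = 55, cens = 0.1)
  bs <- bootstrap_stability(list(co), names(betas), n_boot = 60,
                            pass_fraction = 0.8, seed = 9)
  expect_equal(bs$counts$passes[bs$counts$gene == "strong"], 60)
  expect_lt(bs$counts$passes[bs$counts$gene == "weak0"], 0.4 * 60)
  expect_identical(bs$counts,
                   bootstrap_stability(list(co), names(betas), n_boot = 60,
                                       pass_fraction = 0.8, seed = 9)$counts)
})

test_that("forest search recovers informative genes among nulls", {
  betas <- setNames(c(1.2, -1.2, rep(0, 8)),
                    c("info_up", "info_dn", sprintf("nse%d", 1:8)))
  co <- make_surv_cohort(250, betas, seed = 77, cens = 0.1)
  fs <- forest_combination_search(list(co), names(betas),
                                  n_replicates = 3, num_trees = 300,
                                  seed = 5)
  expect_true(all(c("info_up", "info_dn") %in% fs$genes))
  expect_false(fs$low_confidence)
  expect_identical(
    fs$genes,
    forest_combination_search(list(co), names(betas), n_replicates = 3,
                              num_trees = 300, seed = 5)$genes)
})

test_that("signature score is the multivariate Cox linear predictor", {
  betas <- c(a = 0.8, b = -0.8, c = 0.4)
  co <- make_surv_cohort(200, betas, seed = 33, cens = 0.1)
  dat <- hetgeo:::pool_cohorts(list(co), names(betas))
  mv <- survival::coxph(survival::Surv(time, event) ~ a + b + c, data = dat)
  model <- structure(list(genes = names(betas),
                          weights = setNames(unname(coef(mv)), names(betas)),
                          direction = ifelse(coef(mv) > 0, "risk",
                                             "protective"),
                          score_rule = "linear"),
                     class = "signature_model")
  s <- signature_score(model, co$expression)
  lp <- as.numeric(predict(mv, newdata = dat, type = "lp"))
  expect_equal(unname(s - mean(s)), lp - mean(lp), tolerance = 1e-10)
  # invariant to gene order and unrelated genes in the matrix
  extra <- rbind(co$expression[c("c", "a", "b"), ],
                 junk = rnorm(ncol(co$expression)))
  expect_equal(signature_score(model, extra), s)
  expect_error(signature_score(model, co$expression[c("a", "b"), ]), "c")
})

test_that("time-dependent AUC: null marker near 0.5, perfect marker at 1", {
  set.seed(61)
  n <- 2000
  time <- rexp(n, 0.1); event <- rep(1L, n)
  noise <- rnorm(n)
  tt <- quantile(time, c(0.25, 0.5, 0.75))
  a0 <- td_auc(noise, time, event, tt)
  expect_true(all(abs(a0$auc - 0.5) < 0.06))
  # with no censoring the IPCW weights are flat: estimator must equal the
  # plain case/control concordance
  t1 <- tt[[1]]
  case <- which(time <= t1); ctrl <- which(time > t1)
  cmp <- outer(noise[case], noise[ctrl], function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(a0$auc[1], mean(cmp))
  a1 <- td_auc(-time, time, event, tt)      # score = -time, uncensored
  expect_equal(a1$auc, rep(1, 3))
})

test_that("prognostic evaluation separates a real signal from noise", {
  betas <- c(g_up = 1.0, g_noise = 0)
  co <- make_surv_cohort(300, betas, seed = 91, cens = 0.2, name = "eval")
  model <- structure(list(genes = "g_up", weights = c(g_up = 1),
                          direction = c(g_up = "risk"), score_rule = "linear"),
                     class = "signature_model")
  ev <- evaluate_prognosis(model, list(co))
  expect_gt(ev$hr, 1)
  expect_lt(ev$logrank_p, 0.01)
  expect_gt(ev$mean_auc, 0.6)
  null_model <- structure(list(genes = "g_noise", weights = c(g_noise = 1),
                               direction = c(g_noise = "risk"),
                               score_rule = "linear"),
                          class = "signature_model")
  ev0 <- evaluate_prognosis(null_model, list(co))
  expect_lt(abs(ev0$mean_auc - 0.5), 0.1)
})

test_that("mean AUC grows with the survival effect size", {
  aucs <- vapply(c(0, 0.7, 1.6), function(b) {
    co <- make_surv_cohort(250, c(g = b), seed = 120, cens = 0.2)
    model <- structure(list(genes = "g", weights = c(g = 1),
                            direction = c(g = "risk"), score_rule = "linear"),
                       class = "signature_model")
    evaluate_prognosis(model, list(co))$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("zero-ITH signatures give concordant calls and a full PGOR curve", {
  ng <- 40
  cfg <- sim_config(n_patients = 8, regions_per_patient = 4, n_genes = ng,
                    sigma_within = c(rep(0, 5), rep(0.6, ng - 5)),
                    sigma_between = 1.5, seed = 55)
  coh <- simulate_cohort(cfg)
  sig_genes <- sprintf("g%d", 1:5)          # the zero-within-variance genes
  ihs_tab <- ihs_table(coh$expression[1:10, ], coh$meta$patient_id)
  model <- structure(list(genes = sig_genes,
                          weights = setNames(rep(1, 5), sig_genes),
                          direction = setNames(rep("risk", 5), sig_genes),
                          score_rule = "linear"),
                     class = "signature_model")
  rb <- evaluate_ith_robustness(model, coh$expression, coh$meta, ihs_tab)
  expect_equal(rb$discordant_prop, 0)
  expect_equal(rb$pgor_auc, rb$P - 1)       # perfect co-clustering
  expect_lt(rb$median_ihs, 0.25)

  # contrast: structure-free signature scores poorly on the same cohort
  set.seed(7)
  free <- matrix(2^rnorm(5 * nrow(coh$meta), mean = 4), nrow = 5,
                 dimnames = list(sprintf("rnd%d", 1:5), coh$meta$sample_id))
  expr2 <- rbind(coh$expression, free)
  tab2 <- ihs_table(free, coh$meta$patient_id)
  model2 <- structure(list(genes = rownames(free),
                           weights = setNames(rep(1, 5), rownames(free)),
                           direction = setNames(rep("risk", 5),
                                                rownames(free)),
                           score_rule = "linear"),
                      class = "signature_model")
  rb2 <- evaluate_ith_robustness(model2, expr2, coh$meta, tab2)
  expect_gt(rb2$discordant_prop, rb$discordant_prop)
  expect_lt(rb2$pgor_auc, rb$pgor_auc)
})

test_that("end-to-end signature build is deterministic and serializable", {
  betas <- setNames(c(1.0, -1.0, rep(0, 4)),
                    c("gA", "gB", sprintf("gN%d", 1:4)))
  co1 <- make_surv_cohort(200, betas, seed = 301, name = "tr1")
  co2 <- make_surv_cohort(200, betas, seed = 302, name = "tr2")
  ihs_tab <- data.frame(feature = names(betas),
                        ihs = c(0.1, 0.12, 0.15, 0.2, 0.22, 0.24))
  m1 <- build_signature(list(co1, co2), ihs_tab, n_boot = 40,
                        pass_fraction = 0.7, n_replicates = 2,
                        num_trees = 200, seed = 11)
  m2 <- build_signature(list(co1, co2), ihs_tab, n_boot = 40,
                        pass_fraction = 0.7, n_replicates = 2,
                        num_trees = 200, seed = 11)
  expect_identical(m1$genes, m2$genes)
  expect_equal(m1$weights, m2$weights)
  expect_true(all(c("gA", "gB") %in% m1$genes))
  expect_equal(unname(m1$direction[c("gA", "gB")]), c("risk", "protective"))

  f <- withr::local_tempfile(fileext = ".json")
  write_signature(m1, f)
  m3 <- read_signature(f)
  expect_equal(m3$genes, m1$genes)
  expect_equal(m3$weights, m1$weights, tolerance = 1e-12)
})
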