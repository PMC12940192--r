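test_that("genotype priors implement the relatedness hypotheses", {
  fq <- toy_freqs()
  pop0 <- population_model(0)
  ref <- genotype(list(L1 = c("10", "10"), L2 = c("8", "9")))
  # parent-child with a homozygous reference: the obligate allele is certain
  gp <- genotype_prior(relatedness_prior("parent-child", ref), "L1", fq, pop0)
  has10 <- gp$a1 == "10" | gp$a2 == "10"
  expect_equal(sum(gp$prob[has10]), 1)
  expect_equal(sum(gp$prob), 1)
  # unrelated at theta = 0: Hardy-Weinberg
  gu <- genotype_prior(relatedness_prior("unrelated", ref), "L1", fq, pop0)
  p <- fq$L1
  for (i in seq_len(nrow(gu))) {
    expected <- if (gu$a1[i] == gu$a2[i]) p[[gu$a1[i]]]^2
    else 2 * p[[gu$a1[i]]] * p[[gu$a2[i]]]
    expect_equal(gu$prob[i], unname(expected))
  }
  # normalisation holds with theta > 0 too
  popt <- population_model(0.05)
  for (rel in c("parent-child", "unrelated")) {
    g <- genotype_prior(relatedness_prior(rel, ref), "L2", fq, popt)
    expect_equal(sum(g$prob), 1)
  }
})

test_that("locus log-likelihoods reproduce the model factors", {
  kit <- toy_kit()
  fq <- toy_freqs()
  params <- continuous_params(mu = 500, omega = 0.3, beta = 0.9,
                              xi_b = 0.05, xi_f = 0.01, lambda = 0.05,
                              p_c = 0.05)
  # pure drop-in peak at the threshold: factor p_c * p_a * lambda * exp(0),
  # times the drop-out factors of the unobserved genotype contributions
  fl <- locus_frequencies(fq, "L1", character(), population_model())
  pr <- make_rep(list(L1 = list(alleles = "10", heights = 50)), kit = kit)
  ll <- locus_loglik(list(pr), "L1", c("12", "12"), params, kit, fq)
  dropin <- 0.05 * fl[["10"]] * 0.05
  w11 <- 2 * params$xi_b * params$beta^((allele_size(kit, "L1", 11) - 125) / 100)
  w12 <- 2 * (1 - params$xi_b - params$xi_f) *
    params$beta^((allele_size(kit, "L1", 12) - 125) / 100)
  w13 <- 2 * params$xi_f * params$beta^((allele_size(kit, "L1", 13) - 125) / 100)
  expected <- log(dropin) +
    sum(stats::pgamma(50, shape = c(w11, w12, w13) / 0.09,
                      scale = 500 * 0.09, log.p = TRUE))
  expect_equal(ll, expected, tolerance = 1e-12)

  # censored-gamma drop-out factor verified against quadrature
  pr2 <- make_rep(list(L1 = list(alleles = "10", heights = 400)), kit = kit)
  par2 <- continuous_params(mu = 500, omega = 0.3, beta = 1,
                            xi_b = 0, xi_f = 0, lambda = 0.05, p_c = 0.05)
  ll2 <- locus_loglik(list(pr2), "L1", c("10", "11"), par2, kit, fq)
  lik_oracle <- oracle_cont_lik(list(pr2$peaks$L1), "L1", c("10", "11"),
                                par2, kit, fl)
  expect_equal(ll2, log(lik_oracle), tolerance = 1e-9)

  # two replicates: log-likelihoods add
  ll_two <- locus_loglik(list(pr2, pr2), "L1", c("10", "11"), par2, kit, fq)
  expect_equal(ll_two, 2 * ll2 , tolerance = 1e-12)
})

test_that("the vectorised likelihood agrees with the direct implementation", {
  set.seed(51)
  kit <- toy_kit()
  fq <- toy_freqs()
  cfgp <- continuous_params(mu = 300, omega = 0.4, beta = 0.7, xi_b = 0.06,
                            xi_f = 0.01, lambda = 0.04, p_c = 0.05)
  g <- genotype(list(L1 = c("10", "11"), L2 = c("9", "9")))
  reps <- lapply(1:2, function(i)
    simulate_replicate(g, kit, cfgp, fq, replicate_id = i))
  ref <- genotype(list(L1 = c("10", "12"), L2 = c("9", "10")))
  pop <- population_model(0.01)
  for (rel in c("parent-child", "unrelated")) {
    prior <- relatedness_prior(rel, ref)
    sup <- strkin:::.build_supports(reps, prior, fq, pop)
    skel <- strkin:::.cont_skeleton(reps, sup, list(K = kit),
                                    c(K = cfgp$lambda), cfgp$p_c, fq, pop)
    pars <- list(mu = cfgp$mu, om = cfgp$omega, beta = cfgp$beta,
                 xib = cfgp$xi_b, xif = cfgp$xi_f)
    ev <- strkin:::.cont_eval(skel, pars)
    # direct route: genotype-by-genotype locus_loglik, marginalised by hand
    for (li in seq_along(skel$loci)) {
      l <- skel$loci[li]
      direct <- 0
      for (gi in seq_len(nrow(sup[[l]]))) {
        gg <- c(sup[[l]]$a1[gi], sup[[l]]$a2[gi])
        direct <- direct + sup[[l]]$prob[gi] *
          exp(locus_loglik(reps, l, gg, cfgp, kit, fq))
      }
      expect_equal(ev$per_locus[li], log(direct), tolerance = 1e-10)
    }
    # the fast per-combo path agrees with the general evaluator
    prep <- strkin:::.prep_combo(skel, list(degradation = TRUE, xi_b = TRUE,
                                            xi_f = TRUE))
    expect_equal(strkin:::.cont_eval_fast(skel, prep, pars), ev$total,
                 tolerance = 1e-12)
  }
})

test_that("drop-in rates are recovered by the closed-form exponential MLE", {
  expect_equal(fit_dropin_lambda(c(60, 70, 80), at = 50)$lambda, 0.05)
  expect_error(fit_dropin_lambda(numeric()), "no drop-in")
  expect_error(fit_dropin_lambda(c(50, 50), at = 50), "zero mean")
  set.seed(52)
  h <- 50 + stats::rexp(1e4, rate = 0.038)
  est <- fit_dropin_lambda(h, at = 50)
  se <- 0.038 / sqrt(1e4)
  expect_lt(abs(est$lambda - 0.038), 3 * se)
  expect_true(est$ci[1] < 0.038 && 0.038 < est$ci[2])
})

test_that("the MLE recovers simulated parameters and is deterministic", {
  set.seed(53)
  n_loci <- 60
  kit <- synthetic_kit("R", paste0("M", 1:n_loci),
                       stats::setNames(round(seq(80, 380, length.out = n_loci)),
                                       paste0("M", 1:n_loci)))
  fr <- allele_frequencies(stats::setNames(
    rep(list(c(`10` = 0.2, `11` = 0.3, `12` = 0.3, `13` = 0.2)), n_loci),
    kit$loci))
  truth <- continuous_params(mu = 1000, omega = 0.3, beta = 0.8,
                             xi_b = 0, xi_f = 0, lambda = 0.04, p_c = 0)
  g <- genotype(lapply(fr, function(p) sample(names(p), 2, prob = p)))
  pr <- simulate_replicate(g, kit, truth, fr)
  fit <- fit_mle(list(pr), flags = list(degradation = TRUE, xi_b = FALSE,
                                        xi_f = FALSE),
                 kits = list(R = kit), freqs = fr,
                 lambda_by_kit = c(R = 0.04), p_c = 0.05,
                 genotypes = g, n_starts = 2, seed = 7)
  expect_lt(abs(fit$params$R$mu / 1000 - 1), 0.15)
  expect_lt(abs(fit$params$R$beta - 0.8), 0.07)
  expect_equal(fit$adjusted, fit$loglik - 3)
  fit2 <- fit_mle(list(pr), flags = list(degradation = TRUE, xi_b = FALSE,
                                         xi_f = FALSE),
                  kits = list(R = kit), freqs = fr,
                  lambda_by_kit = c(R = 0.04), p_c = 0.05,
                  genotypes = g, n_starts = 2, seed = 7)
  expect_identical(fit$params, fit2$params)   # same seed, same result
})

test_that("the artefact-free reduced model matches a closed-form gamma fit", {
  # tall clean heterozygotes, flags off: every peak is a single-copy gamma
  # draw, so the profile loglik equals the pooled gamma MLE loglik plus the
  # (negligible) censoring and constant drop-in terms
  set.seed(54)
  n_loci <- 80
  kit <- synthetic_kit("R", paste0("M", 1:n_loci),
                       stats::setNames(rep(117, n_loci), paste0("M", 1:n_loci)))
  fr <- allele_frequencies(stats::setNames(
    rep(list(c(`2` = 0.5, `6` = 0.5)), n_loci), kit$loci))
  truth <- continuous_params(mu = 3000, omega = 0.25, beta = 1,
                             xi_b = 0, xi_f = 0, p_c = 0)
  g <- genotype(stats::setNames(rep(list(c("2", "6")), n_loci), kit$loci))
  pr <- simulate_replicate(g, kit, truth, fr)
  fit <- fit_mle(list(pr), flags = list(degradation = FALSE, xi_b = FALSE,
                                        xi_f = FALSE),
                 kits = list(R = kit), freqs = fr,
                 lambda_by_kit = c(R = 0.04), p_c = 0.05,
                 genotypes = g, n_starts = 2, seed = 3)
  h <- unlist(lapply(pr$peaks, `[[`, "height"))
  gm <- MASS::fitdistr(h, "gamma")
  ll_gamma <- gm$loglik
  ll_fit <- fit$loglik - n_loci * log(1 - 0.05)   # remove drop-in constants
  expect_lt(abs(ll_fit - ll_gamma), 2)
  expect_lt(abs(fit$params$R$mu / mean(h) - 1), 0.05)
})

test_that("likelihood-ratio invariants hold", {
  set.seed(55)
  kit <- toy_kit()
  fq <- toy_freqs()
  pop <- population_model(0.01)
  cfgp <- md_preset()
  g <- genotype(list(L1 = c("10", "11"), L2 = c("9", "11")))
  reps <- lapply(1:2, function(i)
    simulate_replicate(g, kit, cfgp, fq, replicate_id = i))
  ref <- genotype(list(L1 = c("10", "12"), L2 = c("9", "9")))
  # identical priors on both sides: LR is exactly 1
  mk_fit <- function() {
    sup <- strkin:::.build_supports(reps, relatedness_prior("unrelated", ref),
                                    fq, pop)
    skel <- strkin:::.cont_skeleton(reps, sup, list(K = kit),
                                    c(K = 0.04), 0.05, fq, pop)
    strkin:::.fit_core(skel, list(degradation = FALSE, xi_b = TRUE,
                                  xi_f = FALSE), 2, 5, 400)
  }
  f_hp <- mk_fit()
  f_hd <- mk_fit()
  expect_identical(exp(f_hp$loglik - f_hd$loglik), 1)
  # an uninformative locus (no peaks anywhere, reference untyped) is skipped
  # and leaves the result unchanged
  kit3 <- toy_kit(c("L1", "L2", "L3"), c(L1 = 100, L2 = 220, L3 = 150))
  reps3 <- lapply(reps, function(r) {
    r$loci <- kit3$loci
    r
  })
  lr1 <- select_model_and_lr(reps, ref, list(K = kit), fq, pop,
                             lambda_by_kit = c(K = 0.04),
                             fixed_flags = list(degradation = TRUE,
                                                xi_b = TRUE, xi_f = FALSE),
                             n_starts = 2, seed = 9)
  lr3 <- select_model_and_lr(reps3, ref, list(K = kit3), fq, pop,
                             lambda_by_kit = c(K = 0.04),
                             fixed_flags = list(degradation = TRUE,
                                                xi_b = TRUE, xi_f = FALSE),
                             n_starts = 2, seed = 9)
  expect_equal(lr3$log10_lr, lr1$log10_lr, tolerance = 1e-6)
})

test_that("duplicating the kit label matches doubling the replicates", {
  # multi-kit combination consistency: two identical kits with one replicate
  # each give the same LR as one kit with both replicates
  set.seed(56)
  kit <- toy_kit()
  kitB <- kit
  kitB$kit_id <- "K2"
  fq <- toy_freqs()
  pop <- population_model(0.01)
  g <- genotype(list(L1 = c("10", "11"), L2 = c("9", "11")))
  reps <- lapply(1:2, function(i)
    simulate_replicate(g, kit, md_preset(), fq, replicate_id = i))
  ref <- genotype(list(L1 = c("10", "12"), L2 = c("9", "9")))
  flags <- list(degradation = FALSE, xi_b = TRUE, xi_f = FALSE)
  one <- select_model_and_lr(reps, ref, list(K = kit), fq, pop,
                             lambda_by_kit = c(K = 0.04),
                             fixed_flags = flags, n_starts = 3, seed = 2)
  repsB <- reps
  repsB[[2]]$kit_id <- "K2"
  two <- select_model_and_lr(repsB, ref, list(K = kit, K2 = kitB), fq, pop,
                             lambda_by_kit = c(K = 0.04, K2 = 0.04),
                             fixed_flags = flags, n_starts = 3, seed = 2)
  expect_lt(abs(two$log10_lr - one$log10_lr), 0.15)
})

test_that("PP-plot validation is calibrated under the model and flags mutant loci", {
  kits <- demo_kits()
  freqs <- demo_frequencies()
  pop <- population_model(0.01)
  devs <- numeric()
  flagged <- logical()
  for (s in 1:8) {
    sim <- simulation_config(seed = 700 + s, fraction_hd = 0,
                             fraction_trio = 0)
    case <- generate_case(sim, case_index = 1)
    ref <- case$references$child
    res <- select_model_and_lr(case$replicates[1:2], ref, kits, freqs, pop,
                               lambda_by_kit = sim$lambda_by_kit,
                               fixed_flags = list(degradation = FALSE,
                                                  xi_b = TRUE, xi_f = FALSE),
                               n_starts = 2, seed = s)
    v <- validate_model(res$fit_hp)
    devs <- c(devs, v$max_deviation)
    flagged <- c(flagged, length(v$outlier_loci) > 0)
  }
  expect_gte(mean(devs < 0.15), 0.7)

  # a father-child mutation makes the affected locus stand out
  hits <- 0
  n_runs <- 8
  for (s in seq_len(n_runs)) {
    sim <- simulation_config(seed = 800 + s, fraction_hd = 0,
                             fraction_trio = 0)
    case <- generate_case(sim, case_index = 1)
    ref <- case$references$child
    # inject a mutation at a locus where the father is heterozygous with
    # well-separated alleles: the model is then forced to call one of his
    # tall peaks a drop-in, which the PP plot exposes. (A one-repeat
    # mutant hides in the stutter channel, adjacent heterozygotes let the
    # fitted stutter proportion absorb the mismatch, and a
    # homozygous-father mismatch surfaces as a drop-out of an expected
    # allele, which a peak-based PP plot cannot show.)
    l <- NULL
    for (cand in kits$ESI$loci) {
      fa <- as.numeric(case$truth$genotypes$father[[cand]])
      if (abs(fa[1] - fa[2]) >= 2) { l <- cand; break }
    }
    p <- freqs[[l]]
    far <- names(p)[vapply(as.numeric(names(p)), function(a)
      min(abs(a - fa)) >= 2, TRUE)]
    mut <- far[which.max(vapply(as.numeric(far), function(a)
      min(abs(a - fa)), 0))]
    ref[[l]] <- c(mut, mut)   # visible mismatch: no shared allele remains
    res <- select_model_and_lr(case$replicates[1:2], ref, kits, freqs, pop,
                               lambda_by_kit = sim$lambda_by_kit,
                               fixed_flags = list(degradation = FALSE,
                                                  xi_b = TRUE, xi_f = FALSE),
                               n_starts = 2, seed = s)
    v <- validate_model(res$fit_hp)
    if (l %in% v$outlier_loci) hits <- hits + 1
  }
  expect_gt(hits / n_runs, 0.5)

  # degenerate single-peak input stays in bounds
  kit <- toy_kit("L1", c(L1 = 100))
  fq1 <- allele_frequencies(list(L1 = c(`10` = 0.5, `11` = 0.5)))
  pr <- make_rep(list(L1 = list(alleles = "10", heights = 200)), kit = kit)
  fit <- fit_mle(list(pr), flags = list(degradation = FALSE, xi_b = FALSE,
                                        xi_f = FALSE),
                 kits = list(K = kit), freqs = fq1,
                 lambda_by_kit = c(K = 0.04), p_c = 0.05,
                 genotypes = genotype(list(L1 = c("10", "10"))),
                 n_starts = 2, seed = 1)
  v1 <- validate_model(fit)
  expect_equal(nrow(v1$table), 1L)
  expect_true(v1$table$model_prob > 0 && v1$table$model_prob < 1)
})
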