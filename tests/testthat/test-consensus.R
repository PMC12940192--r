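test_that("drop-out logistic regression recovers known coefficients", {
  # flat response: drop-out probability 0.5 regardless of height
  set.seed(31)
  n <- 2000
  h <- 10^stats::runif(n, 1.8, 3.2)
  cal <- data.frame(locus = "L1", allele = "10",
                    detected = stats::runif(n) < 0.5,
                    partner_height = h, partner_detected = TRUE)
  m <- fit_dropout_logistic(cal, "K")
  expect_lt(abs(m$b1), 3 * m$fit$se[2])
  expect_lt(abs(predict_dropout(m, 150) - 0.5), 0.05)

  # parameter recovery at (b0, b1) = (6, -4), n = 5000
  set.seed(32)
  n <- 5000
  h <- 10^stats::runif(n, 1.2, 3.0)
  pdrop <- stats::plogis(6 - 4 * log10(h))
  cal2 <- data.frame(locus = "L1", allele = "10",
                     detected = stats::runif(n) > pdrop,
                     partner_height = h, partner_detected = TRUE)
  m2 <- fit_dropout_logistic(cal2, "K")
  expect_lt(abs(m2$b0 - 6), 3 * m2$fit$se[1])
  expect_lt(abs(m2$b1 + 4), 3 * m2$fit$se[2])

  # degenerate input: all detected -> separation error
  cal3 <- cal2
  cal3$detected <- TRUE
  expect_error(fit_dropout_logistic(cal3, "K"), "calibration")
})

test_that("consensus construction follows the replicate-agreement rules", {
  kit <- toy_kit()
  m <- dropout_model("K", b0 = 6, b1 = -4)
  rep_of <- function(alleles, heights, id)
    make_rep(list(L1 = list(alleles = alleles, heights = heights)),
             kit = kit, replicate_id = id)

  # allele seen once only: locus not considered
  cons <- build_consensus(rep_of("10", 300, 1), rep_of(character(0), numeric(0), 2), m)
  expect_equal(cons$loci$L1$status, "excluded")
  cons <- build_consensus(rep_of("10", 300, 1), rep_of("11", 200, 2), m)
  expect_equal(cons$loci$L1$status, "excluded")

  # both replicates clean, single shared allele: highest peak drives d
  cons <- build_consensus(rep_of("10", 300, 1), rep_of("10", 250, 2), m)
  expect_equal(cons$loci$L1$status, "single")
  expect_equal(cons$loci$L1$height_used, 300)
  expect_equal(cons$loci$L1$d, predict_dropout(m, 300))

  # one replicate with an extra allele: the clean replicate's peak drives d
  cons <- build_consensus(rep_of(c("10", "11"), c(300, 200), 1),
                          rep_of("10", 250, 2), m)
  expect_equal(cons$loci$L1$alleles, "10")
  expect_equal(cons$loci$L1$height_used, 250)
  # order-swapped input uses the clean replicate regardless of position
  cons_sw <- build_consensus(rep_of("10", 250, 1),
                             rep_of(c("10", "11"), c(300, 200), 2), m)
  expect_equal(cons_sw$loci$L1$height_used, 250)

  # both replicates with different extras: lowest shared peak drives d
  cons <- build_consensus(rep_of(c("10", "11"), c(300, 200), 1),
                          rep_of(c("10", "12"), c(250, 90), 2), m)
  expect_equal(cons$loci$L1$alleles, "10")
  expect_equal(cons$loci$L1$height_used, 250)

  # full agreement on two alleles: consensus genotype, no drop-out
  cons <- build_consensus(rep_of(c("10", "11"), c(300, 200), 1),
                          rep_of(c("10", "11"), c(280, 150), 2), m)
  expect_equal(cons$loci$L1$status, "double")
  expect_equal(cons$loci$L1$alleles, c("10", "11"))
  expect_equal(cons$loci$L1$d, 0)

  # three reproducible alleles violate the single-source assumption
  r3a <- rep_of(c("10", "11", "12"), c(300, 250, 200), 1)
  r3b <- rep_of(c("10", "11", "12"), c(280, 240, 180), 2)
  expect_error(build_consensus(r3a, r3b, m), "single-source")
  expect_warning(cons <- build_consensus(r3a, r3b, m,
                                         on_conflict = "exclude"),
                 "excluded")
  expect_equal(cons$loci$L1$status, "excluded")
})

test_that("consensus allele sets are invariant to replicate order", {
  kit <- toy_kit()
  m <- flat_dropout_model(0.3)
  set.seed(33)
  cfg <- simulation_config(seed = 33)
  for (i in 1:5) {
    case <- generate_case(cfg, case_index = i)
    r1 <- filter_stutter(case$replicates[[1]])
    r2 <- filter_stutter(case$replicates[[2]])
    c12 <- suppressWarnings(build_consensus(r1, r2, m, on_conflict = "exclude"))
    c21 <- suppressWarnings(build_consensus(r2, r1, m, on_conflict = "exclude"))
    a12 <- lapply(c12$loci, `[[`, "alleles")
    a21 <- lapply(c21$loci, `[[`, "alleles")
    expect_identical(a12, a21)
  }
})

test_that("stutter filtering removes sub-ratio peaks at one-repeat positions", {
  kit <- toy_kit()
  pr <- make_rep(list(L1 = list(alleles = c("9", "10", "11"),
                                heights = c(40 + 5, 1000, 400)),
                      L2 = list(alleles = c("8", "9"),
                                heights = c(500, 450))),
                 kit = kit)
  f <- filter_stutter(pr, ratio = 0.15)
  expect_equal(f$peaks$L1$allele, c("10", "11"))  # 45 < 0.15*1000 removed
  expect_equal(f$peaks$L2$allele, c("8", "9"))    # balanced het untouched
})

test_that("degradation is classified by the largest low-drop-out amplicon", {
  kit <- synthetic_kit("K", c("S", "M", "L"), c(S = 60, M = 160, L = 280))
  m <- dropout_model("K", b0 = 6, b1 = -4)   # d < 5% above ~172 RFU
  mk <- function(hS, hM, hL) make_rep(list(
    S = list(alleles = "10", heights = hS),
    M = list(alleles = "10", heights = hM),
    L = list(alleles = "10", heights = hL)), kit = kit)
  # all tall: 5ST at the largest amplicon -> MD
  deg <- classify_degradation(list(mk(900, 800, 700)), m)
  expect_equal(deg$five_st_size, allele_size(kit, "L", 10))
  expect_equal(deg$class, "MD")
  # tall only below 200 bp, larger amplicons faint -> HD
  deg2 <- classify_degradation(list(mk(900, 120, 60)), m)
  expect_equal(deg2$five_st_size, allele_size(kit, "S", 10))
  expect_equal(deg2$class, "HD")
  # empty profile
  empty <- replicate_profile("s", "K", 1, list(), loci = kit$loci)
  deg3 <- classify_degradation(list(empty), m)
  expect_equal(deg3$five_st_size, 0)
  expect_equal(deg3$class, "HD")
  # per-replicate mode takes the weaker replicate
  deg4 <- classify_degradation(list(mk(900, 800, 700), mk(900, 120, 60)), m,
                               mode = "per-replicate")
  expect_equal(deg4$class, "HD")
})

test_that("informative loci are counted per method rule", {
  cons <- make_cons(list(L1 = list(alleles = c("10", "11")),
                         L2 = NULL,
                         L3 = list(alleles = "9", d = 0.2),
                         L4 = NULL))
  expect_equal(count_informative_loci(cons), 2L)

  kit <- toy_kit()
  r1 <- make_rep(list(L1 = list(alleles = "10", heights = 100)), kit = kit)
  r2 <- make_rep(list(L2 = list(alleles = "9", heights = 80)), kit = kit,
                 replicate_id = 2)
  # a locus appearing in only one replicate still counts in replicate mode
  expect_equal(count_informative_loci(list(r1, r2)), 2L)
  empty <- replicate_profile("s", "K", 1, list(), loci = kit$loci)
  expect_equal(count_informative_loci(list(empty)), 0L)
  # replicate-mode count is never below the consensus-mode count
  set.seed(34)
  cfg <- simulation_config(seed = 34)
  m <- flat_dropout_model(0.3)
  for (i in 1:5) {
    case <- generate_case(cfg, case_index = i)
    r1 <- filter_stutter(case$replicates[[1]])
    r2 <- filter_stutter(case$replicates[[2]])
    cons <- suppressWarnings(build_consensus(r1, r2, m,
                                             on_conflict = "exclude"))
    expect_gte(count_informative_loci(case$replicates[1:2]),
               count_informative_loci(cons))
  }
})

test_that("saturated profiles give full consensus and vanishing drop-out", {
  # with a huge template every heterozygote reaches two-allele consensus and
  # homozygotes get a single-allele consensus with d near 0
  kit <- toy_kit()
  freqs <- toy_freqs()
  params <- continuous_params(mu = 5e4, omega = 0.1, beta = 1,
                              xi_b = 0, xi_f = 0, p_c = 0)
  m <- dropout_model("K", b0 = 6, b1 = -4)
  g <- genotype(list(L1 = c("10", "11"), L2 = c("9", "9")))
  set.seed(35)
  r1 <- simulate_replicate(g, kit, params, freqs, replicate_id = 1)
  r2 <- simulate_replicate(g, kit, params, freqs, replicate_id = 2)
  cons <- build_consensus(r1, r2, m)
  expect_equal(cons$loci$L1$status, "double")
  expect_equal(cons$loci$L2$status, "single")
  expect_lt(cons$loci$L2$d, 1e-6)
})

test_that("drop-out models serialise to JSON and back", {
  m <- dropout_model("ESI", b0 = 5.5, b1 = -3.7, fit = list(n = 100))
  path <- withr::local_tempfile(fileext = ".json")
  write_dropout_model(m, path)
  m2 <- read_dropout_model(path)
  expect_equal(m2$b0, m$b0)
  expect_equal(m2$b1, m$b1)
  expect_equal(m2$kit_id, "ESI")
})
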