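# End-to-end study emulation: simulate a case cohort, run the binary
# consensus method and the continuous method (single-kit and multi-kit
# modes) on every case, classify degradation, and summarise LR
# distributions, threshold proportions, informative-locus counts and the
# paired statistical tests.

#' Study configuration
#'
#' @param n_cases cohort size.
#' @param seed base seed for the whole study.
#' @param threshold LR decision threshold (court acceptance), default 10,000.
#' @param sim a [simulation_config()]; its seed is overridden by `seed`.
#' @param n_starts optimizer starts used for the continuous fits.
#' @param calibration_n heterozygous locus amplifications simulated per kit
#'   to calibrate the drop-out logistic regression.
#' @param stutter_filter_ratio ratio of [filter_stutter()] applied to the
#'   binary arm's replicates before consensus.
#' @param maxit Nelder-Mead iteration cap per continuous fit.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_cases = 33, seed = 1, threshold = 1e4,
                         sim = simulation_config(), n_starts = 2,
                         calibration_n = 2000, maxit = 400,
                         stutter_filter_ratio = 0.15) {
  stopifnot(threshold > 0, n_cases >= 1)
  sim$seed <- seed
  sim$n_cases <- n_cases
  structure(list(n_cases = n_cases, seed = seed, threshold = threshold,
                 sim = sim, n_starts = n_starts,
                 calibration_n = calibration_n, maxit = maxit,
                 stutter_filter_ratio = stutter_filter_ratio),
            class = "study_config")
}

# log10 with clipping so degenerate LRs keep summaries finite.
clip_log10 <- function(lr, cap = 300) {
  x <- log10(lr)
  pmin(pmax(x, -cap), cap)
}

#' Calibrate drop-out models for a study
#'
#' Simulates a dilution-series calibration per kit -- heterozygous locus
#' amplifications at template amounts spanning a 16-fold range around the
#' highly-degraded preset, the standard validation design for drop-out
#' regression -- and fits the logistic drop-out model for each kit.
#' Deterministic given the config seed.
#'
#' @param config a [study_config()].
#' @return named list of [dropout_model()]s by kit id.
#' @export
calibrate_study_dropout <- function(config) {
  sim <- config$sim
  out <- list()
  dilution <- c(0.25, 0.5, 1, 2, 4)
  for (kid in names(sim$kits)) {
    set.seed(case_seed(config$seed, 900000L + match(kid, names(sim$kits))))
    n_level <- ceiling(config$calibration_n / length(dilution))
    cal <- do.call(rbind, lapply(dilution, function(m) {
      params <- hd_preset(lambda = unname(sim$lambda_by_kit[[kid]]))
      params$mu <- params$mu * m
      params$beta <- 0.5    # calibration series: moderate degradation
      generate_calibration_set(sim$kits[[kid]], params, n_level,
                               sim$freqs, sim$pop)
    }))
    out[[kid]] <- fit_dropout_logistic(cal, kit_id = kid)
  }
  out
}

#' Run all three LR methods on one case bundle
#'
#' Computes the binary consensus LR (duo view, plus the trio view when a
#' maternal genotype is present), the continuous single-kit LR on the
#' duplicate replicate pair with adjusted-loglikelihood model selection
#' ("EFM mode"), and the continuous multi-kit LR on one replicate per kit
#' with the single-kit flag selection carried over ("EFMrep mode"). Records
#' the informative-locus count under each method's counting rule and the
#' 5ST degradation call. Method failures are caught and recorded as NA.
#'
#' @param case a `case_bundle` from [generate_case()].
#' @param dropout_models named list of [dropout_model()]s by kit id.
#' @param config a [study_config()].
#' @return one-row data frame of per-case results.
#' @export
run_case_all_methods <- function(case, dropout_models, config) {
  sim <- config$sim
  dup <- case$dup_kit
  rep_pair <- case$replicates[1:2]
  rep_other <- case$replicates[[3]]
  dmodel <- dropout_models[[dup]]
  filtered <- lapply(rep_pair, filter_stutter,
                     ratio = config$stutter_filter_ratio)
  cons <- suppressWarnings(build_consensus(filtered[[1]], filtered[[2]],
                                           dmodel, on_conflict = "exclude"))
  deg <- classify_degradation(filtered, dmodel)
  role <- case$ltdna_role
  reference <- if (role == "father") case$references$child
  else case$references$father
  has_mother <- !is.null(case$references$mother)
  safe <- function(expr) tryCatch(expr, error = function(e) {
    warning(conditionMessage(e))
    NULL
  })

  bin_duo <- safe(paternity_lr(
    cons, case$references[setdiff(names(case$references), "mother")],
    binary_hypothesis(role, "duo"), sim$freqs, sim$pop))
  bin_trio <- if (has_mother) safe(paternity_lr(
    cons, case$references, binary_hypothesis(role, "trio"),
    sim$freqs, sim$pop)) else NULL

  efm <- safe(select_model_and_lr(
    rep_pair, reference, sim$kits, sim$freqs, sim$pop,
    lambda_by_kit = sim$lambda_by_kit, n_starts = config$n_starts,
    seed = case_seed(config$seed, 500000L + case$truth$seed %% 100000L),
    maxit = config$maxit))
  efmrep <- if (!is.null(efm)) safe(select_model_and_lr(
    list(rep_pair[[1]], rep_other), reference, sim$kits, sim$freqs, sim$pop,
    lambda_by_kit = sim$lambda_by_kit, fixed_flags = efm$flags,
    n_starts = config$n_starts,
    init_hp = efm$fit_hp$params, init_hd = efm$fit_hd$params,
    seed = case_seed(config$seed, 600000L + case$truth$seed %% 100000L),
    maxit = config$maxit)) else NULL

  data.frame(
    case_id = case$case_id,
    pedigree = case$pedigree,
    class = deg$class,
    class_preset = case$truth$class_preset,
    five_st_size = deg$five_st_size,
    case_kind = case$case_kind,
    dup_kit = dup,
    log10_binary_duo = if (is.null(bin_duo)) NA_real_
    else clip_log10(bin_duo$lr),
    log10_binary_trio = if (is.null(bin_trio)) NA_real_
    else clip_log10(bin_trio$lr),
    log10_efm = if (is.null(efm)) NA_real_ else clip_log10(efm$lr),
    log10_efmrep = if (is.null(efmrep)) NA_real_ else clip_log10(efmrep$lr),
    informative_binary = count_informative_loci(cons),
    informative_efm = count_informative_loci(rep_pair),
    informative_efmrep = count_informative_loci(
      list(rep_pair[[1]], rep_other)),
    flags_deg = if (is.null(efm)) NA else efm$flags$degradation,
    flags_xib = if (is.null(efm)) NA else efm$flags$xi_b,
    flags_xif = if (is.null(efm)) NA else efm$flags$xi_f,
    stringsAsFactors = FALSE)
}

#' Run the full simulated study
#'
#' Generates the cohort, calibrates per-kit drop-out models, runs every case
#' through all methods, and summarises. Fully deterministic given the
#' config seed.
#'
#' @param config a [study_config()].
#' @param progress print a progress line per case.
#' @return object of class `study_result` with elements `results` (per-case
#'   data frame), `summary` (see [summarize_study()]), `tests` (see
#'   [paired_tests()]) and `config`.
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  dropout_models <- calibrate_study_dropout(config)
  rows <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    case <- generate_case(config$sim, case_index = i)
    rows[[i]] <- run_case_all_methods(case, dropout_models, config)
    if (progress)
      message(sprintf("case %d/%d (%s %s) done", i, config$n_cases,
                      rows[[i]]$class, rows[[i]]$pedigree))
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = summarize_study(results, config),
                 tests = paired_tests(results),
                 dropout_models = dropout_models,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("Simulated study:", nrow(x$results), "cases\n")
  print(x$summary$table, digits = 3)
  invisible(x)
}

# The per-method log10 LR used for cross-method comparison: the binary arm
# uses the maternal genotype when available.
.method_cols <- function(results) {
  bin <- ifelse(results$pedigree == "trio", results$log10_binary_trio,
                results$log10_binary_duo)
  data.frame(binary = bin, efm = results$log10_efm,
             efmrep = results$log10_efmrep)
}

.informative_cols <- function(results) {
  data.frame(binary = results$informative_binary,
             efm = results$informative_efm,
             efmrep = results$informative_efmrep)
}

#' Summarise a study's results
#'
#' Per degradation class x pedigree stratum and method: the number of cases,
#' median log10 LR, proportion of LRs at or above the decision threshold,
#' mean and SD of the informative-locus count, and the share of cases in
#' which the method attains the stratum's highest LR (ties credited to every
#' tied method). Per stratum, the maximum cross-method spread of log10 LR
#' rounded half-up to whole orders of magnitude (the "delta LR max").
#'
#' @param results per-case data frame from [run_study()].
#' @param config a [study_config()] (threshold).
#' @return list with `table` (stratum x method rows), `delta_lr` (per
#'   stratum) and the threshold.
#' @export
summarize_study <- function(results, config) {
  thr <- log10(config$threshold)
  meth <- .method_cols(results)
  info <- .informative_cols(results)
  strata <- split(seq_len(nrow(results)),
                  paste(results$class, results$pedigree, sep = "-"))
  tab <- list()
  dl <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    if (length(idx) < 1L) next
    m <- meth[idx, , drop = FALSE]
    spread <- apply(m, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2L) NA_real_ else max(v) - min(v)
    })
    best <- apply(m, 1, function(v) {
      if (all(is.na(v))) return(rep(FALSE, length(v)))
      !is.na(v) & v >= max(v, na.rm = TRUE) - 1e-9
    })
    best <- matrix(best, nrow = ncol(m),
                   dimnames = list(colnames(m), NULL))
    dl[[s]] <- data.frame(
      stratum = s, n = length(idx),
      delta_lr_max = if (all(is.na(spread))) NA_real_
      else floor(max(spread, na.rm = TRUE) + 0.5))
    for (mm in colnames(m)) {
      v <- m[[mm]]
      ok <- !is.na(v)
      if (!any(ok)) next
      tab[[paste(s, mm)]] <- data.frame(
        stratum = s, method = mm, n = sum(ok),
        median_log10_lr = stats::median(v[ok]),
        prop_ge_threshold = mean(v[ok] >= thr),
        mean_informative = mean(info[idx, mm][ok]),
        sd_informative = stats::sd(info[idx, mm][ok]),
        best_method_share = mean(best[mm, ][ok]))
    }
  }
  rbind0 <- function(x) if (length(x))
    do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(table = rbind0(tab), delta_lr = rbind0(dl),
       threshold = config$threshold)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign patterns
# (valid with tied absolute differences); zero differences already removed.
.signed_rank_exact_p <- function(d) {
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ew <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-12)
}

#' Paired statistical tests across methods
#'
#' Within each stratum, two-sided Wilcoxon signed-rank tests on the paired
#' log10 LRs of every method pair (exact by sign-pattern enumeration for
#' n <= 12, which remains valid with tied differences; exact signed-rank
#' distribution for larger n up to 25 without ties; normal approximation
#' with continuity correction otherwise; all-zero difference vectors are
#' reported as p = 1 with a flag), and the Pearson correlation of the
#' informative-locus count with log10 LR per method, with its t-test
#' p-value.
#'
#' @param results per-case data frame from [run_study()].
#' @return list with `wilcoxon` and `pearson` data frames.
#' @export
paired_tests <- function(results) {
  meth <- .method_cols(results)
  info <- .informative_cols(results)
  strata <- split(seq_len(nrow(results)),
                  paste(results$class, results$pedigree, sep = "-"))
  wil <- list()
  pea <- list()
  pairs <- utils::combn(colnames(meth), 2)
  for (s in names(strata)) {
    idx <- strata[[s]]
    for (pp in seq_len(ncol(pairs))) {
      a <- pairs[1, pp]; b <- pairs[2, pp]
      x <- meth[idx, a]; y <- meth[idx, b]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 2L) next
      d <- x[ok] - y[ok]
      dd <- d[d != 0]
      if (!length(dd)) {
        wil[[paste(s, pp)]] <- data.frame(
          stratum = s, method_a = a, method_b = b, n = sum(ok),
          p_value = 1, all_zero = TRUE)
        next
      }
      pv <- if (length(dd) <= 12) .signed_rank_exact_p(dd)
      else suppressWarnings(stats::wilcox.test(
        x[ok], y[ok], paired = TRUE, exact = length(dd) <= 25,
        correct = TRUE))$p.value
      wil[[paste(s, pp)]] <- data.frame(
        stratum = s, method_a = a, method_b = b, n = sum(ok),
        p_value = pv, all_zero = FALSE)
    }
    for (mm in colnames(meth)) {
      x <- info[idx, mm]; y <- meth[idx, mm]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      pea[[paste(s, mm)]] <- data.frame(
        stratum = s, method = mm, n = sum(ok),
        r = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  rbind0 <- function(x) if (length(x))
    do.call(rbind, c(x, list(make.row.names = FALSE))) else NULL
  list(wilcoxon = rbind0(wil), pearson = rbind0(pea))
}

#' Write study tables, JSON summary and figures
#'
#' Writes the per-case results and stratum summaries as tab-separated
#' tables, the summary as JSON, and (when there are cases and `plots` is
#' TRUE) three figures: a boxplot of log10 LR by method per stratum, a
#' density plot with a dashed line at the decision threshold, and a
#' per-case lollipop plot of log10 LR by method.
#'
#' @param study a `study_result`.
#' @param out_dir output directory (created if needed).
#' @param plots draw the figures.
#' @return invisibly, the vector of written file paths.
#' @export
render_report <- function(study, out_dir, plots = TRUE) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  results <- study$results
  wr(results, "cases.tsv")
  summ <- study$summary$table
  if (is.null(summ))
    summ <- data.frame(stratum = character(), method = character(),
                       n = integer(), median_log10_lr = numeric(),
                       prop_ge_threshold = numeric(),
                       mean_informative = numeric(),
                       sd_informative = numeric(),
                       best_method_share = numeric())
  wr(summ, "summary.tsv")
  dlr <- study$summary$delta_lr
  if (is.null(dlr))
    dlr <- data.frame(stratum = character(), n = integer(),
                      delta_lr_max = numeric())
  wr(dlr, "delta_lr.tsv")
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(summary = summ, delta_lr = dlr,
                            tests = study$tests,
                            threshold = study$summary$threshold),
                       jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)
  if (plots && !is.null(results) && nrow(results) > 0) {
    meth <- .method_cols(results)
    long <- do.call(rbind, lapply(colnames(meth), function(mm)
      data.frame(case_id = results$case_id,
                 stratum = paste(results$class, results$pedigree, sep = "-"),
                 method = mm, log10_lr = meth[[mm]])))
    long <- long[!is.na(long$log10_lr), ]
    thr <- log10(study$summary$threshold)
    pbox <- ggplot2::ggplot(long,
                            ggplot2::aes(x = method,
                                         y = log10_lr)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~stratum) +
      ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
      ggplot2::labs(y = "log10 LR")
    pden <- ggplot2::ggplot(long,
                            ggplot2::aes(x = log10_lr,
                                         colour = method)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~stratum, scales = "free") +
      ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
      ggplot2::labs(x = "log10 LR")
    plol <- ggplot2::ggplot(long,
                            ggplot2::aes(x = case_id,
                                         y = log10_lr,
                                         colour = method)) +
      ggplot2::geom_segment(ggplot2::aes(xend = case_id, yend = 0)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
      ggplot2::theme(axis.text.x =
                       ggplot2::element_text(angle = 90, vjust = 0.5)) +
      ggplot2::labs(x = NULL, y = "log10 LR")
    for (nm in c("boxplot", "density", "lollipop")) {
      p <- file.path(out_dir, paste0(nm, ".pdf"))
      ggplot2::ggsave(p, switch(nm, boxplot = pbox, density = pden,
                                lollipop = plol),
                      width = 8, height = 6)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
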