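# Binary-arm preprocessing: 2x consensus construction, logistic drop-out
# calibration, drop-out probability assignment, stochastic-threshold (5ST)
# degradation classification and informative-locus counting.

#' Logistic drop-out model
#'
#' Allelic drop-out probability as a function of the surviving heterozygous
#' partner peak height: `logit P(drop-out) = b0 + b1 * log10(height)`.
#' `b1` is expected to be negative (taller partner peaks imply less
#' drop-out).
#'
#' @param kit_id kit label the calibration belongs to.
#' @param b0,b1 logistic regression coefficients.
#' @param fit optional list of fit diagnostics.
#' @return object of class `dropout_model`.
#' @export
dropout_model <- function(kit_id, b0, b1, fit = NULL) {
  stopifnot(is.finite(b0), is.finite(b1))
  structure(list(kit_id = kit_id, b0 = b0, b1 = b1, fit = fit),
            class = "dropout_model")
}

#' @export
print.dropout_model <- function(x, ...) {
  cat("Drop-out model (", x$kit_id, "): logit d = ",
      signif(x$b0, 4), " + ", signif(x$b1, 4), " * log10(height)\n", sep = "")
  invisible(x)
}

#' Predicted drop-out probability at a peak height
#'
#' @param model a [dropout_model()].
#' @param height peak height(s) in RFU.
#' @return drop-out probabilities in (0, 1).
#' @export
predict_dropout <- function(model, height) {
  stats::plogis(model$b0 + model$b1 * log10(height))
}

#' Fit the drop-out logistic regression
#'
#' Maximum-likelihood logistic fit of the drop-out indicator on
#' log10(partner peak height), using the calibration rows whose partner peak
#' was itself detected (the covariate is undefined otherwise).
#'
#' @param calibration data frame from [generate_calibration_set()] (columns
#'   `detected`, `partner_height`, `partner_detected`).
#' @param kit_id kit label stored on the model.
#' @return a [dropout_model()] with fit diagnostics (n, coefficient standard
#'   errors, residual deviance).
#' @export
fit_dropout_logistic <- function(calibration, kit_id = "kit") {
  use <- calibration[!is.na(calibration$partner_height) &
                       calibration$partner_detected, , drop = FALSE]
  y <- !use$detected
  if (nrow(use) == 0L || all(y) || !any(y))
    stop("calibration data must contain both detected and undetected ",
         "outcomes; collect more calibration data near the threshold")
  x <- log10(use$partner_height)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- stats::coef(fit)
  if (!fit$converged || any(abs(co) > 1e3))
    stop("logistic fit did not stabilise (complete separation?); ",
         "collect more calibration data near the threshold")
  sm <- summary(fit)$coefficients
  dropout_model(kit_id, b0 = unname(co[1]), b1 = unname(co[2]),
                fit = list(n = nrow(use), se = unname(sm[, "Std. Error"]),
                           deviance = stats::deviance(fit)))
}

#' Remove stutter peaks with a ratio filter
#'
#' GeneMapper-style per-kit stutter filter: a peak one repeat unit below or
#' above a taller parent peak is removed when its height is less than
#' `ratio` times the parent's height. Applied to the binary arm's
#' replicates before consensus construction (the continuous arm models
#' stutter explicitly and must see unfiltered peaks).
#'
#' @param profile a [replicate_profile()].
#' @param ratio stutter filter threshold as a fraction of the parent peak
#'   height (default 0.15).
#' @return the filtered [replicate_profile()].
#' @export
filter_stutter <- function(profile, ratio = 0.15) {
  for (l in names(profile$peaks)) {
    pk <- profile$peaks[[l]]
    if (nrow(pk) < 2L) next
    a <- as.numeric(pk$allele)
    drop <- vapply(seq_len(nrow(pk)), function(i) {
      parent <- abs(a - a[i]) > 1 - 1e-9 & abs(a - a[i]) < 1 + 1e-9
      any(parent & pk$height[i] < ratio * pk$height)
    }, TRUE)
    profile$peaks[[l]] <- pk[!drop, , drop = FALSE]
    if (!nrow(profile$peaks[[l]])) profile$peaks[[l]] <- NULL
  }
  profile
}

#' Build a 2x consensus profile from two replicates
#'
#' The consensus allele set at each locus is the intersection of the two
#' replicates' allele sets. An empty intersection excludes the locus; a
#' two-allele consensus carries no drop-out (d = 0); a single-allele
#' consensus A is assigned a drop-out probability from the logistic model
#' evaluated at a height chosen by which replicates carry non-consensus
#' extra alleles: the highest A peak when both replicates are clean, the A
#' peak of the clean replicate when exactly one replicate shows extras, and
#' the lowest A peak when both do. More than two consensus alleles violates
#' the single-source assumption and is an error.
#'
#' @param rep1,rep2 two [replicate_profile()]s of the same sample and kit.
#' @param model a [dropout_model()] for that kit.
#' @param on_conflict what to do when a locus has more than two consensus
#'   alleles: `"error"` (default) or `"exclude"` the locus with a warning.
#' @return object of class `consensus_profile`: per locus a record with
#'   `status` ("excluded", "single" or "double"), `alleles`, drop-out `d`
#'   (NA unless single) and the peak height the model was evaluated at.
#' @export
build_consensus <- function(rep1, rep2, model,
                            on_conflict = c("error", "exclude")) {
  on_conflict <- match.arg(on_conflict)
  if (!identical(rep1$kit_id, rep2$kit_id))
    stop("consensus replicates must come from the same kit")
  if (!identical(rep1$sample_id, rep2$sample_id))
    stop("consensus replicates must come from the same sample")
  loci <- rep1$loci
  out <- vector("list", length(loci))
  names(out) <- loci
  for (l in loci) {
    p1 <- rep1$peaks[[l]]
    p2 <- rep2$peaks[[l]]
    s1 <- if (is.null(p1)) character() else p1$allele
    s2 <- if (is.null(p2)) character() else p2$allele
    cons <- intersect(s1, s2)
    if (length(cons) > 2L) {
      if (on_conflict == "error")
        stop(">2 consensus alleles at locus ", l,
             ": single-source assumption violated")
      warning(">2 consensus alleles at locus ", l, "; locus excluded")
      cons <- character()
    }
    if (length(cons) == 0L) {
      out[[l]] <- list(status = "excluded", alleles = character(),
                       d = NA_real_, height_used = NA_real_)
    } else if (length(cons) == 2L) {
      out[[l]] <- list(status = "double",
                       alleles = cons[order(as.numeric(cons))],
                       d = 0, height_used = NA_real_)
    } else {
      a <- cons
      h1 <- p1$height[match(a, p1$allele)]
      h2 <- p2$height[match(a, p2$allele)]
      extra1 <- length(setdiff(s1, cons)) > 0L
      extra2 <- length(setdiff(s2, cons)) > 0L
      h <- if (!extra1 && !extra2) max(h1, h2)
      else if (extra1 && extra2) min(h1, h2)
      else if (extra1) h2                    # clean replicate's A peak
      else h1
      out[[l]] <- list(status = "single", alleles = a,
                       d = predict_dropout(model, h), height_used = h)
    }
  }
  structure(list(sample_id = rep1$sample_id, kit_id = rep1$kit_id,
                 loci = out),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  st <- vapply(x$loci, `[[`, "", "status")
  cat("Consensus profile ", x$sample_id, " (", x$kit_id, "): ",
      sum(st == "double"), " full, ", sum(st == "single"),
      " single-allele, ", sum(st == "excluded"), " excluded loci\n", sep = "")
  invisible(x)
}

#' Consensus profile as a data frame
#'
#' @param x a `consensus_profile`.
#' @param ... unused.
#' @return data frame with columns `locus`, `alleles` (comma-joined),
#'   `d`, `excluded`.
#' @export
as.data.frame.consensus_profile <- function(x, ...) {
  data.frame(
    locus = names(x$loci),
    alleles = vapply(x$loci, function(e) paste(e$alleles, collapse = ","), ""),
    d = vapply(x$loci, function(e) if (is.na(e$d)) NA_real_ else e$d, 0),
    excluded = vapply(x$loci, function(e) e$status == "excluded", TRUE),
    row.names = NULL)
}

#' Write a consensus profile as tab-separated text
#'
#' @param consensus a `consensus_profile`.
#' @param path output path.
#' @export
write_consensus_tsv <- function(consensus, path) {
  utils::write.table(as.data.frame(consensus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify degradation by the 5% stochastic threshold
#'
#' Pools the observed peaks of the supplied replicates, keeps those whose
#' model-predicted drop-out probability at their height is below 5%, and
#' takes the largest fragment size among them (0 bp when none qualifies).
#' Profiles whose largest such amplicon is shorter than the cutoff are
#' called highly degraded (HD), otherwise mildly degraded (MD).
#'
#' @param replicates list of [replicate_profile()]s.
#' @param model a [dropout_model()].
#' @param cutoff_bp HD/MD boundary (default 200 bp).
#' @param mode `"pooled"` (default) evaluates all peaks of all replicates
#'   together; `"per-replicate"` computes a 5ST size per replicate and
#'   takes the smallest (the reproducible profile quality).
#' @return object of class `degradation_call` with fields `five_st_size`,
#'   `class` and `cutoff_bp`.
#' @export
classify_degradation <- function(replicates, model, cutoff_bp = 200,
                                 mode = c("pooled", "per-replicate")) {
  mode <- match.arg(mode)
  stopifnot(length(replicates) >= 1L)
  one <- function(reps) {
    sizes <- numeric()
    heights <- numeric()
    for (r in reps) for (pk in r$peaks) {
      sizes <- c(sizes, pk$size)
      heights <- c(heights, pk$height)
    }
    if (!length(heights)) return(0)
    ok <- predict_dropout(model, heights) < 0.05
    if (any(ok)) max(sizes[ok]) else 0
  }
  five_st <- if (mode == "pooled") one(replicates)
  else min(vapply(replicates, function(r) one(list(r)), 0))
  structure(list(five_st_size = five_st,
                 class = if (five_st < cutoff_bp) "HD" else "MD",
                 cutoff_bp = cutoff_bp),
            class = "degradation_call")
}

#' @export
print.degradation_call <- function(x, ...) {
  cat("5ST = ", x$five_st_size, " bp -> ", x$class,
      " (cutoff ", x$cutoff_bp, " bp)\n", sep = "")
  invisible(x)
}

#' Count informative loci
#'
#' Consensus mode (the binary arm's rule) counts loci of a consensus profile
#' with at least one consensus allele; replicate mode (the continuous arm's
#' rule) counts loci with at least one above-threshold peak in at least one
#' of the supplied replicates.
#'
#' @param x a `consensus_profile`, or a list of [replicate_profile()]s.
#' @param mode counting rule; defaults to the mode matching `x`.
#' @return integer count.
#' @export
count_informative_loci <- function(x, mode = c("auto", "consensus",
                                               "replicate")) {
  mode <- match.arg(mode)
  if (inherits(x, "consensus_profile")) {
    if (mode == "replicate")
      stop("replicate mode needs replicate profiles, not a consensus profile")
    return(sum(vapply(x$loci, function(e) e$status != "excluded", TRUE)))
  }
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "replicate_profile")))
  loci <- unique(unlist(lapply(x, function(r)
    names(Filter(function(pk) nrow(pk) > 0, r$peaks)))))
  length(loci)
}

#' Write a drop-out model as JSON
#'
#' @param model a [dropout_model()].
#' @param path output path.
#' @export
write_dropout_model <- function(model, path) {
  jsonlite::write_json(list(kit_id = model$kit_id, b0 = model$b0,
                            b1 = model$b1, fit = model$fit),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a drop-out model from JSON
#'
#' @param path file written by [write_dropout_model()].
#' @return a [dropout_model()].
#' @export
read_dropout_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dropout_model(x$kit_id, x$b0, x$b1, fit = x$fit)
}
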