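# Continuous single-source likelihood with relatedness propositions: gamma
# peak-height model with degradation, backward/forward stutter, exponential
# drop-in and drop-out as censoring at the analytical threshold; joint over
# PCR replicates and kits with a shared genotype; maximum-likelihood
# estimation, adjusted-loglikelihood model selection, likelihood ratios and
# probability-probability plot validation.

#' Relatedness prior specification
#'
#' The genotype prior of the low-template person relative to a single typed
#' reference person: `"parent-child"` (one allele identical by descent from
#' the reference) or `"unrelated"`.
#'
#' @param relationship `"parent-child"` or `"unrelated"`.
#' @param reference the reference person's [genotype()].
#' @return object of class `relatedness_prior`.
#' @export
relatedness_prior <- function(relationship = c("parent-child", "unrelated"),
                              reference) {
  structure(list(relationship = match.arg(relationship),
                 reference = reference),
            class = "relatedness_prior")
}

#' Genotype prior at one locus
#'
#' Parent-child: one allele is copied from the reference (each of its two
#' alleles with probability 1/2) and the other is drawn from the
#' Balding-Nichols urn conditioned on the reference's two alleles.
#' Unrelated: both alleles are drawn sequentially from the urn conditioned
#' on the reference's two alleles. Probabilities are returned over unordered
#' genotypes and sum to one.
#'
#' @param prior a [relatedness_prior()].
#' @param locus locus name.
#' @param freqs an [allele_frequencies()] table.
#' @param pop a [population_model()].
#' @param extra_alleles further allele designations that must be in the
#'   allele universe (e.g. observed peaks), floored if absent from the table.
#' @return data frame with columns `a1`, `a2` (a1 <= a2 numerically) and
#'   `prob`.
#' @export
genotype_prior <- function(prior, locus, freqs, pop = population_model(),
                           extra_alleles = character()) {
  ref <- prior$reference[[locus]]
  if (is.null(ref)) stop("reference untyped at locus ", locus)
  fl <- locus_frequencies(freqs, locus, c(ref, extra_alleles), pop)
  al <- names(fl)
  k <- length(al)
  th <- pop$theta
  ri <- match(ref, al)
  acc <- new.env()
  add <- function(i, j, pr) {      # al is already in canonical order
    key <- paste(min(i, j), max(i, j))
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pr
  }
  if (prior$relationship == "parent-child") {
    nxt <- bn_locus_probs(ref, pop, fl)
    for (t in 1:2) for (j in seq_len(k)) add(ri[t], j, 0.5 * nxt[j])
  } else {
    g2 <- expand.grid(i = seq_len(k), j = seq_len(k))
    pr <- seq_bn_prob(cbind(g2$i, g2$j), ri, th, unname(fl))
    for (r in seq_len(nrow(g2))) add(g2$i[r], g2$j[r], pr[r])
  }
  keys <- ls(acc)
  ij <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(a1 = al[as.integer(ij[, 1])],
                    a2 = al[as.integer(ij[, 2])],
                    prob = vapply(keys, function(kk) acc[[kk]], 0))
  out <- out[order(as.integer(ij[, 1]), as.integer(ij[, 2])), ]
  rownames(out) <- NULL
  attr(out, "freqs") <- fl
  out
}

#' Continuous locus log-likelihood for a fixed genotype
#'
#' Direct (readable, per-position) evaluation of the continuous model for
#' one locus and genotype across one or more replicates of the same kit:
#' the expected contribution at position `a` follows the stutter/degradation
#' weight formula of [simulate_replicate()]; an observed peak at a
#' contributing position adds a gamma log-density, a contributing position
#' with no peak adds the gamma CDF at the analytical threshold (drop-out),
#' an observed peak with zero contribution adds the exponential drop-in
#' factor `p_c * p_a * lambda * exp(-lambda (h - AT))`, and a replicate-locus
#' with no drop-ins adds `log(1 - p_c)`. Replicates are conditionally
#' independent given the genotype, so their log-likelihoods add.
#'
#' @param replicates list of [replicate_profile()]s from `kit`.
#' @param locus locus name.
#' @param geno character vector of length 2 (the candidate genotype).
#' @param params a [continuous_params()] object.
#' @param kit the [kit_panel()].
#' @param freqs an [allele_frequencies()] table (drop-in allele frequencies).
#' @param pop a [population_model()] (rare-allele flooring only).
#' @return log-probability.
#' @export
locus_loglik <- function(replicates, locus, geno, params, kit, freqs,
                         pop = population_model()) {
  gn <- round(as.numeric(geno), 1)
  ll <- 0
  for (r in replicates) {
    pk <- r$peaks[[locus]]
    obs_al <- if (is.null(pk)) character() else pk$allele
    obs_h <- if (is.null(pk)) numeric() else pk$height
    fl <- locus_frequencies(freqs, locus, c(geno, obs_al), pop)
    pos <- sort(unique(round(c(gn, gn - 1, gn + 1, as.numeric(obs_al)), 1)))
    ndropin <- 0L
    for (a in pos) {
      np <- sum(abs(gn - a) < 1e-9)
      nb <- sum(abs(gn - (a + 1)) < 1e-9)
      nf <- sum(abs(gn - (a - 1)) < 1e-9)
      w <- (1 - params$xi_b - params$xi_f) * np +
        params$xi_b * nb + params$xi_f * nf
      if (w > 0) {
        s <- allele_size(kit, locus, a)
        w <- w * params$beta^((s - 125) / 100)
      }
      hi <- obs_h[match(format_allele(a), obs_al)]
      if (w > 0) {
        sh <- w / params$omega^2
        sc <- params$mu * params$omega^2
        ll <- ll + if (!is.na(hi))
          stats::dgamma(hi, shape = sh, scale = sc, log = TRUE)
        else stats::pgamma(params$at, shape = sh, scale = sc, log.p = TRUE)
      } else if (!is.na(hi)) {
        pa <- fl[[format_allele(a)]]
        ll <- ll + log(params$p_c * pa * params$lambda) -
          params$lambda * (hi - params$at)
        ndropin <- ndropin + 1L
      }
      if (!is.finite(ll))
        stop("non-finite locus likelihood at ", locus,
             " (mu=", params$mu, ", omega=", params$omega, ")")
    }
    if (ndropin == 0L) ll <- ll + log1p(-params$p_c)
  }
  ll
}

# --- vectorised likelihood skeleton ----------------------------------------
# Flattened row structure over (locus, genotype, replicate, position),
# reused across model-flag combinations and optimizer restarts.

.cont_skeleton <- function(replicates, supports, kits, lambda_by_kit,
                           p_c, freqs, pop) {
  kit_ids <- unique(vapply(replicates, `[[`, "", "kit_id"))
  rep_kit <- match(vapply(replicates, `[[`, "", "kit_id"), kit_ids)
  at_k <- vapply(kit_ids, function(kk) kits[[kk]]$analytical_threshold, 0)
  lam_k <- vapply(kit_ids, function(kk) unname(lambda_by_kit[[kk]]), 0)
  pc_k <- if (length(p_c) == 1L) rep(p_c, length(kit_ids))
  else vapply(kit_ids, function(kk) unname(p_c[[kk]]), 0)
  loci <- names(supports)

  rows <- list(h = list(), pa = list(), n_par = list(), n_back = list(),
               n_fwd = list(), delta = list(), kit = list(), grp = list(),
               peak = list())
  grp_lg <- integer()
  grp_kit <- integer()
  lg_locus <- integer()
  lg_logprior <- numeric()
  lg_a1 <- character(); lg_a2 <- character()
  peaks_tab <- list()
  grp_n <- 0L; lg_n <- 0L; peak_n <- 0L; row_i <- 0L

  for (li in seq_along(loci)) {
    l <- loci[li]
    sup <- supports[[l]]
    fl <- attr(sup, "freqs")
    # per-replicate observed peaks at this locus (with peak ids)
    obs <- lapply(seq_along(replicates), function(rr) {
      pk <- replicates[[rr]]$peaks[[l]]
      if (is.null(pk) || !nrow(pk)) return(NULL)
      pk
    })
    for (rr in seq_along(obs)) if (!is.null(obs[[rr]])) {
      ids <- peak_n + seq_len(nrow(obs[[rr]]))
      peak_n <- peak_n + nrow(obs[[rr]])
      obs[[rr]]$peak_id <- ids
      peaks_tab[[length(peaks_tab) + 1L]] <- data.frame(
        peak_id = ids, locus = l,
        replicate = replicates[[rr]]$replicate_id,
        kit = replicates[[rr]]$kit_id,
        allele = obs[[rr]]$allele, height = obs[[rr]]$height)
    }
    # fragment-size exponent per kit, cached over candidate positions
    cand <- sort(unique(round(c(as.numeric(sup$a1), as.numeric(sup$a2),
                                as.numeric(sup$a1) + 1, as.numeric(sup$a1) - 1,
                                as.numeric(sup$a2) + 1, as.numeric(sup$a2) - 1,
                                unlist(lapply(obs, function(pk)
                                  if (is.null(pk)) NULL
                                  else as.numeric(pk$allele)))), 1)))
    cand_key <- as.integer(round(cand * 10))
    delta_k <- lapply(kit_ids, function(kk)
      (vapply(cand, function(a) allele_size(kits[[kk]], l, a), 0) - 125) / 100)
    pa_cand <- unname(fl[format_allele(cand)])
    pa_cand[is.na(pa_cand)] <- 0

    for (g in seq_len(nrow(sup))) {
      gn <- round(c(as.numeric(sup$a1[g]), as.numeric(sup$a2[g])), 1)
      gt <- as.integer(round(gn * 10))
      lg_n <- lg_n + 1L
      lg_locus[lg_n] <- li
      lg_logprior[lg_n] <- log(sup$prob[g])
      lg_a1[lg_n] <- sup$a1[g]; lg_a2[lg_n] <- sup$a2[g]
      for (rr in seq_along(replicates)) {
        pk <- obs[[rr]]
        obs_key <- if (is.null(pk)) integer()
        else as.integer(round(as.numeric(pk$allele) * 10))
        pos_key <- sort(unique(c(gt, gt - 10L, gt + 10L, obs_key)))
        ci <- match(pos_key, cand_key)
        np <- (gt[1] == pos_key) + (gt[2] == pos_key)
        nb <- (gt[1] == pos_key + 10L) + (gt[2] == pos_key + 10L)
        nf <- (gt[1] == pos_key - 10L) + (gt[2] == pos_key - 10L)
        oi <- match(pos_key, obs_key)
        grp_n <- grp_n + 1L
        grp_lg[grp_n] <- lg_n
        grp_kit[grp_n] <- rep_kit[rr]
        n <- length(pos_key)
        row_i <- row_i + 1L
        rows$h[[row_i]] <- ifelse(is.na(oi), NA_real_, pk$height[oi])
        rows$pa[[row_i]] <- pa_cand[ci]
        rows$n_par[[row_i]] <- np
        rows$n_back[[row_i]] <- nb
        rows$n_fwd[[row_i]] <- nf
        rows$delta[[row_i]] <- delta_k[[rep_kit[rr]]][ci]
        rows$kit[[row_i]] <- rep(rep_kit[rr], n)
        rows$grp[[row_i]] <- rep(grp_n, n)
        rows$peak[[row_i]] <- ifelse(is.na(oi), NA_integer_, pk$peak_id[oi])
      }
    }
  }
  h <- unlist(rows$h, use.names = FALSE)
  skel <- list(
    h = h, obs = !is.na(h),
    pa = unlist(rows$pa, use.names = FALSE),
    n_par = unlist(rows$n_par, use.names = FALSE),
    n_back = unlist(rows$n_back, use.names = FALSE),
    n_fwd = unlist(rows$n_fwd, use.names = FALSE),
    delta = unlist(rows$delta, use.names = FALSE),
    row_kit = unlist(rows$kit, use.names = FALSE),
    grp = unlist(rows$grp, use.names = FALSE),
    peak = unlist(rows$peak, use.names = FALSE),
    grp_lg = grp_lg, grp_kit = grp_kit, grp_pc = pc_k[grp_kit],
    lg_locus = lg_locus, lg_logprior = lg_logprior,
    lg_a1 = lg_a1, lg_a2 = lg_a2,
    lg_by_locus = split(seq_len(lg_n), lg_locus),
    loci = loci, kit_ids = kit_ids,
    at_k = at_k, lam_k = lam_k, pc_k = pc_k,
    peaks = if (length(peaks_tab)) do.call(rbind, peaks_tab) else NULL,
    n_grp = grp_n, n_lg = lg_n)
  skel$at_row <- at_k[skel$row_kit]
  skel$lam_row <- lam_k[skel$row_kit]
  skel$pc_row <- pc_k[skel$row_kit]
  # mean observed height per kit (optimizer start)
  skel$mean_h_kit <- vapply(seq_along(kit_ids), function(kk) {
    v <- h[!is.na(h) & skel$row_kit == kk]
    if (length(v)) mean(v) else 2 * at_k[kk]
  }, 0)
  skel
}

# Evaluate the joint log-likelihood on a skeleton. `pars` holds per-kit
# vectors mu, om, beta, xib, xif aligned with skel$kit_ids.
.cont_eval <- function(skel, pars, detail = FALSE) {
  mu <- pars$mu[skel$row_kit]
  om2 <- (pars$om^2)[skel$row_kit]
  w <- pars$beta[skel$row_kit]^skel$delta *
    ((1 - pars$xib - pars$xif)[skel$row_kit] * skel$n_par +
       pars$xib[skel$row_kit] * skel$n_back +
       pars$xif[skel$row_kit] * skel$n_fwd)
  shape <- w / om2
  scale <- mu * om2
  logf <- numeric(length(w))
  i1 <- skel$obs & w > 0
  logf[i1] <- stats::dgamma(skel$h[i1], shape = shape[i1],
                            scale = scale[i1], log = TRUE)
  i2 <- !skel$obs & w > 0
  logf[i2] <- stats::pgamma(skel$at_row[i2], shape = shape[i2],
                            scale = scale[i2], log.p = TRUE)
  i3 <- skel$obs & w == 0
  logf[i3] <- log(skel$pc_row[i3] * skel$pa[i3] * skel$lam_row[i3]) -
    skel$lam_row[i3] * (skel$h[i3] - skel$at_row[i3])
  gs <- rowsum(logf, skel$grp)[, 1]
  ndi <- rowsum(as.numeric(i3), skel$grp)[, 1]
  gs <- gs + (ndi == 0) * log1p(-skel$grp_pc)
  lg <- rowsum(gs, skel$grp_lg)[, 1]
  tot <- lg + skel$lg_logprior
  nl <- length(skel$lg_by_locus)
  ll_loc <- numeric(nl)
  for (li in seq_len(nl)) {
    ii <- skel$lg_by_locus[[li]]
    M <- max(tot[ii])
    ll_loc[li] <- if (!is.finite(M)) -Inf else M + log(sum(exp(tot[ii] - M)))
  }
  out <- list(total = sum(ll_loc), per_locus = ll_loc)
  if (detail) {
    out$lg_logpost <- tot - ll_loc[skel$lg_locus]
    out$w <- w
    out$shape <- shape
    out$scale <- scale
  }
  out
}

.flag_combos <- function() {
  g <- expand.grid(degradation = c(FALSE, TRUE), xi_b = c(FALSE, TRUE),
                   xi_f = c(FALSE, TRUE))
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}

.pack_start <- function(skel, flags, jitter_seed = NULL, init = NULL) {
  nk <- length(skel$kit_ids)
  par <- numeric(0)
  if (!is.null(jitter_seed)) set.seed(jitter_seed)
  clamp <- function(x, lo = 1e-4, hi = 1 - 1e-4) min(max(x, lo), hi)
  for (kk in seq_len(nk)) {
    ini <- if (!is.null(init)) init[[skel$kit_ids[kk]]]
    if (is.null(ini) && !is.null(init) && length(init) == 1L)
      ini <- init[[1L]]      # single-kit parameters carried to another kit
    lmu <- if (!is.null(ini)) log(ini$mu)
    else log(max(skel$mean_h_kit[kk], 1.5 * skel$at_k[kk]))
    lom <- if (!is.null(ini)) log(ini$omega) else log(0.4)
    v <- c(lmu, lom)
    if (flags$degradation)
      v <- c(v, stats::qlogis(clamp(if (!is.null(ini)) ini$beta else 0.85)))
    if (flags$xi_b)
      v <- c(v, stats::qlogis(clamp(
        (if (!is.null(ini) && ini$xi_b > 0) ini$xi_b else 0.05) / 0.5)))
    if (flags$xi_f)
      v <- c(v, stats::qlogis(clamp(
        (if (!is.null(ini) && ini$xi_f > 0) ini$xi_f else 0.02) / 0.5)))
    if (!is.null(jitter_seed))
      v <- v + stats::runif(length(v), -0.6, 0.6)
    par <- c(par, v)
  }
  par
}

.unpack_pars <- function(par, flags, nk) {
  mu <- om <- beta <- xib <- xif <- numeric(nk)
  i <- 0L
  for (kk in seq_len(nk)) {
    mu[kk] <- exp(par[i + 1L]); om[kk] <- exp(par[i + 2L]); i <- i + 2L
    if (flags$degradation) { beta[kk] <- stats::plogis(par[i + 1L]); i <- i + 1L }
    else beta[kk] <- 1
    if (flags$xi_b) { xib[kk] <- 0.5 * stats::plogis(par[i + 1L]); i <- i + 1L }
    else xib[kk] <- 0
    if (flags$xi_f) { xif[kk] <- 0.5 * stats::plogis(par[i + 1L]); i <- i + 1L }
    else xif[kk] <- 0
  }
  list(mu = mu, om = om, beta = beta, xib = xib, xif = xif)
}

# Per-combo preparation: with the channel flags fixed, the set of positions
# with positive contribution weight is fixed, so the row partition and the
# drop-in/no-drop-in constants can be computed once and reused across every
# optimizer iteration.
.prep_combo <- function(skel, flags) {
  pos <- skel$n_par > 0 |
    (if (flags$xi_b) skel$n_back > 0 else FALSE) |
    (if (flags$xi_f) skel$n_fwd > 0 else FALSE)
  i1 <- which(pos & skel$obs)
  i2 <- which(pos & !skel$obs)
  i3 <- which(!pos & skel$obs)
  dropin_logf <- log(skel$pc_row[i3] * skel$pa[i3] * skel$lam_row[i3]) -
    skel$lam_row[i3] * (skel$h[i3] - skel$at_row[i3])
  gs0 <- numeric(skel$n_grp)
  ndi <- numeric(skel$n_grp)
  if (length(i3)) {
    sm <- rowsum(cbind(dropin_logf, 1), skel$grp[i3])
    gi <- as.integer(rownames(sm))
    gs0[gi] <- sm[, 1]
    ndi[gi] <- sm[, 2]
  }
  gs0 <- gs0 + (ndi == 0) * log1p(-skel$grp_pc)
  gam <- c(i1, i2)
  list(obs1 = rep(c(TRUE, FALSE), c(length(i1), length(i2))),
       h1 = skel$h[i1], at2 = skel$at_row[i2],
       n_par = skel$n_par[gam], n_back = skel$n_back[gam],
       n_fwd = skel$n_fwd[gam], delta = skel$delta[gam],
       kit = skel$row_kit[gam], grp = skel$grp[gam], gs0 = gs0)
}

.cont_eval_fast <- function(skel, prep, pars) {
  om2 <- (pars$om^2)[prep$kit]
  w <- pars$beta[prep$kit]^prep$delta *
    ((1 - pars$xib - pars$xif)[prep$kit] * prep$n_par +
       pars$xib[prep$kit] * prep$n_back +
       pars$xif[prep$kit] * prep$n_fwd)
  shape <- w / om2
  scale <- pars$mu[prep$kit] * om2
  logf <- numeric(length(w))
  n1 <- length(prep$h1)
  if (n1) logf[seq_len(n1)] <-
    stats::dgamma(prep$h1, shape = shape[seq_len(n1)],
                  scale = scale[seq_len(n1)], log = TRUE)
  if (length(prep$at2)) logf[n1 + seq_along(prep$at2)] <-
    stats::pgamma(prep$at2, shape = shape[n1 + seq_along(prep$at2)],
                  scale = scale[n1 + seq_along(prep$at2)], log.p = TRUE)
  gs <- prep$gs0
  sm <- rowsum(logf, prep$grp)
  gs[as.integer(rownames(sm))] <- gs[as.integer(rownames(sm))] + sm[, 1]
  lg <- rowsum(gs, skel$grp_lg)[, 1]
  tot <- lg + skel$lg_logprior
  ll <- 0
  for (ii in skel$lg_by_locus) {
    M <- max(tot[ii])
    ll <- ll + if (!is.finite(M)) -Inf else M + log(sum(exp(tot[ii] - M)))
  }
  ll
}

.fit_core <- function(skel, flags, n_starts = 3, seed = 1, maxit = 400,
                      reltol = 1e-7, start_from = 1L, init = NULL) {
  nk <- length(skel$kit_ids)
  prep <- .prep_combo(skel, flags)
  negll <- function(par) {
    v <- .cont_eval_fast(skel, prep, .unpack_pars(par, flags, nk))
    if (!is.finite(v)) 1e12 else -v
  }
  best <- NULL
  if (!is.null(init)) n_starts <- n_starts + 1L   # extra start at init
  for (s in seq(start_from, n_starts)) {
    par0 <- .pack_start(skel, flags,
                        jitter_seed = if (s == 1L) NULL
                        else as.integer((as.numeric(seed) * 1009 + s) %%
                                          2147483647),
                        init = if (s <= 2L) init else NULL)
    res <- tryCatch(
      stats::optim(par0, negll, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e12) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("continuous MLE did not converge from any start; ",
         "check peak data and fixed drop-in parameters")
  pars <- .unpack_pars(best$par, flags, nk)
  n_free <- nk * (2L + sum(unlist(flags)))
  ev <- .cont_eval(skel, pars)
  params <- lapply(seq_len(nk), function(kk)
    list(mu = pars$mu[kk], omega = pars$om[kk], beta = pars$beta[kk],
         xi_b = pars$xib[kk], xi_f = pars$xif[kk]))
  names(params) <- skel$kit_ids
  structure(list(params = params, flags = flags,
                 loglik = ev$total, adjusted = ev$total - n_free,
                 n_free = n_free, per_locus = ev$per_locus,
                 pars_raw = pars, skeleton = skel,
                 convergence = best$convergence, n_starts = n_starts),
            class = "cont_fit")
}

#' @export
print.cont_fit <- function(x, ...) {
  cat("Continuous model fit: loglik ", signif(x$loglik, 6), " (adjusted ",
      signif(x$adjusted, 6), "), flags deg=", x$flags$degradation,
      " xiB=", x$flags$xi_b, " xiF=", x$flags$xi_f, "\n", sep = "")
  for (kk in names(x$params)) {
    p <- x$params[[kk]]
    cat("  ", kk, ": mu=", signif(p$mu, 4), " omega=", signif(p$omega, 3),
        " beta=", signif(p$beta, 3), " xiB=", signif(p$xi_b, 3),
        " xiF=", signif(p$xi_f, 3), "\n", sep = "")
  }
  invisible(x)
}

# Build genotype supports per locus for a hypothesis prior.
.build_supports <- function(replicates, prior, freqs, pop) {
  loci <- unique(unlist(lapply(replicates, `[[`, "loci")))
  out <- list()
  for (l in loci) {
    if (is.null(prior$reference[[l]])) {
      has_peaks <- any(vapply(replicates, function(r) {
        pk <- r$peaks[[l]]
        !is.null(pk) && nrow(pk) > 0
      }, TRUE))
      if (has_peaks)
        warning("reference untyped at locus ", l, "; locus skipped")
      next
    }
    obs_al <- unique(unlist(lapply(replicates, function(r) {
      pk <- r$peaks[[l]]
      if (is.null(pk)) character() else pk$allele
    })))
    out[[l]] <- genotype_prior(prior, l, freqs, pop, extra_alleles = obs_al)
  }
  out
}

#' Maximum-likelihood fit of the continuous model
#'
#' Maximises the marginal likelihood
#' `sum_loci log sum_G prior(G) prod_replicates P(peaks | G, params)`
#' over the peak-height parameters (mu, omega, and, per the model flags,
#' beta, xi_b, xi_f), separately per kit with the genotype shared across
#' kits. Optimisation is multi-start Nelder-Mead on transformed parameters
#' (log mu, log omega, logit-type transforms keeping beta in (0,1) and each
#' stutter proportion below 0.5); starts are deterministic given `seed`.
#' Drop-in parameters (lambda, p_c) and the analytical threshold are fixed,
#' not optimised.
#'
#' @param replicates list of [replicate_profile()]s (1+ replicates, 1-2
#'   kits).
#' @param prior a [relatedness_prior()], ignored when `genotypes` is given.
#' @param flags list with logical elements `degradation`, `xi_b`, `xi_f`;
#'   switched-off channels are pinned (beta = 1, xi = 0).
#' @param kits named list of [kit_panel()]s covering the replicates' kits.
#' @param freqs an [allele_frequencies()] table.
#' @param pop a [population_model()].
#' @param lambda_by_kit named drop-in rates per kit id.
#' @param p_c per-locus per-replicate drop-in probability (scalar or named
#'   per kit).
#' @param genotypes optional known [genotype()] of the donor; when given the
#'   genotype prior is a point mass (parameter-recovery studies).
#' @param n_starts number of optimizer starts (first from moment-based
#'   values, the rest jittered deterministically).
#' @param seed integer seed for the jittered starts.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return object of class `cont_fit`: per-kit parameter estimates, flags,
#'   `loglik`, `adjusted` loglikelihood (loglik minus the number of free
#'   parameters), per-locus marginal logliks and the fitted skeleton.
#' @export
fit_mle <- function(replicates, prior = NULL,
                    flags = list(degradation = TRUE, xi_b = TRUE,
                                 xi_f = TRUE),
                    kits, freqs, pop = population_model(),
                    lambda_by_kit, p_c = 0.05, genotypes = NULL,
                    n_starts = 3, seed = 1, maxit = 400) {
  supports <- if (!is.null(genotypes)) {
    loci <- intersect(unique(unlist(lapply(replicates, `[[`, "loci"))),
                      names(genotypes))
    out <- lapply(loci, function(l) {
      g <- sort(as.numeric(genotypes[[l]]))
      obs_al <- unique(unlist(lapply(replicates, function(r) {
        pk <- r$peaks[[l]]
        if (is.null(pk)) character() else pk$allele
      })))
      sup <- data.frame(a1 = format_allele(g[1]), a2 = format_allele(g[2]),
                        prob = 1)
      attr(sup, "freqs") <- locus_frequencies(freqs, l,
                                              c(genotypes[[l]], obs_al), pop)
      sup
    })
    names(out) <- loci
    out
  } else {
    if (is.null(prior)) stop("either a relatedness prior or known genotypes")
    .build_supports(replicates, prior, freqs, pop)
  }
  if (!length(supports)) stop("no loci with a typed reference to fit")
  skel <- .cont_skeleton(replicates, supports, kits, lambda_by_kit, p_c,
                         freqs, pop)
  .fit_core(skel, flags, n_starts = n_starts, seed = seed, maxit = maxit)
}

#' Model selection and continuous likelihood ratio
#'
#' Fits the continuous model under both propositions (Hp: the sample comes
#' from the parent/child of the reference person; Hd: from an unrelated
#' individual) for every on/off combination of the degradation, backward-
#' and forward-stutter channels, selects the combination maximising the
#' summed adjusted loglikelihoods, and returns
#' `LR = exp(loglik_Hp - loglik_Hd)` at the respective MLEs. With
#' `check_reciprocal = TRUE` the chosen combination is refitted from
#' different starts with relatedness placed in the denominator, and the
#' reciprocal of that LR is reported alongside for comparison.
#'
#' @inheritParams fit_mle
#' @param reference the reference person's [genotype()].
#' @param fixed_flags optional single flag combination to use instead of
#'   searching all eight (e.g. reusing a selection made with another kit).
#' @param init_hp,init_hd optional per-kit parameter lists (as in a
#'   `cont_fit`'s `params`) used as additional optimizer starts for the
#'   numerator / denominator fits; a single-kit list seeds every kit, the
#'   multi-kit mode's assumption that single-kit estimates carry over.
#' @param check_reciprocal also compute the swapped-proposition LR.
#' @return object of class `cont_lr_result`: `lr`, `log10_lr`, chosen
#'   `flags`, fits under both hypotheses, a per-locus LR table and (when
#'   requested) `lr_reciprocal`.
#' @export
select_model_and_lr <- function(replicates, reference, kits, freqs,
                                pop = population_model(), lambda_by_kit,
                                p_c = 0.05, fixed_flags = NULL,
                                n_starts = 3, seed = 1, maxit = 400,
                                init_hp = NULL, init_hd = NULL,
                                check_reciprocal = FALSE) {
  sup_hp <- .build_supports(replicates,
                            relatedness_prior("parent-child", reference),
                            freqs, pop)
  sup_hd <- .build_supports(replicates,
                            relatedness_prior("unrelated", reference),
                            freqs, pop)
  if (!length(sup_hp)) stop("no loci with a typed reference")
  skel_hp <- .cont_skeleton(replicates, sup_hp, kits, lambda_by_kit, p_c,
                            freqs, pop)
  skel_hd <- .cont_skeleton(replicates, sup_hd, kits, lambda_by_kit, p_c,
                            freqs, pop)
  combos <- if (is.null(fixed_flags)) .flag_combos() else list(fixed_flags)
  # search pass: single moment-based start per combo; the winning combo is
  # then refitted with the full multi-start schedule
  fits <- vector("list", length(combos))
  score <- rep(-Inf, length(combos))
  search_starts <- if (length(combos) == 1L) n_starts else 1L
  search_reltol <- if (length(combos) == 1L) 1e-7 else 1e-6
  for (i in seq_along(combos)) {
    fp <- .fit_core(skel_hp, combos[[i]], search_starts, seed + 17L * i,
                    maxit, reltol = search_reltol, init = init_hp)
    fd <- .fit_core(skel_hd, combos[[i]], search_starts, seed + 17L * i + 7L,
                    maxit, reltol = search_reltol, init = init_hd)
    fits[[i]] <- list(hp = fp, hd = fd)
    score[i] <- fp$adjusted + fd$adjusted
  }
  best <- which.max(score)
  fp <- fits[[best]]$hp
  fd <- fits[[best]]$hd
  if (search_starts < n_starts) {
    # polish the winning combination from the remaining jittered starts
    fp2 <- tryCatch(.fit_core(skel_hp, combos[[best]], n_starts,
                              seed + 17L * best, maxit, start_from = 2L),
                    error = function(e) NULL)
    fd2 <- tryCatch(.fit_core(skel_hd, combos[[best]], n_starts,
                              seed + 17L * best + 7L, maxit,
                              start_from = 2L),
                    error = function(e) NULL)
    if (!is.null(fp2) && fp2$loglik > fp$loglik) fp <- fp2
    if (!is.null(fd2) && fd2$loglik > fd$loglik) fd <- fd2
  }
  lr <- exp(fp$loglik - fd$loglik)
  per_locus <- data.frame(
    locus = skel_hp$loci,
    log10_lr = (fp$per_locus -
                  fd$per_locus[match(skel_hp$loci, skel_hd$loci)]) / log(10))
  out <- list(lr = lr, log10_lr = fp$loglik / log(10) - fd$loglik / log(10),
              flags = combos[[best]], fit_hp = fp, fit_hd = fd,
              per_locus = per_locus, scores = score)
  if (check_reciprocal) {
    fp2 <- .fit_core(skel_hp, combos[[best]], n_starts, seed + 9001L, maxit)
    fd2 <- .fit_core(skel_hd, combos[[best]], n_starts, seed + 9002L, maxit)
    lr_swapped <- exp(fd2$loglik - fp2$loglik)  # relatedness under Hd
    out$lr_reciprocal <- 1 / lr_swapped
  }
  structure(out, class = "cont_lr_result")
}

#' @export
print.cont_lr_result <- function(x, ...) {
  cat("Continuous LR: log10 LR = ", signif(x$log10_lr, 4),
      " (deg=", x$flags$degradation, ", xiB=", x$flags$xi_b,
      ", xiF=", x$flags$xi_f, ")\n", sep = "")
  invisible(x)
}

#' Exponential drop-in rate from validation peak heights
#'
#' Maximum-likelihood estimate of the exponential rate on the height
#' excesses above the analytical threshold: `lambda = 1 / mean(h - AT)`,
#' with a large-sample confidence interval.
#'
#' @param heights drop-in peak heights (all at or above `at`).
#' @param at analytical threshold.
#' @param conf confidence level.
#' @return list with `lambda`, `n` and `ci`.
#' @export
fit_dropin_lambda <- function(heights, at = 50, conf = 0.95) {
  if (!length(heights)) stop("no drop-in heights supplied")
  if (any(heights < at)) stop("drop-in heights must be >= the threshold")
  ex <- mean(heights - at)
  if (ex <= 0) stop("zero mean excess above the threshold; cannot fit a rate")
  lam <- 1 / ex
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- length(heights)
  list(lambda = lam, n = n,
       ci = c(lam * exp(-z / sqrt(n)), lam * exp(z / sqrt(n))))
}

#' Probability-probability model validation
#'
#' For every observed peak, computes its cumulative probability under the
#' fitted genotype-marginalised model (truncated-at-threshold gamma CDF at
#' contributing positions, exponential drop-in CDF otherwise, weighted by
#' the per-locus genotype posterior). If the model is adequate these values
#' are uniform: the table pairs each sorted probability with its empirical
#' plotting position. Loci are flagged as outliers when their peaks deviate
#' from the diagonal by more than `deviation_threshold`, or when a peak's
#' model probability is more extreme than `tail_threshold` (a peak the
#' fitted model can only explain through an astronomically unlikely channel,
#' e.g. a tall peak forced into the drop-in tail by an unmodelled
#' parent-child mutation, sits at 0 or 1 to machine precision while its
#' vertical distance to the diagonal stays small).
#'
#' @param fit a `cont_fit` (typically `result$fit_hp`).
#' @param deviation_threshold flagging threshold on |model - empirical|
#'   (default 0.2).
#' @param tail_threshold flagging threshold on min(U, 1 - U) (default 1e-4).
#' @return list with `table` (locus, replicate, allele, height, model
#'   probability, empirical probability, deviation), `max_deviation`,
#'   `outlier_loci` and the threshold.
#' @export
validate_model <- function(fit, deviation_threshold = 0.2,
                           tail_threshold = 1e-4) {
  skel <- fit$skeleton
  if (is.null(skel$peaks) || !nrow(skel$peaks))
    return(list(table = NULL, max_deviation = NA_real_,
                outlier_loci = character(), threshold = deviation_threshold))
  ev <- .cont_eval(skel, fit$pars_raw, detail = TRUE)
  post_row <- exp(ev$lg_logpost[skel$grp_lg[skel$grp]])
  Frow <- numeric(length(skel$h))
  io <- skel$obs
  wpos <- ev$w > 0 & io
  pl <- stats::pgamma(skel$h[wpos], shape = ev$shape[wpos],
                      scale = ev$scale[wpos])
  p0 <- stats::pgamma(skel$at_row[wpos], shape = ev$shape[wpos],
                      scale = ev$scale[wpos])
  Frow[wpos] <- ifelse(1 - p0 > 1e-12, (pl - p0) / (1 - p0), 1)
  wdi <- ev$w == 0 & io
  Frow[wdi] <- 1 - exp(-skel$lam_row[wdi] * (skel$h[wdi] - skel$at_row[wdi]))
  keep <- io
  u <- rowsum((post_row * Frow)[keep], skel$peak[keep])
  uid <- as.integer(rownames(u))
  tab <- skel$peaks[match(uid, skel$peaks$peak_id), ]
  tab$model_prob <- pmin(pmax(u[, 1], 0), 1)
  tab$tail_prob <- pmin(u[, 1], 1 - u[, 1])
  o <- order(tab$model_prob)
  tab <- tab[o, ]
  n <- nrow(tab)
  tab$empirical <- (seq_len(n) - 0.5) / n
  tab$deviation <- abs(tab$model_prob - tab$empirical)
  rownames(tab) <- NULL
  dev_by_locus <- tapply(tab$deviation, tab$locus, max)
  tail_by_locus <- tapply(tab$tail_prob, tab$locus, min)
  flagged <- union(
    names(dev_by_locus)[dev_by_locus > deviation_threshold],
    names(tail_by_locus)[tail_by_locus < tail_threshold])
  list(table = tab,
       max_deviation = max(tab$deviation),
       outlier_loci = flagged,
       threshold = deviation_threshold)
}
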