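# Synthetic electropherogram generator: pedigrees, replicate profiles with
# degradation / stutter / drop-in / drop-out, case bundles and calibration
# data for the drop-out logistic regression. The generative model mirrors
# the continuous likelihood so that the two form a consistent model pair.

#' Continuous peak-height model parameters
#'
#' Parameters of the gamma peak-height model shared by the simulator and the
#' continuous likelihood: at a position receiving total contribution weight
#' `w`, the peak height is Gamma(shape = w / omega^2, scale = mu * omega^2),
#' so a single heterozygote allele at the 125 bp reference size has mean `mu`
#' and coefficient of variation `omega`. Degradation scales the contribution
#' by `beta^((size - 125) / 100)`; stutter moves proportions `xi_b` / `xi_f`
#' of a parent allele's contribution one repeat back / forward; drop-in adds,
#' with per-locus per-replicate probability `p_c`, a frequency-sampled allele
#' with height `at` plus an Exponential(`lambda`) excess; peaks below the
#' analytical threshold `at` are censored.
#'
#' @param mu expected single-allele heterozygote peak height (RFU) at the
#'   reference size.
#' @param omega coefficient of variation of peak height.
#' @param beta degradation slope per 100 bp, in (0, 1].
#' @param xi_b,xi_f backward / forward stutter proportions (xi_b + xi_f < 1).
#' @param lambda drop-in peak-height rate (per RFU above the threshold).
#' @param p_c per-locus per-replicate drop-in probability.
#' @param at analytical threshold (RFU).
#' @return object of class `continuous_params`.
#' @export
continuous_params <- function(mu, omega, beta = 1, xi_b = 0, xi_f = 0,
                              lambda = 0.05, p_c = 0.05, at = 50) {
  stopifnot(mu > 0, omega > 0, beta > 0, beta <= 1,
            xi_b >= 0, xi_f >= 0, xi_b + xi_f < 1,
            lambda > 0, p_c >= 0, p_c < 1, at > 0)
  structure(list(mu = mu, omega = omega, beta = beta, xi_b = xi_b,
                 xi_f = xi_f, lambda = lambda, p_c = p_c, at = at),
            class = "continuous_params")
}

#' Mildly-degraded preset
#'
#' Default peak-height parameters for the "mildly degraded" simulation class:
#' tall peaks, modest variability, shallow degradation. Chosen so that the
#' stochastic-threshold classifier labels profiles simulated under it as MD.
#'
#' @param lambda drop-in rate (kit-specific; 0.038 and 0.061 for the two demo
#'   kits).
#' @param at analytical threshold.
#' @return a [continuous_params()] object.
#' @export
md_preset <- function(lambda = 0.038, at = 50) {
  continuous_params(mu = 1500, omega = 0.3, beta = 0.95, xi_b = 0.06,
                    xi_f = 0.01, lambda = lambda, p_c = 0.05, at = at)
}

#' Highly-degraded preset
#'
#' Peak-height parameters for the "highly degraded" class: low template,
#' high variability and steep exponential degradation, so amplicons beyond
#' roughly 200 bp drop below the analytical threshold and the
#' stochastic-threshold classifier calls the profile HD. The slope (0.05
#' per 100 bp) was calibrated so that profiles simulated under this preset
#' are classified HD by the 5ST rule in the large majority of cases, which
#' is what the preset label promises; gentler slopes leave 300 bp amplicons
#' at appreciable heights and the classifier (correctly) refuses to call
#' such profiles highly degraded.
#'
#' @inheritParams md_preset
#' @return a [continuous_params()] object.
#' @export
hd_preset <- function(lambda = 0.038, at = 50) {
  continuous_params(mu = 400, omega = 0.45, beta = 0.05, xi_b = 0.06,
                    xi_f = 0.01, lambda = lambda, p_c = 0.05, at = at)
}

#' Simulation configuration
#'
#' Study conditions for cohort simulation. The defaults mirror the casework
#' composition the pipeline emulates: 33 cases of which 21 have maternal
#' information (trios) and 20 are highly degraded, duplicate amplification
#' with one kit plus a single amplification with the complementary kit, and
#' kit-specific drop-in rates.
#'
#' @param seed base RNG seed; per-case substreams are derived by counter so
#'   cases are order-independent.
#' @param n_cases number of cases.
#' @param fraction_trio probability a case has a typed mother.
#' @param fraction_hd probability a case uses the highly-degraded preset.
#' @param md,hd [continuous_params()] presets for the two degradation classes.
#' @param lambda_by_kit named drop-in rates per kit id.
#' @param kits named list of [kit_panel()]s (exactly two).
#' @param freqs an [allele_frequencies()] table covering the kits' loci.
#' @param pop a [population_model()].
#' @param case_kind `"paternal-sample"` (the low-template person is the
#'   alleged father) or `"remains-sample"` (the low-template person is the
#'   child).
#' @param mutation_rate per-transmission mutation probability injected into
#'   simulated pedigrees; 0 by default (mutation is an explicit option, not
#'   part of the standard conditions).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_cases = 33,
                              fraction_trio = 21 / 33,
                              fraction_hd = 20 / 33,
                              md = md_preset(), hd = hd_preset(),
                              lambda_by_kit = c(ESI = 0.038, ESX = 0.061),
                              kits = demo_kits(),
                              freqs = demo_frequencies(),
                              pop = population_model(0.01),
                              case_kind = "paternal-sample",
                              mutation_rate = 0) {
  stopifnot(fraction_trio >= 0, fraction_trio <= 1,
            fraction_hd >= 0, fraction_hd <= 1,
            length(kits) == 2L,
            all(names(kits) %in% names(lambda_by_kit)))
  structure(list(seed = seed, n_cases = n_cases,
                 fraction_trio = fraction_trio, fraction_hd = fraction_hd,
                 md = md, hd = hd, lambda_by_kit = lambda_by_kit,
                 kits = kits, freqs = freqs, pop = pop,
                 case_kind = match.arg(case_kind,
                                       c("paternal-sample", "remains-sample")),
                 mutation_rate = mutation_rate),
            class = "simulation_config")
}

# Derived per-case seed, kept under 2^31.
case_seed <- function(seed, index) {
  v <- (as.numeric(seed) %% 65011 + 1) * 32003 + as.numeric(index) * 7919
  as.integer(v %% 2147483647)
}

#' Sample a pedigree's genotypes
#'
#' Draws founder genotypes allele by allele with Balding-Nichols urn
#' conditioning within the pedigree (father first, then mother), and gives
#' the child one uniformly-chosen allele from each parent. No mutation is
#' injected unless `mutation_rate > 0`, in which case each transmission is
#' replaced, with that probability, by a uniformly-chosen different allele
#' (the equal-probability model).
#'
#' @param freqs an [allele_frequencies()] table.
#' @param pedigree_kind `"trio"` or `"duo"` (recorded on the result; all
#'   three genotypes are always drawn).
#' @param pop a [population_model()].
#' @param mutation_rate per-transmission mutation probability.
#' @return list with `genotype` elements `father`, `mother`, `child` and the
#'   `pedigree_kind`.
#' @export
sample_pedigree <- function(freqs, pedigree_kind = c("trio", "duo"),
                            pop = population_model(),
                            mutation_rate = 0) {
  pedigree_kind <- match.arg(pedigree_kind)
  loci <- names(freqs)
  fa <- mo <- ch <- vector("list", length(loci))
  names(fa) <- names(mo) <- names(ch) <- loci
  for (l in loci) {
    p <- freqs[[l]]
    al <- names(p)
    seen <- character()
    draw <- function() {
      pr <- bn_locus_probs(seen, pop, p)
      a <- sample(al, 1L, prob = pr)
      seen <<- c(seen, a)
      a
    }
    f <- c(draw(), draw())
    m <- c(draw(), draw())
    transmit <- function(g) {
      a <- g[sample.int(2L, 1L)]
      if (mutation_rate > 0 && stats::runif(1) < mutation_rate)
        a <- sample(setdiff(al, a), 1L)
      a
    }
    fa[[l]] <- f
    mo[[l]] <- m
    ch[[l]] <- c(transmit(f), transmit(m))
  }
  list(father = genotype(fa), mother = genotype(mo), child = genotype(ch),
       pedigree_kind = pedigree_kind)
}

#' Simulate one replicate amplification of a genotype
#'
#' Implements the generative peak-height model: per locus, the contribution
#' weight at allele position `a` is
#' `sum_g ((1 - xi_b - xi_f) n_g 1(a = g) + xi_b n_g 1(a = g - 1) +
#'  xi_f n_g 1(a = g + 1)) * beta^((s_a - 125) / 100)`
#' with `n_g` the genotype copy number at `g`; the height at each position
#' with positive weight is Gamma(shape = w / omega^2, scale = mu * omega^2).
#' With probability `p_c` one drop-in allele sampled by population frequency
#' is added with height `at` plus an Exponential(`lambda`) excess. Heights
#' are rounded half-up to integer RFU and peaks below the analytical
#' threshold are removed.
#'
#' @param geno a [genotype()] typed at the kit's loci.
#' @param kit a [kit_panel()].
#' @param params a [continuous_params()] object.
#' @param freqs an [allele_frequencies()] table (drop-in allele sampling).
#' @param sample_id,replicate_id identifiers for the resulting profile.
#' @return a [replicate_profile()].
#' @export
simulate_replicate <- function(geno, kit, params, freqs,
                               sample_id = "sim", replicate_id = 1L) {
  peaks <- list()
  for (l in kit$loci) {
    g <- geno[[l]]
    if (is.null(g)) stop("genotype not typed at kit locus ", l)
    gn <- as.numeric(g)
    pos <- sort(unique(round(c(gn, gn - 1, gn + 1), 1)))
    w <- vapply(pos, function(a) {
      np <- sum(abs(gn - a) < 1e-9)
      nb <- sum(abs(gn - (a + 1)) < 1e-9)
      nf <- sum(abs(gn - (a - 1)) < 1e-9)
      base <- (1 - params$xi_b - params$xi_f) * np +
        params$xi_b * nb + params$xi_f * nf
      if (base <= 0) return(0)
      s <- allele_size(kit, l, a)
      base * params$beta^((s - 125) / 100)
    }, 0)
    keep <- w > 0
    pos <- pos[keep]
    w <- w[keep]
    h <- stats::rgamma(length(pos), shape = w / params$omega^2,
                       scale = params$mu * params$omega^2)
    al <- format_allele(pos)
    sz <- vapply(pos, function(a) allele_size(kit, l, a), 0)
    if (stats::runif(1) < params$p_c) {
      p <- freqs[[l]]
      da <- sample(names(p), 1L, prob = p)
      dh <- params$at + stats::rexp(1L, rate = params$lambda)
      hit <- match(da, al)
      if (is.na(hit)) {
        al <- c(al, da)
        h <- c(h, dh)
        sz <- c(sz, allele_size(kit, l, da))
      } else {
        h[hit] <- h[hit] + dh
      }
    }
    h <- floor(h + 0.5)  # integer RFU, half-up
    keep <- h >= params$at
    if (any(keep)) {
      o <- order(as.numeric(al[keep]))
      peaks[[l]] <- data.frame(allele = al[keep][o],
                               height = h[keep][o],
                               size = sz[keep][o])
    }
  }
  replicate_profile(sample_id, kit$kit_id, replicate_id, peaks,
                    loci = kit$loci)
}

#' Generate one simulated paternity case
#'
#' Draws the pedigree, picks the duplicate kit, and simulates the replicate
#' scheme used throughout: two replicates of the low-template person with one
#' kit plus one replicate with the complementary kit. The low-template
#' person is the alleged father (`"paternal-sample"`) or the child
#' (`"remains-sample"`); references are the remaining typed persons (no
#' maternal genotype in duo cases). Deterministic given `(config$seed,
#' case_index)`.
#'
#' @param config a [simulation_config()].
#' @param case_kind overrides `config$case_kind`.
#' @param case_index case counter used to derive the per-case RNG substream.
#' @return a `case_bundle`: list with `replicates` (list of 3
#'   [replicate_profile()]s), `references` (named genotypes), `hypothesis`
#'   role info, and a `truth` record (all genotypes, preset class label,
#'   pedigree kind, duplicate kit).
#' @export
generate_case <- function(config, case_kind = config$case_kind,
                          case_index = 1L) {
  case_kind <- match.arg(case_kind, c("paternal-sample", "remains-sample"))
  set.seed(case_seed(config$seed, case_index))
  is_trio <- stats::runif(1) < config$fraction_trio
  is_hd <- stats::runif(1) < config$fraction_hd
  preset <- if (is_hd) config$hd else config$md
  kit_ids <- names(config$kits)
  dup_kit <- sample(kit_ids, 1L)
  other_kit <- setdiff(kit_ids, dup_kit)
  ped <- sample_pedigree(config$freqs,
                         pedigree_kind = if (is_trio) "trio" else "duo",
                         pop = config$pop,
                         mutation_rate = config$mutation_rate)
  lt_role <- if (case_kind == "paternal-sample") "father" else "child"
  lt_geno <- ped[[lt_role]]
  sample_id <- sprintf("case%03d", case_index)
  params_for <- function(kid) {
    p <- preset
    p$lambda <- unname(config$lambda_by_kit[[kid]])
    p
  }
  reps <- list(
    simulate_replicate(lt_geno, config$kits[[dup_kit]], params_for(dup_kit),
                       config$freqs, sample_id, 1L),
    simulate_replicate(lt_geno, config$kits[[dup_kit]], params_for(dup_kit),
                       config$freqs, sample_id, 2L),
    simulate_replicate(lt_geno, config$kits[[other_kit]],
                       params_for(other_kit), config$freqs, sample_id, 3L)
  )
  references <- if (case_kind == "paternal-sample") {
    list(child = ped$child)
  } else {
    list(father = ped$father)
  }
  if (is_trio) references$mother <- ped$mother
  structure(list(
    case_id = sample_id,
    replicates = reps,
    references = references,
    ltdna_role = lt_role,
    pedigree = if (is_trio) "trio" else "duo",
    case_kind = case_kind,
    dup_kit = dup_kit,
    truth = list(genotypes = ped[c("father", "mother", "child")],
                 class_preset = if (is_hd) "HD" else "MD",
                 pedigree = if (is_trio) "trio" else "duo",
                 dup_kit = dup_kit,
                 seed = case_seed(config$seed, case_index))
  ), class = "case_bundle")
}

#' Generate drop-out calibration data
#'
#' Simulates heterozygous single-locus amplifications (stutter and drop-in
#' switched off, as in a clean validation series) and pairs each allele's
#' detection outcome with the observed height of its heterozygous partner
#' peak -- the covariate of the drop-out logistic regression. Loci where both
#' alleles fall below the threshold contribute no rows; rows whose partner
#' itself dropped out carry `partner_height = NA` and are flagged.
#'
#' @param kit a [kit_panel()].
#' @param params a [continuous_params()] object (its stutter and drop-in
#'   channels are ignored here).
#' @param n_loci number of heterozygous locus amplifications to simulate.
#' @param freqs an [allele_frequencies()] table.
#' @param pop a [population_model()] (allele sampling).
#' @return data frame with columns `locus`, `allele`, `detected`,
#'   `partner_height`, `partner_detected`.
#' @export
generate_calibration_set <- function(kit, params, n_loci, freqs,
                                     pop = population_model()) {
  clean <- params
  clean$xi_b <- 0
  clean$xi_f <- 0
  clean$p_c <- 0
  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    l <- sample(kit$loci, 1L)
    p <- freqs[[l]]
    al <- sample(names(p), 2L, prob = p)     # heterozygote by construction
    g <- genotype(stats::setNames(list(al), l))
    one <- list()
    one[[l]] <- g[[l]]
    pr <- simulate_replicate(genotype(one), kit_subset(kit, l), clean, freqs,
                             sample_id = "cal", replicate_id = i)
    seen <- pr$peaks[[l]]
    det <- al %in% (if (is.null(seen)) character() else seen$allele)
    if (!any(det)) next
    hts <- vapply(al, function(a) {
      if (is.null(seen)) return(NA_real_)
      j <- match(a, seen$allele)
      if (is.na(j)) NA_real_ else seen$height[j]
    }, 0)
    rows[[i]] <- data.frame(
      locus = l, allele = al, detected = det,
      partner_height = rev(hts),       # covariate: the *other* allele's height
      partner_detected = rev(det))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Single-locus view of a kit (keeps allele_size and AT semantics).
kit_subset <- function(kit, loci) {
  kit_panel(kit$kit_id, loci, kit$size_map[loci], kit$analytical_threshold)
}
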