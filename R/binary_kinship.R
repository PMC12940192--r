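# Binary-arm paternity likelihood ratios on consensus profiles: per-allele
# drop-out observation model, equal-probability mutation model with
# sex-specific rates, Balding-Nichols coancestry correction, duo and trio
# pedigrees. Likelihoods are evaluated by exact enumeration over the
# unknown founder genotypes, with founder alleles sampled sequentially from
# the subpopulation urn (order-invariant by exchangeability).

#' Equal-probability mutation model
#'
#' Per-locus mutation rates for male and female transmissions. Under the
#' equal-probability model a transmitted allele mutates with probability `r`
#' and the mutant is uniform over the other `k - 1` alleles of the locus,
#' so the transition matrix rows sum to one.
#'
#' @param default_rate rate used where no per-locus rate is given
#'   (default 0.002).
#' @param male,female optional named numeric vectors of per-locus overrides
#'   (e.g. `c(SE33 = 0.0064, TH01 = 0.0001)`).
#' @return object of class `mutation_model`.
#' @export
mutation_model <- function(default_rate = 0.002, male = numeric(),
                           female = numeric()) {
  stopifnot(default_rate >= 0, default_rate < 1,
            all(male >= 0), all(male < 1),
            all(female >= 0), all(female < 1))
  structure(list(default_rate = default_rate, male = male, female = female),
            class = "mutation_model")
}

#' Mutation rate for a locus and transmitting sex
#'
#' @param mut a [mutation_model()].
#' @param locus locus name.
#' @param sex `"male"` or `"female"`.
#' @return mutation rate.
#' @export
mutation_rate <- function(mut, locus, sex = c("male", "female")) {
  sex <- match.arg(sex)
  tab <- mut[[sex]]
  if (!is.null(tab) && locus %in% names(tab)) unname(tab[[locus]])
  else mut$default_rate
}

#' Observation probability of a consensus locus state
#'
#' Each of a true genotype's two allele copies drops independently with the
#' locus's assigned drop-out probability `d`; the observed consensus set is
#' the set of non-dropped designations and there is no drop-in channel.
#' A two-allele consensus requires the matching heterozygous genotype
#' (d = 0); a single-allele consensus A has probability `1 - d^2` under A/A
#' and `(1 - d) * d` under A/X; any observed allele outside the genotype has
#' probability zero. An excluded locus contributes no factor (returns 1).
#'
#' @param observed character vector of consensus alleles (length 0, 1 or 2).
#' @param true_genotype character vector of length 2.
#' @param d drop-out probability assigned to the locus.
#' @return probability.
#' @export
obs_prob <- function(observed, true_genotype, d) {
  o <- sort(unique(observed))
  g <- sort(true_genotype)
  if (length(o) == 0L) return(1)
  if (length(o) == 2L)
    return(as.numeric(g[1] != g[2] && identical(o, g)))
  a <- o
  if (g[1] == a && g[2] == a) return(1 - d^2)
  if (a %in% g) return((1 - d) * d)
  0
}

#' Parent-to-child transmission probability
#'
#' Equal-probability mutation model: the parent transmits each of its two
#' alleles with probability 1/2; the transmitted allele is passed unchanged
#' with probability `1 - r` and otherwise mutates uniformly to one of the
#' other `k - 1` alleles of the locus.
#'
#' @param parent_genotype character vector of length 2.
#' @param child_allele allele designation.
#' @param r mutation rate.
#' @param k number of alleles at the locus.
#' @return probability.
#' @export
transmission_prob <- function(parent_genotype, child_allele, r, k) {
  stopifnot(k >= 2)
  mean(ifelse(parent_genotype == child_allele, 1 - r, r / (k - 1)))
}

#' Duo/trio hypothesis pair for the binary arm
#'
#' @param ltdna_role who the low-template sample is: the alleged `"father"`
#'   or the `"child"` (remains identification).
#' @param pedigree `"duo"` (no maternal genotype) or `"trio"`.
#' @return object of class `binary_hypothesis`.
#' @export
binary_hypothesis <- function(ltdna_role = c("father", "child"),
                              pedigree = c("duo", "trio")) {
  structure(list(ltdna_role = match.arg(ltdna_role),
                 pedigree = match.arg(pedigree)),
            class = "binary_hypothesis")
}

# --- internal enumeration machinery ---------------------------------------

# Sequential Balding-Nichols probability of drawing the allele index columns
# of `idx` in order, after the fixed conditioning indices `seen_idx`.
seq_bn_prob <- function(idx, seen_idx, th, p) {
  idx <- as.matrix(idx)
  out <- rep(1, nrow(idx))
  n0 <- length(seen_idx)
  for (t in seq_len(ncol(idx))) {
    m <- rep(0, nrow(idx))
    for (s in seen_idx) m <- m + (idx[, t] == s)
    if (t > 1L) for (s in seq_len(t - 1L)) m <- m + (idx[, t] == idx[, s])
    n <- n0 + t - 1L
    out <- out * (m * th + (1 - th) * p[idx[, t]]) / (1 + (n - 1) * th)
  }
  out
}

# Transition matrix by allele index under the equal-probability model.
tmat_idx <- function(k, r) {
  M <- matrix(r / (k - 1), k, k)
  diag(M) <- 1 - r
  M
}

# Observation factor over enumerated ordered genotype index pairs.
obs_pair_vec <- function(i, j, al, observed, d) {
  o <- sort(unique(observed))
  if (length(o) == 0L) return(rep(1, length(i)))
  if (length(o) == 2L) {
    ia <- match(o[1], al); ib <- match(o[2], al)
    return(as.numeric((i == ia & j == ib) | (i == ib & j == ia)))
  }
  ia <- match(o, al)
  ifelse(i == ia & j == ia, 1 - d^2,
         ifelse(i == ia | j == ia, (1 - d) * d, 0))
}

# Marginal probability that an untyped founder parent transmits allele index
# `c_idx` to the child, given conditioning draws `cond_idx` (matrix of allele
# indices, one row per enumerated configuration), with mutation rate r.
# By exchangeability of the urn the transmitted allele's marginal equals the
# next-draw distribution.
q_untyped_parent <- function(c_idx, cond_idx, th, p, r, k) {
  cond_idx <- as.matrix(cond_idx)
  m <- rowSums(cond_idx == c_idx)
  n <- ncol(cond_idx)
  bnc <- (m * th + (1 - th) * p[c_idx]) / (1 + (n - 1) * th)
  (1 - r) * bnc + (r / (k - 1)) * (1 - bnc)
}

# Per-locus binary likelihoods (numerator, denominator) when the LT-DNA
# person is the alleged father.
lik_ltdna_father <- function(pedigree, observed, d, child, mother,
                             al, p, th, r_m, r_f) {
  k <- length(al)
  ci <- match(child, al)
  het <- ci[1] != ci[2]
  Tm <- tmat_idx(k, r_m)
  tp <- function(pi, pj, cc) (Tm[cbind(pi, cc)] + Tm[cbind(pj, cc)]) / 2
  g2 <- expand.grid(i = seq_len(k), j = seq_len(k))
  if (pedigree == "trio") {
    mi <- match(mother, al)
    Tf <- tmat_idx(k, r_f)
    tM <- function(cc) (Tf[mi[1], cc] + Tf[mi[2], cc]) / 2
    pM <- seq_bn_prob(matrix(mi, 1), integer(), th, p)
    pc2 <- function(pi, pj) {
      if (het) tp(pi, pj, ci[1]) * tM(ci[2]) + tp(pi, pj, ci[2]) * tM(ci[1])
      else tp(pi, pj, ci[1]) * tM(ci[1])
    }
    pF <- seq_bn_prob(cbind(g2$i, g2$j), mi, th, p)
    Lp <- pM * sum(pF * obs_pair_vec(g2$i, g2$j, al, observed, d) *
                     pc2(g2$i, g2$j))
    g4 <- expand.grid(ui = seq_len(k), uj = seq_len(k),
                      fi = seq_len(k), fj = seq_len(k))
    pUF <- seq_bn_prob(cbind(g4$ui, g4$uj, g4$fi, g4$fj), mi, th, p)
    Ld <- pM * sum(pUF * pc2(g4$ui, g4$uj) *
                     obs_pair_vec(g4$fi, g4$fj, al, observed, d))
  } else {
    q <- function(cc, cond) q_untyped_parent(cc, cond, th, p, r_f, k)
    pcduo <- function(pi, pj, cond) {
      if (het) tp(pi, pj, ci[1]) * q(ci[2], cond) +
        tp(pi, pj, ci[2]) * q(ci[1], cond)
      else tp(pi, pj, ci[1]) * q(ci[1], cond)
    }
    pF <- seq_bn_prob(cbind(g2$i, g2$j), integer(), th, p)
    Lp <- sum(pF * obs_pair_vec(g2$i, g2$j, al, observed, d) *
                pcduo(g2$i, g2$j, cbind(g2$i, g2$j)))
    g4 <- expand.grid(fi = seq_len(k), fj = seq_len(k),
                      ui = seq_len(k), uj = seq_len(k))
    pFU <- seq_bn_prob(cbind(g4$fi, g4$fj, g4$ui, g4$uj), integer(), th, p)
    Ld <- sum(pFU * obs_pair_vec(g4$fi, g4$fj, al, observed, d) *
                pcduo(g4$ui, g4$uj, cbind(g4$fi, g4$fj, g4$ui, g4$uj)))
  }
  c(Lp, Ld)
}

# Per-locus binary likelihoods when the LT-DNA person is the child.
lik_ltdna_child <- function(pedigree, observed, d, father, mother,
                            al, p, th, r_m, r_f) {
  k <- length(al)
  fi <- match(father, al)
  Tm <- tmat_idx(k, r_m)
  tpF <- (Tm[fi[1], ] + Tm[fi[2], ]) / 2
  g2 <- expand.grid(cp = seq_len(k), cm = seq_len(k))  # paternal, maternal
  obs2 <- obs_pair_vec(g2$cp, g2$cm, al, observed, d)
  if (pedigree == "trio") {
    mi <- match(mother, al)
    Tf <- tmat_idx(k, r_f)
    tpM <- (Tf[mi[1], ] + Tf[mi[2], ]) / 2
    pRefs <- seq_bn_prob(matrix(c(mi, fi), 1), integer(), th, p)
    Lp <- pRefs * sum(tpF[g2$cp] * tpM[g2$cm] * obs2)
    pC <- seq_bn_prob(cbind(g2$cp, g2$cm), c(mi, fi), th, p)
    Ld <- pRefs * sum(pC * obs2)
  } else {
    pRefs <- seq_bn_prob(matrix(fi, 1), integer(), th, p)
    qv <- vapply(seq_len(k), function(cc)
      q_untyped_parent(cc, matrix(fi, 1), th, p, r_f, k), 0)
    Lp <- pRefs * sum(tpF[g2$cp] * qv[g2$cm] * obs2)
    pC <- seq_bn_prob(cbind(g2$cp, g2$cm), fi, th, p)
    Ld <- pRefs * sum(pC * obs2)
  }
  c(Lp, Ld)
}

#' Binary paternity likelihood ratio
#'
#' Per-locus and combined LR of parent-child versus unrelated for a
#' consensus profile against error-free reference genotypes. Each locus LR
#' is `L(Hp) / L(Hd)` where the likelihood sums, over all genotypes of the
#' low-template person, the drop-out observation probability times the
#' pedigree genotype probability: founder alleles are sampled sequentially
#' with the Balding-Nichols theta correction conditioned on all alleles
#' already sampled in the pedigree, transmissions use the equal-probability
#' mutation model with sex-specific rates, the alternative parent under Hd
#' is an unrelated founder, and an untyped mother in duo cases is
#' marginalised. Excluded loci contribute no factor; loci missing from the
#' references are skipped with a warning. The case LR is the product over
#' contributing loci.
#'
#' @param consensus a `consensus_profile` of the low-template person.
#' @param references named list of [genotype()]s: `child` (and optionally
#'   `mother`) when the low-template person is the father; `father` (and
#'   optionally `mother`) when it is the child.
#' @param hypothesis a [binary_hypothesis()].
#' @param freqs an [allele_frequencies()] table.
#' @param pop a [population_model()].
#' @param mut a [mutation_model()].
#' @return object of class `binary_lr_result` with a per-locus table
#'   (`locus`, `status`, `lr`, `log10_lr`), the combined `lr` and
#'   `log10_lr`, and the informative-locus count.
#' @export
paternity_lr <- function(consensus, references, hypothesis,
                         freqs, pop = population_model(),
                         mut = mutation_model()) {
  role <- hypothesis$ltdna_role
  pedigree <- hypothesis$pedigree
  main_ref <- if (role == "father") "child" else "father"
  if (is.null(references[[main_ref]]))
    stop("references must include the ", main_ref, " genotype")
  if (pedigree == "trio" && is.null(references$mother))
    stop("trio calculations need the maternal genotype")
  th <- pop$theta
  loci <- names(consensus$loci)
  lr <- rep(NA_real_, length(loci))
  status <- vapply(consensus$loci, `[[`, "", "status")
  for (i in seq_along(loci)) {
    l <- loci[i]
    st <- consensus$loci[[l]]
    if (st$status == "excluded") next
    refg <- references[[main_ref]][[l]]
    mog <- if (pedigree == "trio") references$mother[[l]] else NULL
    if (is.null(refg) || (pedigree == "trio" && is.null(mog))) {
      warning("locus ", l, " missing in references; skipped")
      next
    }
    need <- c(st$alleles, refg, mog)
    fl <- locus_frequencies(freqs, l, need, pop)
    al <- names(fl)
    k <- length(al)
    r_m <- mutation_rate(mut, l, "male")
    r_f <- mutation_rate(mut, l, "female")
    L <- if (role == "father") {
      lik_ltdna_father(pedigree, st$alleles, st$d, refg, mog,
                       al, unname(fl), th, r_m, r_f)
    } else {
      lik_ltdna_child(pedigree, st$alleles, st$d, refg, mog,
                      al, unname(fl), th, r_m, r_f)
    }
    lr[i] <- if (L[2] == 0) Inf else L[1] / L[2]
  }
  used <- !is.na(lr)
  combined <- prod(lr[used])
  structure(list(
    per_locus = data.frame(locus = loci, status = status, lr = lr,
                           log10_lr = log10(lr), row.names = NULL),
    lr = combined, log10_lr = log10(combined),
    n_informative = sum(status != "excluded"),
    hypothesis = hypothesis, pedigree = pedigree),
    class = "binary_lr_result")
}

#' @export
print.binary_lr_result <- function(x, ...) {
  cat("Binary ", x$pedigree, " LR (LT-DNA ", x$hypothesis$ltdna_role,
      "): log10 LR = ", signif(x$log10_lr, 4), " over ",
      sum(!is.na(x$per_locus$lr)), " loci\n", sep = "")
  invisible(x)
}

#' Trio and duo views of the same case
#'
#' Computes the paternity LR twice from identical inputs, with and without
#' the maternal genotype, as when maternal information is available but its
#' contribution is examined.
#'
#' @inheritParams paternity_lr
#' @return list with elements `trio` and `duo`, both `binary_lr_result`s.
#' @export
trio_and_duo_views <- function(consensus, references, freqs,
                               pop = population_model(),
                               mut = mutation_model(),
                               ltdna_role = "father") {
  if (is.null(references$mother))
    stop("trio/duo comparison needs a case with maternal data")
  trio <- paternity_lr(consensus, references,
                       binary_hypothesis(ltdna_role, "trio"),
                       freqs, pop, mut)
  refs_duo <- references[setdiff(names(references), "mother")]
  duo <- paternity_lr(consensus, refs_duo,
                      binary_hypothesis(ltdna_role, "duo"),
                      freqs, pop, mut)
  list(trio = trio, duo = duo)
}
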