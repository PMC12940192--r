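# Independent brute-force oracles. These re-derive likelihoods by explicit
# enumeration (every founder allele pair, transmission, mutation outcome and
# drop-out mask; numerical quadrature for the censored gamma), sharing no
# code with the package's likelihood implementations.

# Sequential urn probability of one more allele given the multiset seen.
.o_urn <- function(a, seen, th, p) {
  m <- sum(seen == a)
  n <- length(seen)
  unname((m * th + (1 - th) * p[[a]]) / (1 + (n - 1) * th))
}

# P(observed set O | genotype (x, y), drop-out d) by enumerating drop masks.
.o_obs <- function(O, g, d) {
  tot <- 0
  for (d1 in 0:1) for (d2 in 0:1) {
    kept <- c(if (!d1) g[1], if (!d2) g[2])
    pr <- d^(d1 + d2) * (1 - d)^(2 - d1 - d2)
    if (setequal(unique(kept), O) &&
        (length(O) < 2 || length(unique(kept)) == 2)) tot <- tot + pr
  }
  tot
}

# Equal-probability mutation transition.
.o_mut <- function(from, to, r, k) if (from == to) 1 - r else r / (k - 1)

# Child-genotype probability given a transmitted-pair distribution is
# enumerated inline below; multiset comparison helper:
.o_same_geno <- function(a, b, g) setequal(c(a, b), g) &&
  (sum(c(a, b) == g[1]) == sum(g == g[1]) || g[1] != g[2])

# Full-enumeration binary locus likelihoods (numerator, denominator).
# O: observed consensus alleles (character, length 0/1/2); d: drop-out prob;
# child/mother/father: character pairs (mother NULL for duo);
# p: named frequency vector; th: theta; r_m/r_f: mutation rates.
oracle_binary_lik <- function(role, pedigree, O, d, child = NULL,
                              mother = NULL, father = NULL, p, th,
                              r_m = 0, r_f = 0) {
  al <- names(p)
  k <- length(al)
  # probability that a parent with genotype (g1,g2) transmits allele c
  trans <- function(g, cc) {
    s <- 0
    for (t in g) s <- s + 0.5 * .o_mut(t, cc, r_m, k)
    s
  }
  transf <- function(g, cc) {
    s <- 0
    for (t in g) s <- s + 0.5 * .o_mut(t, cc, r_f, k)
    s
  }
  # maternal transmitted allele marginal for an untyped mother: enumerate her
  # genotype from the urn given `seen`, then transmission with mutation
  qm <- function(cc, seen) {
    s <- 0
    for (m1 in al) for (m2 in al) {
      pm <- .o_urn(m1, seen, th, p) * .o_urn(m2, c(seen, m1), th, p)
      s <- s + pm * transf(c(m1, m2), cc)
    }
    s
  }
  child_prob <- function(fg, mg, seen_for_untyped) {
    # P(child | father genotype fg, mother genotype mg or untyped)
    s <- 0
    for (cp in al) for (cm in al) {
      if (!setequal(c(cp, cm), child)) next
      # ordered assignment (paternal cp, maternal cm); skip double counting
      if (child[1] != child[2] || cp == cm) {
        pmat <- if (is.null(mg)) qm(cm, seen_for_untyped)
        else transf(mg, cm)
        contrib <- trans(fg, cp) * pmat
        if (child[1] != child[2] && cp != cm) s <- s + contrib
        if (child[1] == child[2] && cp == cm) s <- s + contrib
      }
    }
    s
  }
  if (role == "father") {
    Lp <- Ld <- 0
    if (pedigree == "duo") {
      for (a in al) for (b in al) {
        pF <- .o_urn(a, character(), th, p) * .o_urn(b, a, th, p)
        Lp <- Lp + pF * .o_obs(O, c(a, b), d) * child_prob(c(a, b), NULL,
                                                           c(a, b))
        for (u1 in al) for (u2 in al) {
          pU <- .o_urn(u1, c(a, b), th, p) * .o_urn(u2, c(a, b, u1), th, p)
          Ld <- Ld + pF * pU * .o_obs(O, c(a, b), d) *
            child_prob(c(u1, u2), NULL, c(a, b, u1, u2))
        }
      }
    } else {
      pM <- .o_urn(mother[1], character(), th, p) *
        .o_urn(mother[2], mother[1], th, p)
      for (a in al) for (b in al) {
        pF <- .o_urn(a, mother, th, p) * .o_urn(b, c(mother, a), th, p)
        Lp <- Lp + pF * .o_obs(O, c(a, b), d) * child_prob(c(a, b), mother)
        for (f1 in al) for (f2 in al) {
          pFF <- .o_urn(f1, c(mother, a, b), th, p) *
            .o_urn(f2, c(mother, a, b, f1), th, p)
          Ld <- Ld + pF * pFF * child_prob(c(a, b), mother) *
            .o_obs(O, c(f1, f2), d)
        }
      }
      Lp <- pM * Lp
      Ld <- pM * Ld
    }
    c(Lp, Ld)
  } else {
    # role "child": the low-template person is the child; father typed
    Lp <- Ld <- 0
    seen_refs <- c(if (pedigree == "trio") mother, father)
    pRefs <- 1
    seen <- character()
    for (a in seen_refs) {
      pRefs <- pRefs * .o_urn(a, seen, th, p)
      seen <- c(seen, a)
    }
    for (cp in al) for (cm in al) {
      obsf <- .o_obs(O, c(cp, cm), d)
      pmat <- if (pedigree == "trio") transf(mother, cm)
      else qm(cm, father)
      Lp <- Lp + trans(father, cp) * pmat * obsf
    }
    for (c1 in al) for (c2 in al) {
      pC <- .o_urn(c1, seen_refs, th, p) *
        .o_urn(c2, c(seen_refs, c1), th, p)
      Ld <- Ld + pC * .o_obs(O, c(c1, c2), d)
    }
    c(pRefs * Lp, pRefs * Ld)
  }
}

# Independent continuous locus likelihood: explicit per-position factors with
# the censoring mass obtained by quadrature instead of the distribution's CDF.
oracle_cont_lik <- function(peaks_by_rep, locus, geno, params, kit, fl) {
  gn <- round(as.numeric(geno), 1)
  lik <- 1
  for (pk in peaks_by_rep) {
    obs_al <- if (is.null(pk)) character() else as.character(pk$allele)
    obs_h <- if (is.null(pk)) numeric() else pk$height
    pos <- sort(unique(c(gn, gn - 1, gn + 1, round(as.numeric(obs_al), 1))))
    ndropin <- 0
    for (a in pos) {
      w <- 0
      for (g in gn) {
        if (abs(g - a) < 1e-9) w <- w + (1 - params$xi_b - params$xi_f)
        if (abs((g - 1) - a) < 1e-9) w <- w + params$xi_b
        if (abs((g + 1) - a) < 1e-9) w <- w + params$xi_f
      }
      if (w > 0)
        w <- w * params$beta^((allele_size(kit, locus, a) - 125) / 100)
      sh <- w / params$omega^2
      sc <- params$mu * params$omega^2
      hit <- match(format_allele(a), obs_al)
      if (w > 0 && !is.na(hit)) {
        h <- obs_h[hit]
        lik <- lik * h^(sh - 1) * exp(-h / sc) / (gamma(sh) * sc^sh)
      } else if (w > 0) {
        cens <- stats::integrate(function(x)
          x^(sh - 1) * exp(-x / sc) / (gamma(sh) * sc^sh),
          0, params$at, rel.tol = 1e-12)$value
        lik <- lik * cens
      } else if (!is.na(hit)) {
        h <- obs_h[hit]
        lik <- lik * params$p_c * fl[[format_allele(a)]] * params$lambda *
          exp(-params$lambda * (h - params$at))
        ndropin <- ndropin + 1
      }
    }
    if (ndropin == 0) lik <- lik * (1 - params$p_c)
  }
  lik
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments.
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W_obs <- sum(rk[d > 0])
  ew <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- signs %*% rk
  mean(abs(W_all - ew) >= abs(W_obs - ew) - 1e-12)
}
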