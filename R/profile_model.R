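# Domain types and I/O shared by every stage: kit panels, allele frequency
# tables, population model, genotypes, replicate electropherogram profiles.

#' Canonical allele designation
#'
#' Allele designations are decimal strings so that microvariants such as
#' "9.3" survive round-trips; this maps a numeric repeat count back to its
#' canonical string form ("9", "9.3").
#'
#' Non-numeric labels (used in worked examples) pass through unchanged.
#'
#' @param x allele designation(s), numeric or character.
#' @return character vector of canonical designations.
#' @export
format_allele <- function(x) {
  xs <- as.character(x)
  n <- suppressWarnings(as.numeric(xs))
  ok <- !is.na(n)
  xs[ok] <- sub("\\.0$", "", sprintf("%.1f", round(n[ok], 1)))
  xs
}

# Ordering permutation for allele designations: numeric when possible,
# lexical otherwise.
allele_order <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) order(x) else order(n)
}

#' STR kit panel definition
#'
#' A kit panel names its loci, maps allele designations to expected fragment
#' sizes via a per-locus linear size map (intercept plus repeat-unit length;
#' the fractional part of a microvariant designation contributes its digit in
#' bases), and carries the analytical threshold below which peaks are noise.
#'
#' @param kit_id single character label, e.g. "ESI".
#' @param loci character vector of locus names (ordered).
#' @param size_map named list, one entry per locus, each a numeric vector with
#'   elements `intercept` (bp) and `repeat_bp` (bp per repeat unit).
#' @param analytical_threshold peak height (RFU) below which peaks are
#'   discarded; default 50.
#' @return object of class `kit_panel`.
#' @export
kit_panel <- function(kit_id, loci, size_map, analytical_threshold = 50) {
  stopifnot(is.character(kit_id), length(kit_id) == 1L,
            analytical_threshold > 0)
  loci <- as.character(loci)
  missing <- setdiff(loci, names(size_map))
  if (length(missing))
    stop("every locus needs a size_map entry; missing: ",
         paste(missing, collapse = ", "))
  size_map <- size_map[loci]
  for (l in loci) {
    sm <- size_map[[l]]
    if (!all(c("intercept", "repeat_bp") %in% names(sm)))
      stop("size_map entry for ", l, " needs 'intercept' and 'repeat_bp'")
    if (sm[["repeat_bp"]] <= 0)
      stop("repeat unit length must be positive at locus ", l)
  }
  structure(list(kit_id = kit_id, loci = loci, size_map = size_map,
                 analytical_threshold = analytical_threshold),
            class = "kit_panel")
}

#' @export
print.kit_panel <- function(x, ...) {
  cat("STR kit panel '", x$kit_id, "': ", length(x$loci), " loci, AT = ",
      x$analytical_threshold, " RFU\n", sep = "")
  invisible(x)
}

#' Expected fragment size of an allele
#'
#' @param kit a [kit_panel()].
#' @param locus locus name.
#' @param allele allele designation(s), character or numeric; the integer part
#'   counts repeat units, the fractional digit counts extra bases.
#' @return numeric fragment size(s) in bp.
#' @export
allele_size <- function(kit, locus, allele) {
  sm <- kit$size_map[[locus]]
  if (is.null(sm))
    stop("unknown locus for kit ", kit$kit_id, ": ", locus)
  a <- as.numeric(allele)
  ip <- floor(a)
  fp <- round(10 * (a - ip))
  unname(sm[["intercept"]] + ip * sm[["repeat_bp"]] + fp)
}

#' Build a synthetic kit panel with a linear size layout
#'
#' Convenience constructor used by the demo kits and by simulation studies
#' needing large locus panels: every locus gets the same repeat-unit length
#' and its own size intercept.
#'
#' @param kit_id kit label.
#' @param loci character vector of locus names.
#' @param intercepts named numeric vector of size intercepts (bp), one per
#'   locus.
#' @param repeat_bp repeat-unit length in bp (default 4).
#' @inheritParams kit_panel
#' @return a `kit_panel`.
#' @export
synthetic_kit <- function(kit_id, loci, intercepts, repeat_bp = 4,
                          analytical_threshold = 50) {
  size_map <- lapply(loci, function(l)
    c(intercept = unname(intercepts[[l]]), repeat_bp = repeat_bp))
  names(size_map) <- loci
  kit_panel(kit_id, loci, size_map, analytical_threshold)
}

#' Bundled demonstration kits
#'
#' Two synthetic 16-locus autosomal STR panels covering the same loci with
#' complementary amplicon layouts: the size intercepts of one kit are the
#' reverse of the other, so loci amplifying long in one kit amplify short in
#' the other. This mirrors commercial kit pairs designed so their combination
#' maximises allele recovery from degraded DNA. Sizes are synthetic (shared
#' 4 bp repeat, linear layout), not the vendors' calibrations.
#'
#' @param analytical_threshold RFU threshold, default 50.
#' @return named list with `kit_panel` elements `ESI` and `ESX`.
#' @export
demo_kits <- function(analytical_threshold = 50) {
  loci <- c("D3S1358", "vWA", "D16S539", "D2S1338", "D8S1179", "D21S11",
            "D18S51", "D19S433", "TH01", "FGA", "D22S1045", "D2S441",
            "D10S1248", "D1S1656", "D12S391", "SE33")
  base <- seq(60, 285, by = 15)
  list(
    ESI = synthetic_kit("ESI", loci, stats::setNames(base, loci),
                        analytical_threshold = analytical_threshold),
    ESX = synthetic_kit("ESX", loci, stats::setNames(rev(base), loci),
                        analytical_threshold = analytical_threshold)
  )
}

# ---------------------------------------------------------------------------
# Allele frequencies

#' Allele frequency table
#'
#' @param freqs named list, one element per locus, each a named numeric vector
#'   mapping allele designation to frequency. Frequencies must be positive;
#'   each locus is renormalised to sum to one.
#' @param n_observed optional number of individuals behind the table, used for
#'   the rare-allele frequency floor `5 / (2 * n_observed)`.
#' @return object of class `allele_frequencies`.
#' @export
allele_frequencies <- function(freqs, n_observed = NULL) {
  stopifnot(is.list(freqs), length(freqs) > 0)
  out <- lapply(names(freqs), function(l) {
    p <- freqs[[l]]
    if (is.null(names(p)) || any(!nzchar(names(p))))
      stop("alleles must be named at locus ", l)
    if (anyDuplicated(format_allele(names(p))))
      stop("duplicate allele at locus ", l)
    if (any(!is.finite(p)) || any(p <= 0))
      stop("frequencies must be positive at locus ", l)
    names(p) <- format_allele(names(p))
    p <- p[allele_order(names(p))]
    p / sum(p)
  })
  names(out) <- names(freqs)
  structure(out, n_observed = n_observed, class = "allele_frequencies")
}

#' @export
print.allele_frequencies <- function(x, ...) {
  cat("Allele frequency table:", length(x), "loci,",
      sum(lengths(x)), "alleles\n")
  invisible(x)
}

#' Read an allele frequency table from delimited text
#'
#' Expects a header row with columns `locus`, `allele`, `frequency`; the field
#' separator (comma or tab) is autodetected. Frequencies are renormalised per
#' locus; non-positive frequencies and duplicate (locus, allele) rows are
#' rejected.
#'
#' @param path file path.
#' @param n_observed optional sample size behind the table (rare-allele floor).
#' @return an [allele_frequencies()] object.
#' @export
read_frequency_table <- function(path, n_observed = NULL) {
  tab <- .read_delim_auto(path)
  need <- c("locus", "allele", "frequency")
  if (!all(need %in% names(tab)))
    stop("frequency table needs columns: ", paste(need, collapse = ", "))
  tab$frequency <- as.numeric(tab$frequency)
  freqs <- lapply(split(tab, tab$locus), function(d)
    stats::setNames(d$frequency, as.character(d$allele)))
  allele_frequencies(freqs, n_observed = n_observed)
}

#' Write an allele frequency table as tab-separated text
#'
#' @param freqs an [allele_frequencies()] object.
#' @param path output path.
#' @export
write_frequency_table <- function(freqs, path) {
  rows <- do.call(rbind, lapply(names(freqs), function(l)
    data.frame(locus = l, allele = names(freqs[[l]]),
               frequency = unname(freqs[[l]]))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", strip.white = TRUE)
}

# Rare-allele floor frequency for alleles absent from the table.
rare_floor_value <- function(freqs, pop) {
  if (!is.null(pop$rare_allele_floor)) return(pop$rare_allele_floor)
  n <- attr(freqs, "n_observed")
  if (is.null(n)) 0.001 else 5 / (2 * n)
}

#' Per-locus frequencies with rare-allele flooring
#'
#' Returns the frequency vector for one locus, extended so that every allele
#' in `alleles` is present: alleles absent from the table get the floor
#' frequency (`5 / (2 n)` when the table's sample size is known, otherwise
#' 0.001, overridable via the population model), and the locus is
#' renormalised.
#'
#' @param freqs an [allele_frequencies()] object.
#' @param locus locus name.
#' @param alleles character vector of allele designations that must be
#'   present (may be empty).
#' @param pop a [population_model()].
#' @return named numeric vector summing to one.
#' @export
locus_frequencies <- function(freqs, locus, alleles = character(),
                              pop = population_model()) {
  p <- freqs[[locus]]
  if (is.null(p)) stop("locus not in frequency table: ", locus)
  alleles <- format_allele(alleles)
  missing <- setdiff(alleles, names(p))
  if (length(missing)) {
    fl <- rare_floor_value(freqs, pop)
    p <- c(p, stats::setNames(rep(fl, length(missing)), missing))
    p <- p[allele_order(names(p))]
    p <- p / sum(p)
  }
  p
}

# ---------------------------------------------------------------------------
# Population model and Balding-Nichols sampling

#' Population substructure model
#'
#' Holds the coancestry coefficient theta (the F_ST correction applied to all
#' allele probabilities) and an optional override of the rare-allele floor.
#'
#' @param theta coancestry coefficient in [0, 1); default 0.01.
#' @param rare_allele_floor optional minimum frequency for alleles unseen in
#'   the frequency table; when `NULL` the floor is derived from the table.
#' @return object of class `population_model`.
#' @export
population_model <- function(theta = 0.01, rare_allele_floor = NULL) {
  stopifnot(theta >= 0, theta < 1)
  structure(list(theta = theta, rare_allele_floor = rare_allele_floor),
            class = "population_model")
}

#' Balding-Nichols sequential allele probability
#'
#' Probability of sampling `allele` next from the subpopulation urn, given
#' the multiset of alleles already sampled:
#' `(m * theta + (1 - theta) * p_a) / (1 + (n - 1) * theta)`,
#' where `m` is the number of copies of `allele` already seen and `n` the
#' total number of alleles already seen. With theta = 0 this reduces to the
#' population frequency.
#'
#' @param allele allele designation.
#' @param seen_alleles character vector (multiset) of alleles already sampled
#'   in the pedigree; may be empty.
#' @param pop a [population_model()].
#' @param freqs named numeric vector of allele frequencies for the locus
#'   (e.g. from [locus_frequencies()]).
#' @return probability.
#' @export
bn_allele_prob <- function(allele, seen_alleles, pop, freqs) {
  allele <- format_allele(allele)
  p <- freqs[[allele]]
  if (is.null(p) || is.na(p))
    stop("allele not in frequency vector: ", allele)
  th <- pop$theta
  m <- sum(seen_alleles == allele)
  n <- length(seen_alleles)
  (m * th + (1 - th) * p) / (1 + (n - 1) * th)
}

#' Balding-Nichols probabilities over a whole locus
#'
#' Vectorised form of [bn_allele_prob()]: the sampling distribution of the
#' next allele over every allele in `freqs`, given the conditioning multiset.
#'
#' @inheritParams bn_allele_prob
#' @return named numeric vector summing to one.
#' @export
bn_locus_probs <- function(seen_alleles, pop, freqs) {
  th <- pop$theta
  m <- if (length(seen_alleles)) {
    as.numeric(table(factor(seen_alleles, levels = names(freqs))))
  } else rep(0, length(freqs))
  n <- length(seen_alleles)
  stats::setNames((m * th + (1 - th) * freqs) / (1 + (n - 1) * th),
                  names(freqs))
}

# ---------------------------------------------------------------------------
# Genotypes

#' Reference genotype
#'
#' A genotype is a named list mapping locus name to an unordered allele pair
#' (character vector of length two; homozygotes repeat the allele). This
#' constructor canonicalises designations and validates the pair lengths.
#'
#' @param x named list of length-2 allele vectors.
#' @return object of class `genotype` (a named list).
#' @export
genotype <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)))
  out <- lapply(x, function(g) {
    if (length(g) != 2L) stop("each typed locus needs exactly 2 allele copies")
    format_allele(g)
  })
  structure(out, class = "genotype")
}

#' Read reference genotypes from delimited text
#'
#' Columns `sample`, `locus`, `allele1`, `allele2`; separator autodetected.
#'
#' @param path file path.
#' @return named list of [genotype()] objects, one per sample.
#' @export
read_genotype_table <- function(path) {
  tab <- .read_delim_auto(path)
  need <- c("sample", "locus", "allele1", "allele2")
  if (!all(need %in% names(tab)))
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$sample), function(d) {
    g <- lapply(seq_len(nrow(d)), function(i) c(d$allele1[i], d$allele2[i]))
    names(g) <- d$locus
    genotype(g)
  })
}

#' Write reference genotypes as tab-separated text
#'
#' @param genotypes named list of [genotype()] objects (one per sample).
#' @param path output path.
#' @export
write_genotype_table <- function(genotypes, path) {
  rows <- do.call(rbind, lapply(names(genotypes), function(s) {
    g <- genotypes[[s]]
    data.frame(sample = s, locus = names(g),
               allele1 = vapply(g, `[`, "", 1L),
               allele2 = vapply(g, `[`, "", 2L))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Replicate profiles

#' Single-amplification peak profile
#'
#' One PCR replicate's peak list: per locus a data frame with columns
#' `allele` (designation), `height` (RFU, integer) and `size` (bp). Peaks are
#' expected to already sit at or above the analytical threshold.
#'
#' @param sample_id,kit_id,replicate_id identifiers.
#' @param peaks named list of per-locus data frames (`allele`, `height`,
#'   `size`); loci without peaks may be omitted.
#' @param loci full locus list of the originating kit (so that loci with no
#'   surviving peaks remain known downstream); defaults to `names(peaks)`.
#' @return object of class `replicate_profile`.
#' @export
replicate_profile <- function(sample_id, kit_id, replicate_id, peaks,
                              loci = names(peaks)) {
  for (l in names(peaks)) {
    pk <- peaks[[l]]
    if (!all(c("allele", "height", "size") %in% names(pk)))
      stop("peak frames need columns allele, height, size (locus ", l, ")")
    pk$allele <- format_allele(pk$allele)
    if (anyDuplicated(pk$allele))
      stop("duplicate allele within locus ", l)
    pk <- pk[allele_order(pk$allele), , drop = FALSE]
    rownames(pk) <- NULL
    peaks[[l]] <- pk
  }
  structure(list(sample_id = sample_id, kit_id = kit_id,
                 replicate_id = replicate_id, peaks = peaks,
                 loci = as.character(loci)),
            class = "replicate_profile")
}

#' @export
print.replicate_profile <- function(x, ...) {
  cat("Replicate profile ", x$sample_id, " / kit ", x$kit_id, " / rep ",
      x$replicate_id, ": ", sum(vapply(x$peaks, nrow, 0L)), " peaks over ",
      length(x$peaks), " loci\n", sep = "")
  invisible(x)
}

#' Read an electropherogram peak table
#'
#' Reads a GeneMapper-export-like delimited table with columns `sample`,
#' `replicate`, `locus`, `allele`, `height` and (optionally blank) `size`.
#' Peaks below the kit's analytical threshold are dropped and counted
#' (attribute `n_below_threshold`); missing sizes are filled from the kit's
#' size map. A peak whose height equals the threshold is retained.
#'
#' @param path file path (comma- or tab-separated, autodetected).
#' @param kit the [kit_panel()] the table was produced with.
#' @return list of [replicate_profile()] objects, one per (sample, replicate),
#'   with attribute `n_below_threshold`.
#' @export
read_peak_table <- function(path, kit) {
  tab <- .read_delim_auto(path)
  need <- c("sample", "replicate", "locus", "allele", "height")
  if (!all(need %in% names(tab)))
    stop("peak table needs columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(tab$locus), kit$loci)
  if (length(unknown))
    stop("unknown locus for kit ", kit$kit_id, ": ",
         paste(unknown, collapse = ", "))
  tab$height <- as.numeric(tab$height)
  if (!"size" %in% names(tab)) tab$size <- NA_real_ else
    tab$size <- suppressWarnings(as.numeric(tab$size))
  fill <- is.na(tab$size)
  if (any(fill))
    tab$size[fill] <- mapply(function(l, a) allele_size(kit, l, a),
                             tab$locus[fill], tab$allele[fill])
  below <- tab$height < kit$analytical_threshold
  n_below <- sum(below)
  tab <- tab[!below, , drop = FALSE]
  key <- interaction(tab$sample, tab$replicate, drop = TRUE)
  out <- lapply(split(tab, key), function(d) {
    peaks <- lapply(split(d, d$locus), function(x)
      data.frame(allele = x$allele, height = round(x$height),
                 size = x$size))
    replicate_profile(d$sample[1], kit$kit_id, d$replicate[1], peaks,
                      loci = kit$loci)
  })
  names(out) <- NULL
  structure(out, n_below_threshold = n_below)
}

#' Write replicate profiles as a tab-separated peak table
#'
#' Inverse of [read_peak_table()]: writing then re-reading reproduces the
#' peak lists exactly.
#'
#' @param profiles list of [replicate_profile()] objects.
#' @param path output path.
#' @export
write_peak_table <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(pr) {
    do.call(rbind, lapply(names(pr$peaks), function(l) {
      pk <- pr$peaks[[l]]
      if (!nrow(pk)) return(NULL)
      data.frame(sample = pr$sample_id, replicate = pr$replicate_id,
                 locus = l, allele = pk$allele, height = pk$height,
                 size = pk$size)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled demonstration allele frequencies
#'
#' A deterministic synthetic frequency table for the 16 demo loci: 6-10
#' alleles per locus with unimodal frequency profiles and one microvariant
#' (TH01 9.3), loosely shaped like European autosomal STR tables but not
#' sourced from any population study.
#'
#' @return an [allele_frequencies()] object with `n_observed = 1000`.
#' @export
demo_frequencies <- function() {
  loci <- demo_kits()$ESI$loci
  freqs <- lapply(seq_along(loci), function(i) {
    k <- c(8, 9, 7, 10, 8, 9, 8, 7, 6, 10, 7, 8, 8, 9, 10, 9)[i]
    start <- c(12, 13, 8, 16, 8, 24, 10, 11, 6, 18, 11, 9, 11, 11, 15, 12)[i]
    al <- start + seq_len(k) - 1
    w <- stats::dnorm(seq_len(k), mean = (k + 1) / 2 + 0.3 * ((i %% 3) - 1),
                      sd = k / 4)
    stats::setNames(w / sum(w), format_allele(al))
  })
  names(freqs) <- loci
  # one microvariant for designation plumbing
  th01 <- freqs[["TH01"]]
  names(th01)[length(th01)] <- "9.3"
  freqs[["TH01"]] <- th01
  allele_frequencies(freqs, n_observed = 1000)
}

#' Write a kit panel as JSON or YAML
#'
#' @param kit a [kit_panel()].
#' @param path output path; a `.yaml`/`.yml` extension selects YAML (needs
#'   the yaml package), anything else JSON.
#' @export
write_kit_panel <- function(kit, path) {
  x <- list(kit_id = kit$kit_id, loci = kit$loci,
            analytical_threshold = kit$analytical_threshold,
            size_map = lapply(kit$size_map, as.list))
  if (grepl("[.]ya?ml$", path)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a kit panel from JSON or YAML
#'
#' @param path file written by [write_kit_panel()].
#' @return a [kit_panel()].
#' @export
read_kit_panel <- function(path) {
  x <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  size_map <- lapply(x$size_map, function(sm)
    c(intercept = as.numeric(sm$intercept),
      repeat_bp = as.numeric(sm$repeat_bp)))
  kit_panel(x$kit_id, unlist(x$loci), size_map,
            analytical_threshold = x$analytical_threshold)
}
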