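## Classification of non-reference alleles relative to a reference genome
## and a population map:
##   private — observed (>= 1 copy) in exactly one sub-population
##   common  — observed in two or more sub-populations
## Diagnostic sub-classes of private alleles (variety markers):
##   fixed_homozygous — every called member of the carrier population is
##                      homozygous for the allele
##   all_heterozygous — every called member is a heterozygous carrier

.allele_counts_by_pop <- function(gm, site, member_idx) {
  lapply(member_idx, function(ix) {
    x1 <- gm$a1[site, ix]; x2 <- gm$a2[site, ix]
    called <- !is.na(x1)
    table(c(x1[called], x2[called]))
  })
}

.member_index <- function(gm, pmap) {
  pops <- pop_names(pmap)
  out <- lapply(pops, function(p) {
    i <- match(pop_members(pmap, p), gm$individuals)
    i[!is.na(i)]
  })
  names(out) <- pops
  out
}

#' Classify every observed non-reference allele as private or common
#'
#' For every SNP site and every non-reference allele with at least one
#' observed copy among the mapped individuals, records the set of carrier
#' sub-populations and classifies the allele as `private` (exactly one
#' carrier population) or `common` (two or more). Classification is by
#' allele presence, not frequency. `locus_universality` is the fraction of
#' all mapped individuals in which the allele's RAD locus was sequenced
#' (locus-level missingness).
#'
#' @param gm A [genotype_matrix()].
#' @param pmap A [population_map()].
#' @return Data frame of class `allele_calls`, one row per (site, allele):
#'   `site`, `locus_id`, `chrom`, `position_bp`, `column`, `ref`, `allele`,
#'   `n_copies`, `category`, `carrier_populations` (comma-separated),
#'   `n_carrier_pops`, `locus_universality`.
#' @export
classify_alleles <- function(gm, pmap) {
  if (any(is.na(gm$sites$ref) | gm$sites$ref == "")) {
    stop("every site must carry a reference-allele designation")
  }
  member_idx <- .member_index(gm, pmap)
  all_idx <- sort(unique(unlist(member_idx)))
  pres <- locus_presence(gm)[, all_idx, drop = FALSE]
  univ <- rowMeans(pres)
  names(univ) <- rownames(pres)

  out <- list()
  k <- 0L
  for (i in seq_len(n_sites(gm))) {
    counts <- .allele_counts_by_pop(gm, i, member_idx)
    ref <- gm$sites$ref[i]
    alts <- setdiff(unique(unlist(lapply(counts, names))), ref)
    for (al in alts) {
      copies <- vapply(counts, function(ct)
        if (al %in% names(ct)) as.integer(ct[[al]]) else 0L, integer(1))
      if (sum(copies) == 0) next
      carriers <- names(copies)[copies > 0]
      k <- k + 1L
      out[[k]] <- data.frame(
        site = i, locus_id = gm$sites$locus_id[i],
        chrom = gm$sites$chrom[i], position_bp = gm$sites$position_bp[i],
        column = gm$sites$column[i], ref = ref, allele = al,
        n_copies = sum(copies),
        category = if (length(carriers) == 1) "private" else "common",
        carrier_populations = paste(carriers, collapse = ","),
        n_carrier_pops = length(carriers),
        locus_universality = unname(univ[as.character(gm$sites$locus_id[i])]),
        stringsAsFactors = FALSE)
    }
  }
  calls <- if (k > 0) do.call(rbind, out) else
    data.frame(site = integer(), locus_id = integer(), chrom = character(),
               position_bp = integer(), column = integer(), ref = character(),
               allele = character(), n_copies = integer(),
               category = character(), carrier_populations = character(),
               n_carrier_pops = integer(), locus_universality = numeric(),
               stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls, class = c("allele_calls", "data.frame"))
}

#' Keep private alleles uniform within their carrier population
#'
#' The diagnostic-marker filter: a private allele is retained only when its
#' carrier population is uniform at the site — either every called member
#' is homozygous for the non-reference allele (`fixed_homozygous`, the
#' allele may be fixed in the variety) or every called member is a
#' heterozygous carrier (`all_heterozygous`, diagnostic but not yet fixed).
#' Uniformity is evaluated over called members only; individuals missing
#' the locus are ignored.
#'
#' @param calls Output of [classify_alleles()].
#' @param gm The `genotype_matrix` the calls were derived from.
#' @param pmap The matching `population_map`.
#' @return Subset of `calls` (private alleles passing the filter) with an
#'   added `diagnostic_class` column.
#' @export
diagnostic_filter <- function(calls, gm, pmap) {
  priv <- calls[calls$category == "private", , drop = FALSE]
  if (nrow(priv) == 0) {
    priv$diagnostic_class <- character(0)
    return(priv)
  }
  member_idx <- .member_index(gm, pmap)
  cls <- character(nrow(priv))
  for (r in seq_len(nrow(priv))) {
    i <- priv$site[r]
    al <- priv$allele[r]
    ix <- member_idx[[priv$carrier_populations[r]]]
    x1 <- gm$a1[i, ix]; x2 <- gm$a2[i, ix]
    called <- !is.na(x1)
    x1 <- x1[called]; x2 <- x2[called]
    hom_alt <- x1 == al & x2 == al
    het_carrier <- xor(x1 == al, x2 == al)
    cls[r] <- if (all(hom_alt)) "fixed_homozygous"
      else if (all(het_carrier)) "all_heterozygous"
      else "none"
  }
  priv$diagnostic_class <- cls
  priv <- priv[priv$diagnostic_class != "none", , drop = FALSE]
  rownames(priv) <- NULL
  priv
}

#' Filter allele calls by locus universality
#'
#' Keeps alleles whose RAD locus was sequenced in at least `min_fraction`
#' of all mapped individuals. With the default `min_fraction = 1` only
#' loci present in every individual survive — the condition for an ideal
#' diagnostic marker locus.
#'
#' @param calls Output of [classify_alleles()] (or a filtered subset).
#' @param min_fraction Minimum fraction of individuals with the locus,
#'   in (0, 1].
#' @return Filtered subset of `calls`.
#' @export
universal_locus_filter <- function(calls, min_fraction = 1.0) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("min_fraction must be in (0, 1]")
  }
  out <- calls[calls$locus_universality >= min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count private alleles per population
#'
#' @param calls Output of [classify_alleles()].
#' @param pmap The matching `population_map`.
#' @return Named integer vector (one entry per population, zero when none).
#' @export
count_private <- function(calls, pmap) {
  pops <- pop_names(pmap)
  priv <- calls[calls$category == "private", , drop = FALSE]
  counts <- table(factor(priv$carrier_populations, levels = pops))
  stats::setNames(as.integer(counts), pops)
}

#' Scan a two-group contrast for group-specific alleles
#'
#' For a phenotype-contrast map with exactly two populations (for example
#' disease-resistant versus susceptible accessions), finds non-reference
#' alleles present in one group and absent (zero copies) in the other, and
#' retains those exceeding a frequency threshold in the carrying group.
#'
#' Three criteria are available for the threshold:
#' * `"alt-frequency"` (default): the allele's frequency among the called
#'   alleles of the focal group must exceed `threshold` (strictly, by
#'   default) — the ">50% alternative allele frequency" selection rule;
#' * `"carrier-nominal"`: the fraction of the nominal group size carrying
#'   at least one copy must reach `threshold` (inclusive by default);
#' * `"carrier-called"`: as above but over genotyped members only.
#'
#' @param gm A `genotype_matrix`.
#' @param pmap A `population_map` with exactly two populations.
#' @param threshold Frequency/fraction threshold (default 0.5).
#' @param criterion See Details.
#' @param inclusive Use `>=` instead of `>`; `NULL` (default) selects the
#'   criterion's convention (strict for `"alt-frequency"`, inclusive for
#'   the carrier criteria).
#' @return Data frame of class `group_contrast`, one row per hit: `site`,
#'   `locus_id`, `chrom`, `position_bp`, `column`, `ref`, `allele`,
#'   `focal_group`, `n_called`, `alt_freq`, `carrier_count`,
#'   `carrier_fraction` (over the nominal group size),
#'   `homozygote_fraction` (among carriers), `absent_in_other`.
#' @export
group_contrast <- function(gm, pmap, threshold = 0.5,
                           criterion = c("alt-frequency", "carrier-nominal",
                                         "carrier-called"),
                           inclusive = NULL) {
  criterion <- match.arg(criterion)
  pops <- pop_names(pmap)
  if (length(pops) != 2) {
    stop("group_contrast requires exactly two populations; ",
         "use classify_alleles() for multi-population maps")
  }
  if (is.null(inclusive)) inclusive <- criterion != "alt-frequency"
  member_idx <- .member_index(gm, pmap)
  nominal <- vapply(pops, function(p) length(pop_members(pmap, p)), integer(1))

  out <- list(); k <- 0L
  for (i in seq_len(n_sites(gm))) {
    counts <- .allele_counts_by_pop(gm, i, member_idx)
    ref <- gm$sites$ref[i]
    alts <- setdiff(unique(unlist(lapply(counts, names))), ref)
    for (al in alts) {
      copies <- vapply(counts, function(ct)
        if (al %in% names(ct)) as.integer(ct[[al]]) else 0L, integer(1))
      carrier_groups <- which(copies > 0)
      if (length(carrier_groups) != 1) next  # absent, or present in both
      focal <- pops[carrier_groups]
      ix <- member_idx[[focal]]
      x1 <- gm$a1[i, ix]; x2 <- gm$a2[i, ix]
      called <- !is.na(x1)
      n_called <- sum(called)
      alt_freq <- copies[carrier_groups] / (2 * n_called)
      is_carrier <- called & (x1 == al | x2 == al)
      carrier_count <- sum(is_carrier, na.rm = TRUE)
      hom_frac <- sum(x1 == al & x2 == al, na.rm = TRUE) / carrier_count
      value <- switch(criterion,
                      "alt-frequency" = alt_freq,
                      "carrier-nominal" = carrier_count / nominal[[focal]],
                      "carrier-called" = carrier_count / n_called)
      pass <- if (inclusive) value >= threshold else value > threshold
      if (!pass) next
      k <- k + 1L
      out[[k]] <- data.frame(
        site = i, locus_id = gm$sites$locus_id[i],
        chrom = gm$sites$chrom[i], position_bp = gm$sites$position_bp[i],
        column = gm$sites$column[i], ref = ref, allele = al,
        focal_group = focal, n_called = n_called,
        alt_freq = unname(alt_freq), carrier_count = carrier_count,
        carrier_fraction = carrier_count / nominal[[focal]],
        homozygote_fraction = hom_frac,
        absent_in_other = TRUE, stringsAsFactors = FALSE)
    }
  }
  hits <- if (k > 0) do.call(rbind, out) else
    data.frame(site = integer(), locus_id = integer(), chrom = character(),
               position_bp = integer(), column = integer(), ref = character(),
               allele = character(), focal_group = character(),
               n_called = integer(), alt_freq = numeric(),
               carrier_count = integer(), carrier_fraction = numeric(),
               homozygote_fraction = numeric(), absent_in_other = logical(),
               stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  structure(hits, class = c("group_contrast", "data.frame"),
            criterion = criterion, threshold = threshold,
            inclusive = inclusive)
}
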