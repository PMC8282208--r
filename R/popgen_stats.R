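## Per-site, per-population summary statistics.
##
## With n = 2N alleles called in a population at a site and p_i the sample
## allele frequencies:
##   H_exp = 1 - sum(p_i^2)
##   pi    = H_exp * n/(n-1)        (unbiased, average pairwise difference)
##   H_obs = heterozygous individuals / N
##   F_IS  = (pi - H_obs)/pi, defined as 0 when pi = 0

.site_pop_stats <- function(x1, x2, ref) {
  called <- !is.na(x1)
  n_ind <- sum(called)
  if (n_ind == 0) return(NULL)
  x1 <- x1[called]; x2 <- x2[called]
  alleles <- c(x1, x2)
  n <- 2L * n_ind
  counts <- table(alleles)
  nuc <- sort(names(counts))
  p <- as.numeric(counts[nuc]) / n
  h_exp <- 1 - sum(p^2)
  pi <- if (n > 1) h_exp * n / (n - 1) else 0
  h_obs <- sum(x1 != x2) / n_ind
  f_is <- if (pi > 0) (pi - h_obs) / pi else 0
  # major allele: largest frequency, alphabetical tie-break
  major <- nuc[which.max(p)]
  p_major <- max(p)
  p_ref <- if (ref %in% nuc) p[match(ref, nuc)] else 0
  alt_obs <- setdiff(nuc, ref)
  # P/Q nucleotide labels as printed in catalog reports: P Nuc is the
  # reference allele when observed in the population ("-" otherwise);
  # Q Nuc the most frequent observed non-reference allele
  p_nuc <- if (ref %in% nuc) ref else "-"
  q_nuc <- if (length(alt_obs) > 0) {
    alt_obs[which.max(p[match(alt_obs, nuc)])]
  } else "-"
  list(n_ind = n_ind, p_nuc = p_nuc, q_nuc = q_nuc,
       major_nuc = major, p_major = p_major, p_ref = p_ref,
       h_obs = h_obs, hom_obs = 1 - h_obs,
       h_exp = h_exp, hom_exp = 1 - h_exp,
       pi = pi, f_is = f_is)
}

#' Per-site statistics within one population
#'
#' Computes, for one SNP site and one population, the sample size N
#' (individuals with a call), major-allele and reference-allele frequencies,
#' observed and expected heterozygosity/homozygosity, sample-size-corrected
#' nucleotide diversity pi = H_exp * n/(n-1) (n = 2N alleles), and the
#' per-site inbreeding coefficient F_IS = (pi - H_obs)/pi (0 when pi = 0).
#'
#' The multi-allele formulas are used throughout, so multi-allelic sites
#' need no special casing.
#'
#' @param gm A [genotype_matrix()].
#' @param site Site index (row of `gm$sites`).
#' @param pop Population name.
#' @param pmap A [population_map()].
#' @return One-row data frame with columns `site`, `locus_id`, `chrom`,
#'   `position_bp`, `column`, `population`, `n_ind`, `p_nuc`, `q_nuc`,
#'   `major_nuc`, `p_major`, `p_ref`, `h_obs`, `hom_obs`, `h_exp`,
#'   `hom_exp`, `pi`, `f_is`. `p_ref` (frequency of the reference
#'   nucleotide) is the "P" column of catalog-style reports; `p_major`
#'   the largest within-population frequency.
#' @export
site_stats <- function(gm, site, pop, pmap) {
  if (!pop %in% pop_names(pmap)) stop("unknown population: ", pop)
  members <- match(pop_members(pmap, pop), gm$individuals)
  members <- members[!is.na(members)]
  st <- .site_pop_stats(gm$a1[site, members], gm$a2[site, members],
                        gm$sites$ref[site])
  if (is.null(st)) {
    stop("site ", site, " absent in population ", pop,
         ": no called individuals")
  }
  cbind(data.frame(site = site,
                   locus_id = gm$sites$locus_id[site],
                   chrom = gm$sites$chrom[site],
                   position_bp = gm$sites$position_bp[site],
                   column = gm$sites$column[site],
                   population = pop,
                   stringsAsFactors = FALSE),
        as.data.frame(st, stringsAsFactors = FALSE))
}

#' Per-site statistics for every site and population
#'
#' Long-format table of [site_stats()] over all (site, population)
#' combinations with at least one called individual.
#'
#' @param gm A `genotype_matrix`.
#' @param pmap A `population_map`.
#' @param site_set `"variant"` restricts to sites polymorphic across the
#'   metapopulation (at least two alleles observed among all mapped,
#'   called individuals); `"all"` keeps every site.
#' @return Data frame, one row per (site, population).
#' @export
site_stats_all <- function(gm, pmap, site_set = c("variant", "all")) {
  site_set <- match.arg(site_set)
  pops <- pop_names(pmap)
  member_idx <- lapply(pops, function(p) {
    i <- match(pop_members(pmap, p), gm$individuals)
    i[!is.na(i)]
  })
  names(member_idx) <- pops
  all_idx <- sort(unique(unlist(member_idx)))
  keep <- seq_len(n_sites(gm))
  if (site_set == "variant") {
    poly <- vapply(keep, function(i) {
      obs <- c(gm$a1[i, all_idx], gm$a2[i, all_idx])
      length(unique(obs[!is.na(obs)])) >= 2
    }, logical(1))
    keep <- keep[poly]
  }
  if (length(keep) == 0) stop("empty site set")
  cap <- length(keep) * length(pops)
  site_v <- integer(cap); pop_v <- character(cap)
  num_cols <- c("n_ind", "p_major", "p_ref", "h_obs", "hom_obs",
                "h_exp", "hom_exp", "pi", "f_is")
  chr_cols <- c("p_nuc", "q_nuc", "major_nuc")
  num_acc <- lapply(num_cols, function(.) numeric(cap))
  names(num_acc) <- num_cols
  chr_acc <- lapply(chr_cols, function(.) character(cap))
  names(chr_acc) <- chr_cols
  k <- 0L
  for (i in keep) {
    ref <- gm$sites$ref[i]
    for (p in pops) {
      st <- .site_pop_stats(gm$a1[i, member_idx[[p]]],
                            gm$a2[i, member_idx[[p]]], ref)
      if (is.null(st)) next
      k <- k + 1L
      site_v[k] <- i
      pop_v[k] <- p
      for (cc in num_cols) num_acc[[cc]][k] <- st[[cc]]
      for (cc in chr_cols) chr_acc[[cc]][k] <- st[[cc]]
    }
  }
  idx <- seq_len(k)
  out <- data.frame(site = site_v[idx],
                    locus_id = gm$sites$locus_id[site_v[idx]],
                    chrom = gm$sites$chrom[site_v[idx]],
                    position_bp = gm$sites$position_bp[site_v[idx]],
                    column = gm$sites$column[site_v[idx]],
                    population = pop_v[idx],
                    stringsAsFactors = FALSE)
  for (cc in chr_cols) out[[cc]] <- chr_acc[[cc]][idx]
  for (cc in num_cols) out[[cc]] <- num_acc[[cc]][idx]
  out$n_ind <- as.integer(out$n_ind)
  out
}

#' Chi-square test for deviation from expected heterozygosity
#'
#' Tests whether a population's mean observed heterozygosity/homozygosity
#' deviates from the expectation under Hardy-Weinberg proportions, using
#' the statistic
#' `chi2 = N * ((H_obs - H_exp)^2 / H_exp + (Hom_obs - Hom_exp)^2 / Hom_exp)`
#' referred to the chi-square distribution with 1 degree of freedom. The
#' p-value is additionally reported as one of the buckets `">0.9"`,
#' `">0.5"`, `"<=0.5"`.
#'
#' When the expected heterozygosity is degenerate (0 or 1) the statistic is
#' undefined; 0 is returned with `degenerate = TRUE` and a warning.
#'
#' @param n_ind Number of individuals N.
#' @param h_obs,h_exp Mean observed and expected heterozygosity.
#' @param hom_obs,hom_exp Mean observed and expected homozygosity
#'   (defaults: complements of the heterozygosities).
#' @return List with `chi2`, `p_value`, `p_bucket`, `degenerate`.
#' @export
chi2_het_deviation <- function(n_ind, h_obs, h_exp,
                               hom_obs = 1 - h_obs, hom_exp = 1 - h_exp) {
  if (h_exp <= 0 || h_exp >= 1 || hom_exp <= 0) {
    warning("expected heterozygosity is degenerate; chi2 undefined, returning 0")
    return(list(chi2 = 0, p_value = 1, p_bucket = ">0.9", degenerate = TRUE))
  }
  chi2 <- n_ind * ((h_obs - h_exp)^2 / h_exp + (hom_obs - hom_exp)^2 / hom_exp)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  bucket <- if (p > 0.9) ">0.9" else if (p > 0.5) ">0.5" else "<=0.5"
  list(chi2 = chi2, p_value = p, p_bucket = bucket, degenerate = FALSE)
}

#' Population-level summary statistics
#'
#' Means of the per-site statistics over the chosen site set for each
#' population, the number of private alleles, and the chi-square test for
#' heterozygosity deviation — one row per population, in the layout of a
#' population-genetics summary table.
#'
#' @param gm A `genotype_matrix`.
#' @param pmap A `population_map`.
#' @param site_set Passed to [site_stats_all()]; `"variant"` (default)
#'   averages over metapopulation-polymorphic sites only.
#' @return Data frame of class `pop_summary` with columns `population`,
#'   `n_private`, `n_ind` (nominal population size), `p` (mean
#'   major-allele frequency), `obs_het`, `obs_hom`, `exp_het`, `exp_hom`,
#'   `pi`, `f_is`, `chi2`, `p_value`, `p_bucket`.
#' @export
population_summary <- function(gm, pmap, site_set = c("variant", "all")) {
  site_set <- match.arg(site_set)
  pops <- pop_names(pmap)
  if (any(!pops %in% pmap$population)) stop("empty population in map")
  ss <- site_stats_all(gm, pmap, site_set = site_set)
  priv <- count_private(classify_alleles(gm, pmap), pmap)
  rows <- lapply(pops, function(p) {
    d <- ss[ss$population == p, , drop = FALSE]
    if (nrow(d) == 0) stop("population ", p, " has no called sites")
    ct <- chi2_het_deviation(length(pop_members(pmap, p)),
                             mean(d$h_obs), mean(d$h_exp),
                             mean(d$hom_obs), mean(d$hom_exp))
    data.frame(population = p,
               n_private = priv[[p]],
               n_ind = length(pop_members(pmap, p)),
               p = mean(d$p_major),
               obs_het = mean(d$h_obs), obs_hom = mean(d$hom_obs),
               exp_het = mean(d$h_exp), exp_hom = mean(d$hom_exp),
               pi = mean(d$pi), f_is = mean(d$f_is),
               chi2 = ct$chi2, p_value = ct$p_value,
               p_bucket = ct$p_bucket,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("pop_summary", "data.frame"), site_set = site_set)
}
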