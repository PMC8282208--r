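## Pairwise FST between sub-populations, as a ratio of sums of per-site
## variance components (the standard multi-locus combination that keeps the
## estimator nearly unbiased at low per-site information).

# Weir & Cockerham (1984) variance components for one allele at one site in
# two populations; n1, n2 individuals, p1, p2 allele frequencies, h1, h2
# frequencies of individuals heterozygous for the allele.
.wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  n_bar <- (n1 + n2) / 2
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  if (n_bar <= 1) return(c(a = 0, b = 0, c = 0))
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - s2 * (r - 1) / r - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - s2 * (r - 1) / r -
       h_bar * (2 * n_bar - 1) / (4 * n_bar))
  c_ <- h_bar / 2
  c(a = a, b = b, c = c_)
}

# Hudson estimator (Bhatia et al. 2013 form) numerator/denominator for a
# biallelic site; sample sizes in allele counts m1 = 2*n1, m2 = 2*n2.
.hudson_components <- function(m1, m2, p1, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  c(num = num, den = den)
}

#' Pairwise FST matrix between sub-populations
#'
#' Multi-site FST for every pair of populations, combining per-site
#' variance components as a ratio of sums. Two estimators are available:
#' Weir-Cockerham (default; per-allele components summed over alleles, so
#' multi-allelic sites are handled) and Hudson (biallelic sites only; sites
#' with more than two alleles observed in the pair are skipped for that
#' pair).
#'
#' Sites where either population of a pair has fewer than `min_called`
#' genotyped individuals are excluded from that pair. A pair with no usable
#' site yields `NA` (flagged missing), never 0.
#'
#' @param gm A [genotype_matrix()].
#' @param pmap A [population_map()] with at least two populations.
#' @param estimator `"weir-cockerham"` or `"hudson"`.
#' @param min_called Minimum called individuals per population per site
#'   (default 2).
#' @return Object of class `fst_matrix`: list with `populations`, `values`
#'   (symmetric matrix, diagonal 0), `n_sites` (sites used per pair) and
#'   `estimator`.
#' @export
pairwise_fst <- function(gm, pmap,
                         estimator = c("weir-cockerham", "hudson"),
                         min_called = 2L) {
  estimator <- match.arg(estimator)
  pops <- pop_names(pmap)
  if (length(pops) < 2) stop("need at least two populations")
  member_idx <- .member_index(gm, pmap)
  np <- length(pops)
  values <- matrix(NA_real_, np, np, dimnames = list(pops, pops))
  diag(values) <- 0
  n_used <- matrix(0L, np, np, dimnames = list(pops, pops))

  # per-site per-pop allele summaries, computed once
  S <- n_sites(gm)
  summaries <- vector("list", np)
  for (pi_ in seq_len(np)) {
    ix <- member_idx[[pi_]]
    summaries[[pi_]] <- lapply(seq_len(S), function(i) {
      x1 <- gm$a1[i, ix]; x2 <- gm$a2[i, ix]
      called <- !is.na(x1)
      x1 <- x1[called]; x2 <- x2[called]
      n <- length(x1)
      if (n == 0) return(NULL)
      counts <- table(c(x1, x2))
      list(n = n, counts = counts, x1 = x1, x2 = x2)
    })
  }

  for (i1 in seq_len(np - 1)) {
    for (i2 in (i1 + 1):np) {
      num <- 0; den <- 0; used <- 0L
      for (s in seq_len(S)) {
        s1 <- summaries[[i1]][[s]]; s2 <- summaries[[i2]][[s]]
        if (is.null(s1) || is.null(s2)) next
        if (s1$n < min_called || s2$n < min_called) next
        alleles <- union(names(s1$counts), names(s2$counts))
        if (length(alleles) < 2) next  # monomorphic in the pair
        if (estimator == "weir-cockerham") {
          for (al in alleles) {
            p1 <- if (al %in% names(s1$counts)) s1$counts[[al]] / (2 * s1$n) else 0
            p2 <- if (al %in% names(s2$counts)) s2$counts[[al]] / (2 * s2$n) else 0
            h1 <- sum(xor(s1$x1 == al, s1$x2 == al)) / s1$n
            h2 <- sum(xor(s2$x1 == al, s2$x2 == al)) / s2$n
            comp <- .wc_components(s1$n, s2$n, p1, p2, h1, h2)
            num <- num + comp[["a"]]
            den <- den + comp[["a"]] + comp[["b"]] + comp[["c"]]
          }
          used <- used + 1L
        } else {
          if (length(alleles) != 2) next
          al <- alleles[1]
          p1 <- if (al %in% names(s1$counts)) s1$counts[[al]] / (2 * s1$n) else 0
          p2 <- if (al %in% names(s2$counts)) s2$counts[[al]] / (2 * s2$n) else 0
          comp <- .hudson_components(2 * s1$n, 2 * s2$n, p1, p2)
          num <- num + comp[["num"]]
          den <- den + comp[["den"]]
          used <- used + 1L
        }
      }
      fst <- if (used > 0 && den != 0) num / den else NA_real_
      values[i1, i2] <- values[i2, i1] <- fst
      n_used[i1, i2] <- n_used[i2, i1] <- used
    }
  }
  structure(list(populations = pops, values = values, n_sites = n_used,
                 estimator = estimator),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("pairwise FST (", x$estimator, ")\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Allele-sharing distance between individuals
#'
#' Simple concatenated-SNP distance for external tree building: one minus
#' the mean fraction of shared alleles per site (1, 0.5 or 0 shared for
#' identical, half-matching and disjoint diploid genotypes), averaged over
#' sites called in both individuals.
#'
#' @param gm A `genotype_matrix`.
#' @return A `dist` object over individuals.
#' @export
allele_sharing_dist <- function(gm) {
  n <- n_individuals(gm)
  d <- matrix(0, n, n, dimnames = list(gm$individuals, gm$individuals))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(gm$a1[, i]) & !is.na(gm$a1[, j])
      if (!any(both)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      a1i <- gm$a1[both, i]; a2i <- gm$a2[both, i]
      a1j <- gm$a1[both, j]; a2j <- gm$a2[both, j]
      # identity-by-state: best of the two pairings of the diploid alleles
      share <- pmax((a1i == a1j) + (a2i == a2j),
                    (a1i == a2j) + (a2i == a1j))
      d[i, j] <- d[j, i] <- 1 - mean(share / 2)
    }
  }
  stats::as.dist(d)
}
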