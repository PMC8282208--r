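## Synthetic ddRAD-style genotype catalogs with known truth, for validating
## every stage of the analysis without sequencing data.
##
## The generative model, per SNP site and population: an alternative-allele
## frequency q is drawn from a Beta prior (or fixed); with a per-population
## inbreeding coefficient F the genotype probabilities are
##   P(ref/ref) = p^2 + F p q,  P(ref/alt) = 2 p q (1 - F),
##   P(alt/alt) = q^2 + F p q,
## with negative F truncated to max(F, -p/q, -q/p) so all three are
## probabilities. Between-population divergence follows the Balding-Nichols
## model: per-population frequencies drawn around the ancestral frequency
## with Beta variance parameter `divergence` (the expected FST). Allele
## dropout is applied per (locus, individual) — a dropped locus loses all
## of its SNPs in that individual.

#' Simulation configuration
#'
#' The default configuration is "study-shaped": nine varietal
#' sub-populations with the study sample sizes (2-8 individuals, 32 in
#' total), 150 bp loci carrying 0-10 SNPs (mean 2), alternative-allele
#' frequencies from a Beta(0.8, 3.2) prior (mean 0.2, matching the
#' observed mean minor-allele frequency of about 0.2 at variant sites),
#' and a small positive inbreeding coefficient.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param populations Named integer vector of population sizes.
#' @param n_loci Number of RAD loci.
#' @param snp_lambda,snp_max SNPs per locus: `min(rpois(snp_lambda), snp_max)`.
#' @param alt_freq_prior Either a length-2 vector of Beta shape parameters
#'   for the ancestral alternative-allele frequency, or a single fixed
#'   frequency in `[0, 1]` (0 gives a monomorphic-reference background,
#'   useful for exact truth-table tests).
#' @param f_is Inbreeding coefficient in `[-0.5, 1]`; scalar or named per
#'   population.
#' @param divergence Balding-Nichols between-population divergence
#'   (expected FST) in `[0, 1)`; 0 means all populations share the
#'   ancestral frequency.
#' @param n_private Number of private alleles to plant per population;
#'   scalar or named per population. Planted alleles sit on dedicated loci
#'   whose planted site is monomorphic-reference in every other population.
#' @param private_profile `"fixed_homozygous"` (all carrier-population
#'   members homozygous alternative), `"all_heterozygous"` (all members
#'   heterozygous) or `"mixed"` (random mixture with at least one carrier).
#' @param locus_dropout_rate Per-(locus, individual) probability of allele
#'   dropout, in `[0, 1)`.
#' @param chromosomes Data frame with `chrom`, `length_bp` for coordinate
#'   assignment; defaults to the 'Tombul' pseudochromosome layout.
#' @param locus_len Locus length in bp (150 for ddRAD tags).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       populations = c("Allahverdi" = 2, "Çakıldak" = 3,
                                       "Karafındık" = 2, "Mincane" = 2,
                                       "Palaz" = 5, "Sarıfındık" = 5,
                                       "Sivri" = 4, "Tombul" = 8, "Yomra" = 2),
                       n_loci = 500L,
                       snp_lambda = 2, snp_max = 10L,
                       alt_freq_prior = c(0.8, 3.2),
                       f_is = 0.02,
                       divergence = 0,
                       n_private = 0L,
                       private_profile = c("fixed_homozygous",
                                           "all_heterozygous", "mixed"),
                       locus_dropout_rate = 0,
                       chromosomes = NULL,
                       locus_len = 150L) {
  private_profile <- match.arg(private_profile)
  if (is.null(names(populations)) || any(populations < 1)) {
    stop("populations must be a named vector of sizes >= 1")
  }
  pops <- names(populations)
  expand <- function(x, what, lo, hi) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(pops)), pops)
    }
    if (!all(pops %in% names(x))) stop(what, " must name every population")
    x <- x[pops]
    if (any(x < lo) || any(x > hi)) {
      stop(what, " must lie in [", lo, ", ", hi, "]")
    }
    x
  }
  f_is <- expand(f_is, "f_is", -0.5, 1)
  n_private <- expand(n_private, "n_private", 0, Inf)
  n_private <- stats::setNames(as.integer(n_private), pops)
  if (!(length(alt_freq_prior) %in% c(1, 2)) || any(alt_freq_prior < 0)) {
    stop("alt_freq_prior must be Beta shapes (length 2, positive) or one fixed frequency")
  }
  if (length(alt_freq_prior) == 2 && any(alt_freq_prior <= 0)) {
    stop("Beta shape parameters must be positive")
  }
  if (length(alt_freq_prior) == 1 && alt_freq_prior > 1) {
    stop("a fixed alternative-allele frequency must be in [0, 1]")
  }
  if (locus_dropout_rate < 0 || locus_dropout_rate >= 1) {
    stop("locus_dropout_rate must be in [0, 1)")
  }
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (sum(n_private) > n_loci) {
    stop("infeasible: ", sum(n_private), " planted private alleles need ",
         "at least as many loci (n_loci = ", n_loci, ")")
  }
  if (is.null(chromosomes)) {
    len <- tombul_chromosome_lengths()
    chromosomes <- data.frame(chrom = names(len), length_bp = unname(len),
                              stringsAsFactors = FALSE)
  }
  if (any(chromosomes$length_bp < locus_len)) {
    stop("every chromosome must be at least one locus long")
  }
  structure(list(seed = as.integer(seed), populations = populations,
                 n_loci = as.integer(n_loci), snp_lambda = snp_lambda,
                 snp_max = as.integer(snp_max),
                 alt_freq_prior = alt_freq_prior, f_is = f_is,
                 divergence = divergence, n_private = n_private,
                 private_profile = private_profile,
                 locus_dropout_rate = locus_dropout_rate,
                 chromosomes = chromosomes, locus_len = as.integer(locus_len)),
            class = "sim_config")
}

#' Two-group contrast configuration
#'
#' A [sim_config()] shaped like the resistant-versus-susceptible contrast:
#' 8 resistant and 13 susceptible accessions, wild-accession-like
#' inbreeding (F about 0.14).
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
contrast_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(populations = c("Resistant" = 8, "Susceptible" = 13),
                   f_is = 0.14)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# deterministic per-locus substream: changing n_loci never reshuffles
# the draws of earlier loci
.locus_seed <- function(seed, locus) {
  (seed * 10007L + locus * 97L) %% 2147483647L
}

.draw_genotype <- function(n, q, f) {
  p <- 1 - q
  if (q <= 0) return(rep.int(0L, n))
  if (q >= 1) return(rep.int(2L, n))
  f_eff <- max(f, -p / q, -q / p)
  probs <- c(p^2 + f_eff * p * q, 2 * p * q * (1 - f_eff), q^2 + f_eff * p * q)
  probs[probs < 0] <- 0
  sample.int(3L, n, replace = TRUE, prob = probs) - 1L  # copies of alt
}

#' Simulate a genotype catalog with known truth
#'
#' Draws a RAD genotype catalog under the model described in
#' [sim_config()], plants population-private alternative alleles with the
#' requested carrier profile, applies locus-level allele dropout, and
#' returns the genotypes together with the matching population map and a
#' truth table for downstream validation.
#'
#' Fully reproducible: the same configuration (including seed) yields a
#' byte-identical catalog. Each locus draws from its own deterministic
#' substream, so increasing `n_loci` extends the catalog without changing
#' earlier loci.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_result` with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()]}
#'     \item{popmap}{a [population_map()]}
#'     \item{truth}{list with `private_alleles` (one row per planted
#'       allele: site, allele, carrier population, intended diagnostic
#'       class), `site_freqs` (drawn ancestral alternative-allele frequency
#'       per background site), `populations` (configured F and realised
#'       mean expected heterozygosity per population), and `loci`
#'       (chromosome placement and SNP count per locus)}
#'   }
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pops <- names(config$populations)
  sizes <- config$populations
  individuals <- unlist(lapply(pops, function(p)
    paste0(gsub("\\s+", "_", p), "-", seq_len(sizes[[p]]))))
  pop_of <- rep(pops, sizes)
  member_idx <- lapply(pops, function(p) which(pop_of == p))
  names(member_idx) <- pops
  n_ind <- length(individuals)

  # reserved loci carry the planted private alleles, one allele per locus
  plant_pop <- rep(pops, config$n_private)
  n_reserved <- length(plant_pop)
  fixed_q <- length(config$alt_freq_prior) == 1

  sites_list <- vector("list", config$n_loci)
  a1_list <- vector("list", config$n_loci)
  a2_list <- vector("list", config$n_loci)
  truth_priv <- vector("list", n_reserved)
  loci_truth <- vector("list", config$n_loci)
  hexp_sum <- stats::setNames(numeric(length(pops)), pops)
  hexp_n <- 0L
  qf_locus <- vector("list", config$n_loci)

  chrom_w <- config$chromosomes$length_bp / sum(config$chromosomes$length_bp)

  for (l in seq_len(config$n_loci)) {
    set.seed(.locus_seed(config$seed, l))
    ci <- sample.int(nrow(config$chromosomes), 1, prob = chrom_w)
    chrom <- config$chromosomes$chrom[ci]
    start <- sample.int(config$chromosomes$length_bp[ci] - config$locus_len + 1L, 1)
    n_snp <- min(stats::rpois(1, config$snp_lambda), config$snp_max)
    reserved <- l <= n_reserved
    if (reserved && n_snp < 1) n_snp <- 1L
    loci_truth[[l]] <- data.frame(locus_id = l, chrom = chrom,
                                  locus_start_bp = start, n_snps = n_snp,
                                  reserved = reserved, stringsAsFactors = FALSE)
    if (n_snp == 0) next
    cols <- sort(sample.int(config$locus_len, n_snp) - 1L)
    ref <- sample(NUCLEOTIDES, n_snp, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(NUCLEOTIDES, r), 1), character(1))

    A1 <- matrix(NA_character_, n_snp, n_ind)
    A2 <- matrix(NA_character_, n_snp, n_ind)
    for (s in seq_len(n_snp)) {
      planted_site <- reserved && s == 1L
      if (planted_site) {
        # monomorphic reference everywhere, overwritten for the carrier pop
        A1[s, ] <- ref[s]; A2[s, ] <- ref[s]
        pop <- plant_pop[l]
        ix <- member_idx[[pop]]
        profile <- config$private_profile
        if (profile == "fixed_homozygous") {
          A1[s, ix] <- alt[s]; A2[s, ix] <- alt[s]
        } else if (profile == "all_heterozygous") {
          A1[s, ix] <- ref[s]; A2[s, ix] <- alt[s]
        } else {
          repeat {
            g <- sample.int(3L, length(ix), replace = TRUE) - 1L
            if (any(g > 0)) break
          }
          A1[s, ix] <- ifelse(g == 2L, alt[s], ref[s])
          A2[s, ix] <- ifelse(g >= 1L, alt[s], ref[s])
        }
        truth_priv[[l]] <- data.frame(
          locus_id = l, chrom = chrom, position_bp = start + cols[s],
          column = cols[s], ref = ref[s], allele = alt[s],
          population = pop, diagnostic_class = switch(profile,
            fixed_homozygous = "fixed_homozygous",
            all_heterozygous = "all_heterozygous", mixed = "none"),
          stringsAsFactors = FALSE)
        next
      }
      q_anc <- if (fixed_q) config$alt_freq_prior else
        stats::rbeta(1, config$alt_freq_prior[1], config$alt_freq_prior[2])
      hexp_n <- hexp_n + 1L
      qf_locus[[l]] <- rbind(qf_locus[[l]],
                             data.frame(locus_id = l, column = cols[s],
                                        q_anc = q_anc, stringsAsFactors = FALSE))
      for (p in pops) {
        q_p <- if (config$divergence > 0 && q_anc > 0 && q_anc < 1) {
          fd <- config$divergence
          stats::rbeta(1, q_anc * (1 - fd) / fd, (1 - q_anc) * (1 - fd) / fd)
        } else q_anc
        hexp_sum[p] <- hexp_sum[p] + 2 * q_p * (1 - q_p)
        ix <- member_idx[[p]]
        g <- .draw_genotype(length(ix), q_p, config$f_is[[p]])
        A1[s, ix] <- ifelse(g == 2L, alt[s], ref[s])
        A2[s, ix] <- ifelse(g >= 1L, alt[s], ref[s])
      }
    }
    # locus-level allele dropout
    if (config$locus_dropout_rate > 0) {
      drop <- stats::runif(n_ind) < config$locus_dropout_rate
      A1[, drop] <- NA_character_
      A2[, drop] <- NA_character_
    }
    sites_list[[l]] <- data.frame(locus_id = l, chrom = chrom,
                                  locus_start_bp = start, column = cols,
                                  position_bp = start + cols,
                                  ref = ref, alt = alt,
                                  stringsAsFactors = FALSE)
    a1_list[[l]] <- A1
    a2_list[[l]] <- A2
  }

  keep <- !vapply(sites_list, is.null, logical(1))
  sites <- do.call(rbind, sites_list[keep])
  a1 <- do.call(rbind, a1_list[keep])
  a2 <- do.call(rbind, a2_list[keep])
  gm <- genotype_matrix(individuals, sites, a1, a2, locus_len = config$locus_len)

  priv <- do.call(rbind, truth_priv[!vapply(truth_priv, is.null, logical(1))])
  if (is.null(priv)) {
    priv <- data.frame(locus_id = integer(), chrom = character(),
                       position_bp = integer(), column = integer(),
                       ref = character(), allele = character(),
                       population = character(), diagnostic_class = character(),
                       stringsAsFactors = FALSE)
  } else {
    priv$site <- match(paste(priv$locus_id, priv$column),
                       paste(sites$locus_id, sites$column))
  }
  site_freqs <- do.call(rbind, qf_locus[!vapply(qf_locus, is.null, logical(1))])
  if (is.null(site_freqs)) {
    site_freqs <- data.frame(locus_id = integer(), column = integer(),
                             q_anc = numeric(), stringsAsFactors = FALSE)
  }
  truth <- list(
    private_alleles = priv,
    site_freqs = site_freqs,
    populations = data.frame(population = pops,
                             f_is = unname(config$f_is),
                             mean_h_exp = if (hexp_n > 0)
                               unname(hexp_sum / hexp_n) else NA_real_,
                             stringsAsFactors = FALSE),
    loci = do.call(rbind, loci_truth))
  role <- if (length(pops) == 2) "phenotype-contrast" else "varietal"
  structure(list(genotypes = gm,
                 popmap = population_map(individuals, pop_of, role = role),
                 truth = truth, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result: seed", x$config$seed, "\n")
  print(x$genotypes)
  cat("  planted private alleles:", nrow(x$truth$private_alleles), "\n")
  invisible(x)
}
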