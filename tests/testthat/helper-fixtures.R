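# Fixture builders used across the test files. All fixtures are built in
# code; genotype strings like "CT" denote the two alleles of a diploid call
# and "--" a missing (dropped-out) locus.

# one-site genotype matrix from genotype strings
single_site_gm <- function(genos, ref, alt, locus_id = 1L, chrom = "1",
                           locus_start = 1000L, column = 10L,
                           individuals = paste0("ind", seq_along(genos))) {
  a1 <- matrix(ifelse(genos == "--", NA_character_, substr(genos, 1, 1)),
               nrow = 1)
  a2 <- matrix(ifelse(genos == "--", NA_character_, substr(genos, 2, 2)),
               nrow = 1)
  sites <- data.frame(locus_id = locus_id, chrom = chrom,
                      locus_start_bp = locus_start, column = column,
                      position_bp = locus_start + column,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(individuals, sites, a1, a2)
}

# multi-site genotype matrix: `sites` is a data.frame (locus_id, chrom,
# locus_start_bp, column, ref, alt); `genos` a character matrix
# (sites x individuals) of genotype strings
multi_site_gm <- function(sites, genos, individuals = NULL) {
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(genos)))
  sites$position_bp <- sites$locus_start_bp + sites$column
  a1 <- apply(genos, 2, function(g) ifelse(g == "--", NA, substr(g, 1, 1)))
  a2 <- apply(genos, 2, function(g) ifelse(g == "--", NA, substr(g, 2, 2)))
  genotype_matrix(individuals, sites, matrix(a1, nrow = nrow(sites)),
                  matrix(a2, nrow = nrow(sites)))
}

# The resistant/susceptible contrast catalog reconstructed from the five
# group-private loci: genotype configurations are fully determined by the
# printed N, P and Obs Het columns. Uncalled group members are dropped-out.
contrast_fixture <- function() {
  pmap <- contrast_population_map()
  res <- paste0("Res-", 1:8)
  sus <- paste0("Sus-", 1:13)
  sites <- data.frame(
    locus_id = c(781L, 22018L, 9218L, 18249L, 21961L),
    chrom = c("1", "3", "5", "11", "3"),
    locus_start_bp = c(22594282L - 18L, 3188310L - 139L, 10896200L - 127L,
                       17261698L - 72L, 30158075L - 40L),
    column = c(18L, 139L, 127L, 72L, 40L),
    ref = c("C", "T", "C", "T", "C"),
    alt = c("T", "A", "T", "C", "T"),
    stringsAsFactors = FALSE)
  g <- matrix("--", nrow = 5, ncol = 21,
              dimnames = list(NULL, c(res, sus)))
  g[1, res[1:4]] <- c("TT", "TT", "TT", "CT")            # 781: 4 called
  g[1, sus] <- "CC"
  g[2, res[1:5]] <- c("TT", "TT", "AA", "AA", "AA")      # 22018: 5 called
  g[2, sus] <- "TT"
  g[3, res[1:7]] <- c("CC", "CC", "CT", "TT", "TT", "TT", "TT")  # 9218
  g[3, sus] <- "CC"
  g[4, res[1:4]] <- c("TC", "TC", "CC", "CC")            # 18249: 4 called
  g[4, sus] <- "TT"
  g[5, sus[1:9]] <- c("CC", "CC", "CC", "TT", "TT", "TT",
                      "TT", "TT", "TT")                   # 21961: 9 called
  g[5, res] <- "CC"
  list(gm = multi_site_gm(sites, g, individuals = c(res, sus)), pmap = pmap)
}

# brute-force nucleotide diversity: mean pairwise difference over all
# unordered pairs of the 2N sampled alleles
brute_force_pi <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(0)
  diff <- 0; pairs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      diff <- diff + (alleles[i] != alleles[j])
      pairs <- pairs + 1
    }
  }
  unname(diff / pairs)
}

# brute-force allele classification by exhaustive occurrence enumeration:
# returns data.frame(site, allele, category) for every non-ref allele seen
brute_force_classify <- function(gm, pmap) {
  out <- NULL
  for (i in seq_len(n_sites(gm))) {
    seen <- list()
    for (pop in pop_names(pmap)) {
      for (ind in pop_members(pmap, pop)) {
        j <- match(ind, gm$individuals)
        for (al in c(gm$a1[i, j], gm$a2[i, j])) {
          if (is.na(al) || al == gm$sites$ref[i]) next
          seen[[al]] <- union(seen[[al]], pop)
        }
      }
    }
    for (al in names(seen)) {
      out <- rbind(out, data.frame(
        site = i, allele = al,
        category = if (length(seen[[al]]) == 1) "private" else "common",
        stringsAsFactors = FALSE))
    }
  }
  out
}
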