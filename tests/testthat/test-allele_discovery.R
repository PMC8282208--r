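# A small hand-built catalog exercising private/common classification:
# site 1: alt T only in pop X (private); site 2: alt T in two pops (common);
# site 3: monomorphic reference.
discovery_fixture <- function() {
  sites <- data.frame(locus_id = 1:3, chrom = "1",
                      locus_start_bp = c(100L, 400L, 700L),
                      column = c(10L, 20L, 30L),
                      ref = c("C", "A", "G"), alt = c("T", "T", "A"),
                      stringsAsFactors = FALSE)
  genos <- rbind(c("CT", "TT", "CC", "CC", "CC", "CC"),
                 c("AT", "AA", "AT", "AA", "AA", "AA"),
                 c("GG", "GG", "GG", "GG", "GG", "GG"))
  gm <- multi_site_gm(sites, genos)
  pmap <- population_map(gm$individuals, c("X", "X", "Y", "Y", "Z", "Z"))
  list(gm = gm, pmap = pmap)
}

test_that("alleles are classified by carrier-population count", {
  fx <- discovery_fixture()
  calls <- classify_alleles(fx$gm, fx$pmap)
  expect_equal(nrow(calls), 2)  # the monomorphic site yields no call
  t1 <- calls[calls$site == 1, ]
  expect_identical(t1$category, "private")
  expect_identical(t1$carrier_populations, "X")
  expect_equal(t1$n_copies, 3)
  t2 <- calls[calls$site == 2, ]
  expect_identical(t2$category, "common")
  expect_setequal(strsplit(t2$carrier_populations, ",")[[1]], c("X", "Y"))
})

test_that("classification matches exhaustive enumeration on small catalogs", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, populations = c(A = 2, B = 2, C = 2),
                      n_loci = 4, snp_lambda = 1, alt_freq_prior = c(1, 2),
                      chromosomes = data.frame(chrom = "1", length_bp = 1e5))
    res <- simulate_genotypes(cfg)
    if (n_sites(res$genotypes) == 0) next
    calls <- classify_alleles(res$genotypes, res$popmap)
    brute <- brute_force_classify(res$genotypes, res$popmap)
    got <- calls[order(calls$site, calls$allele),
                 c("site", "allele", "category")]
    want <- if (is.null(brute)) got[0, ] else
      brute[order(brute$site, brute$allele), ]
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("every observed non-reference allele is classified exactly once (partition)", {
  cfg <- sim_config(seed = 13, n_loci = 80, locus_dropout_rate = 0.1)
  res <- simulate_genotypes(cfg)
  calls <- classify_alleles(res$genotypes, res$popmap)
  expect_false(any(duplicated(calls[, c("site", "allele")])))
  expect_equal(sum(calls$category == "private") + sum(calls$category == "common"),
               nrow(calls))
  # consistency with a direct count of observed (site, alt allele) pairs
  n_observed <- 0L
  gm <- res$genotypes
  for (i in seq_len(n_sites(gm))) {
    obs <- c(gm$a1[i, ], gm$a2[i, ])
    n_observed <- n_observed +
      length(setdiff(unique(obs[!is.na(obs)]), gm$sites$ref[i]))
  }
  expect_equal(nrow(calls), n_observed)
})

test_that("coarsening the population map can only shrink the private set", {
  cfg <- sim_config(seed = 17, n_loci = 60)
  res <- simulate_genotypes(cfg)
  pm <- res$popmap
  fine <- classify_alleles(res$genotypes, pm)
  # merge the two largest populations
  merged <- ifelse(pm$population %in% c("Tombul", "Palaz"), "Merged",
                   pm$population)
  pm2 <- population_map(pm$individual, merged)
  coarse <- classify_alleles(res$genotypes, pm2)
  key <- function(d) paste(d$site, d$allele)
  priv_fine <- key(fine[fine$category == "private", ])
  priv_coarse <- key(coarse[coarse$category == "private", ])
  extra <- setdiff(priv_coarse, priv_fine)
  # any newly-private allele must have been carried only by the merged pair
  if (length(extra) > 0) {
    carriers <- fine$carrier_populations[match(extra, key(fine))]
    expect_true(all(vapply(strsplit(carriers, ","), function(cp)
      all(cp %in% c("Tombul", "Palaz")), logical(1))))
  }
  # alleles private outside the merged pair stay private
  carriers_fine <- fine$carrier_populations[fine$category == "private"]
  outside <- priv_fine[!carriers_fine %in% c("Tombul", "Palaz")]
  expect_true(all(outside %in% priv_coarse))
})

test_that("removing an individual never converts a common allele to absent everywhere", {
  cfg <- sim_config(seed = 19, n_loci = 50)
  res <- simulate_genotypes(cfg)
  gm <- res$genotypes
  calls <- classify_alleles(gm, res$popmap)
  common <- calls[calls$category == "common", ]
  drop_ind <- gm$individuals[5]
  keep <- gm$individuals != drop_ind
  gm2 <- genotype_matrix(gm$individuals[keep], gm$sites,
                         gm$a1[, keep, drop = FALSE], gm$a2[, keep, drop = FALSE])
  pm2 <- population_map(res$popmap$individual[res$popmap$individual != drop_ind],
                        res$popmap$population[res$popmap$individual != drop_ind])
  calls2 <- classify_alleles(gm2, pm2)
  key <- function(d) paste(d$site, d$allele)
  expect_true(all(key(common) %in% key(calls2)))
})

test_that("diagnostic filter keeps only uniform carrier populations", {
  mk <- function(genos_x) {
    sites <- data.frame(locus_id = 1L, chrom = "1", locus_start_bp = 100L,
                        column = 0L, ref = "C", alt = "T",
                        stringsAsFactors = FALSE)
    genos <- matrix(c(genos_x, "CC", "CC"), nrow = 1)
    gm <- multi_site_gm(sites, genos)
    pmap <- population_map(gm$individuals,
                           c(rep("X", length(genos_x)), "Y", "Y"))
    list(gm = gm, pmap = pmap)
  }
  hom <- mk(c("TT", "TT"))
  calls <- classify_alleles(hom$gm, hom$pmap)
  kept <- diagnostic_filter(calls, hom$gm, hom$pmap)
  expect_equal(nrow(kept), 1)
  expect_identical(kept$diagnostic_class, "fixed_homozygous")

  het <- mk(c("CT", "CT", "CT"))
  kept <- diagnostic_filter(classify_alleles(het$gm, het$pmap), het$gm, het$pmap)
  expect_identical(kept$diagnostic_class, "all_heterozygous")

  mixed <- mk(c("TT", "CT"))
  kept <- diagnostic_filter(classify_alleles(mixed$gm, mixed$pmap),
                            mixed$gm, mixed$pmap)
  expect_equal(nrow(kept), 0)
})

test_that("diagnostic filter ignores individuals missing the locus", {
  sites <- data.frame(locus_id = 1L, chrom = "1", locus_start_bp = 100L,
                      column = 0L, ref = "C", alt = "T", stringsAsFactors = FALSE)
  genos <- matrix(c("TT", "TT", "--", "CC", "CC"), nrow = 1)
  gm <- multi_site_gm(sites, genos)
  pmap <- population_map(gm$individuals, c("X", "X", "X", "Y", "Y"))
  kept <- diagnostic_filter(classify_alleles(gm, pmap), gm, pmap)
  expect_identical(kept$diagnostic_class, "fixed_homozygous")
})

test_that("locus-universality filter keeps only sufficiently sequenced loci", {
  sites <- data.frame(locus_id = c(1L, 2L), chrom = "1",
                      locus_start_bp = c(100L, 400L), column = 0L,
                      ref = "C", alt = "T", stringsAsFactors = FALSE)
  genos <- rbind(c("CT", "CC", "CC", "CC"),
                 c("CT", "CC", "CC", "--"))
  gm <- multi_site_gm(sites, genos)
  pmap <- population_map(gm$individuals, c("X", "X", "Y", "Y"))
  calls <- classify_alleles(gm, pmap)
  expect_equal(calls$locus_universality[calls$site == 1], 1.0)
  expect_equal(calls$locus_universality[calls$site == 2], 0.75)
  expect_equal(universal_locus_filter(calls, 1.0)$site, 1L)
  expect_equal(nrow(universal_locus_filter(calls, 0.75)), 2)
  expect_error(universal_locus_filter(calls, 0), "\\(0, 1\\]")
})

test_that("planted private alleles are recovered exactly on a clean background", {
  cfg <- sim_config(seed = 23, alt_freq_prior = 0, n_loci = 40,
                    n_private = c(Allahverdi = 2, "Çakıldak" = 0,
                                  "Karafındık" = 0, Mincane = 0, Palaz = 3,
                                  "Sarıfındık" = 0, Sivri = 0, Tombul = 0,
                                  Yomra = 0))
  res <- simulate_genotypes(cfg)
  calls <- classify_alleles(res$genotypes, res$popmap)
  truth <- res$truth$private_alleles
  key <- function(d) paste(d$site, d$allele)
  expect_setequal(key(calls[calls$category == "private", ]), key(truth))
  kept <- diagnostic_filter(calls, res$genotypes, res$popmap)
  expect_setequal(key(kept), key(truth))
  expect_true(all(kept$diagnostic_class == "fixed_homozygous"))
  expect_equal(count_private(calls, res$popmap)[["Palaz"]], 3L)
  expect_equal(sum(count_private(calls, res$popmap)), 5L)
})

test_that("count_private returns zeros when there are no alternative alleles", {
  gm <- single_site_gm(c("GG", "GG", "GG"), ref = "G", alt = "A")
  pm <- population_map(gm$individuals, c("X", "X", "Y"))
  counts <- count_private(classify_alleles(gm, pm), pm)
  expect_identical(counts, c(X = 0L, Y = 0L))
})

test_that("group contrast recovers the five group-private loci with their printed frequencies", {
  fx <- contrast_fixture()
  hits <- group_contrast(fx$gm, fx$pmap)
  expect_equal(nrow(hits), 5)
  expect_setequal(hits$locus_id, c(781L, 22018L, 9218L, 18249L, 21961L))
  # locus 9218: called in 7 of 8 resistant accessions, 5 of them carriers
  h9218 <- hits[hits$locus_id == 9218, ]
  expect_identical(h9218$focal_group, "Resistant")
  expect_equal(h9218$n_called, 7)
  expect_equal(h9218$carrier_count, 5)
  expect_equal(h9218$carrier_fraction, 5 / 8)
  expect_equal(h9218$alt_freq, 9 / 14)
  # the susceptible-private allele: 12 of 18 called alleles
  h21961 <- hits[hits$locus_id == 21961, ]
  expect_identical(h21961$focal_group, "Susceptible")
  expect_equal(h21961$alt_freq, 2 / 3)
  expect_true(all(hits$absent_in_other))
})

test_that("group contrast criteria switches behave as documented", {
  fx <- contrast_fixture()
  # carrier count over the nominal group size, inclusive >= 0.5:
  # locus 22018 (3 carriers of 8) and 21961 (6 of 13) drop out
  nominal <- group_contrast(fx$gm, fx$pmap, criterion = "carrier-nominal")
  expect_setequal(nominal$locus_id, c(781L, 9218L, 18249L))
  # an allele present once in each group is never a hit
  sites <- data.frame(locus_id = 1L, chrom = "1", locus_start_bp = 100L,
                      column = 0L, ref = "C", alt = "T", stringsAsFactors = FALSE)
  genos <- matrix(c("CT", "CC", "CT", "CC"), nrow = 1)
  gm <- multi_site_gm(sites, genos)
  pmap <- population_map(gm$individuals, c("R", "R", "S", "S"),
                         role = "phenotype-contrast")
  expect_equal(nrow(group_contrast(gm, pmap)), 0)
  # more than two populations is an error pointing at classify_alleles
  fx3 <- discovery_fixture()
  expect_error(group_contrast(fx3$gm, fx3$pmap), "classify_alleles")
})
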