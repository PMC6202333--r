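test_that("transmission phasing resolves forced configurations only", {
  ped <- make_trio()
  # father hom-alt, mother hom-ref, child het: both origins forced
  res <- phase_by_transmission(ped, c(fa = 2L, mo = 0L, ch = 1L))
  hap <- res$haplotypes
  expect_equal(hap$paternal_allele[hap$id == "ch"], 1L)
  expect_equal(hap$maternal_allele[hap$id == "ch"], 0L)
  expect_length(res$mendelian_errors, 0L)

  # both parents het: unforced
  res2 <- phase_by_transmission(ped, c(fa = 1L, mo = 1L, ch = 1L))
  expect_true(is.na(res2$haplotypes$paternal_allele[3]))
  expect_true(is.na(res2$haplotypes$maternal_allele[3]))

  # Mendelian inconsistency flagged
  res3 <- phase_by_transmission(ped, c(fa = 2L, mo = 2L, ch = 0L))
  expect_true("ch" %in% res3$mendelian_errors)
})

test_that("transmission phasing agrees with gene-dropping ground truth wherever assigned", {
  cfg <- simulation_config(n_individuals = 150, n_generations = 4,
                           founder_maf = 0.3, n_decoy_variants = 0,
                           seed = 5L)
  ped <- simulate_genealogy(cfg)
  gd <- gene_drop(ped, cfg)
  counts <- gd$gs$genotypes[1, ]
  hap_truth <- gd$truth[[gd$focal_id]]$haplotypes
  res <- phase_by_transmission(ped, counts)
  expect_length(res$mendelian_errors, 0L)
  assigned_p <- !is.na(res$haplotypes$paternal_allele)
  assigned_m <- !is.na(res$haplotypes$maternal_allele)
  expect_gt(sum(assigned_p), 0L)
  expect_equal(res$haplotypes$paternal_allele[assigned_p],
               hap_truth[assigned_p, 1])
  expect_equal(res$haplotypes$maternal_allele[assigned_m],
               hap_truth[assigned_m, 2])
})

test_that("dosage imputation matches forced-chain expectations and the HWE posterior oracle", {
  p <- 0.01
  ped <- make_trio()
  # untyped mother; typed child carries an allele the typed father lacks
  d <- impute_untyped(ped, c(fa = 0L, mo = NA, ch = 1L), p = p)
  expect_equal(d$theta_hat[d$id == "mo"], 1 + p)
  # exhaustive enumeration weighted by HWE priors gives the same value
  oracle <- oracle_posterior_dosage(ped, c(fa = 0L, mo = NA, ch = 1L), p)
  expect_equal(d$theta_hat[d$id == "mo"], unname(oracle["mo"]),
               tolerance = 1e-12)

  # typed individuals keep observed counts
  expect_equal(d$theta_hat[d$id == "ch"], 1)
  d2 <- impute_untyped(ped, c(fa = 2L, mo = 1L, ch = 2L), p = p)
  expect_equal(d2$theta_hat, c(2, 1, 2))

  # untyped individual with no typed relatives gets the population prior
  ids <- c("fa", "mo", "ch", "solo")
  ped4 <- new_pedigree(data.frame(
    id = ids, father = c(NA, NA, "fa", NA), mother = c(NA, NA, "mo", NA),
    sex = c("male", "female", "male", "female"), affected = "unknown",
    stringsAsFactors = FALSE))
  d4 <- impute_untyped(ped4, c(fa = 0L, mo = 0L, ch = 0L, solo = NA), p = p)
  expect_equal(d4$theta_hat[d4$id == "solo"], 2 * p)

  # grandparental chain: typed homozygous grandfather forces a haplotype
  # through the untyped father into scoring
  ids5 <- c("gf", "gm", "fa", "mo", "ch")
  ped5 <- new_pedigree(data.frame(
    id = ids5, father = c(NA, NA, "gf", NA, "fa"),
    mother = c(NA, NA, "gm", NA, "mo"),
    sex = c("male", "female", "male", "female", "male"),
    affected = "unknown", stringsAsFactors = FALSE))
  obs5 <- c(gf = 2L, gm = 0L, fa = NA, mo = 0L, ch = NA)
  d5 <- impute_untyped(ped5, obs5, p = p)
  expect_equal(d5$theta_hat[d5$id == "fa"], 1)  # one 1, one 0 forced
  # child: maternal haplotype forced to 0 by the typed non-carrier
  # mother; the unforced paternal transmission from the resolved-het
  # father contributes the fair-segregation expectation 1/2
  expect_equal(d5$theta_hat[d5$id == "ch"], 0.5)
  oracle5 <- oracle_posterior_dosage(ped5, obs5, p)
  expect_equal(d5$theta_hat[d5$id == "fa"], unname(oracle5["fa"]),
               tolerance = 1e-12)
  expect_equal(d5$theta_hat[d5$id == "ch"], unname(oracle5["ch"]),
               tolerance = 1e-12)

  expect_error(impute_untyped(ped, c(fa = NA, mo = NA, ch = NA), p = p),
               "typed")
})

test_that("dosages stay calibrated: mean theta-hat converges to 2p", {
  cfg <- simulation_config(n_individuals = 10000, n_generations = 4,
                           founder_maf = 0.1, chip_typed_fraction = 0.5,
                           n_decoy_variants = 0, seed = 31L)
  ped <- simulate_genealogy(cfg)
  gd <- gene_drop(ped, cfg)
  counts <- gd$gs$genotypes[1, ]
  set.seed(77)
  obs <- counts
  obs[runif(length(obs)) > cfg$chip_typed_fraction] <- NA
  p <- cfg$founder_maf
  d <- impute_untyped(ped, obs, p = p)
  se <- sqrt(2 * p * (1 - p) / length(obs))
  expect_lt(abs(mean(d$theta_hat) - 2 * p), 3 * se + abs(mean(counts) - 2 * p))
  # imputed haplotypes never contradict typed genotypes
  expect_equal(d$theta_hat[d$typed], unname(counts[!is.na(obs)]))
})

test_that("information score is 0 when constant, ~1 when fully typed, monotone in typing", {
  # degenerate: same value always imputed
  expect_equal(imputation_information(rep(0.4, 50), p = 0.2), 0)

  # fully informative: dosages equal true counts under HWE
  set.seed(8)
  p <- 0.3
  n <- 4000
  ids <- sprintf("S%04d", 1:n)
  ped <- new_pedigree(data.frame(id = ids, father = NA_character_,
                                 mother = NA_character_, sex = "unknown",
                                 affected = "unknown",
                                 stringsAsFactors = FALSE))
  counts <- stats::setNames(rbinom(n, 2, p), ids)
  full <- impute_untyped(ped, counts, p = p)
  expect_equal(imputation_information(full), 1, tolerance = 0.05)

  # typing more individuals never decreases the information score
  sizes <- c(500, 1000, 2000, 4000)
  perm <- sample(ids)
  infos <- vapply(sizes, function(k) {
    obs <- counts
    obs[!names(obs) %in% perm[1:k]] <- NA
    imputation_information(impute_untyped(ped, obs, p = p))
  }, numeric(1))
  expect_true(all(diff(infos) >= -1e-12))

  expect_error(imputation_information(rep(0.5, 10), p = 0), "undefined")
})

test_that("information score approximates r-squared with truth under partial haplotype resolution", {
  set.seed(99)
  p <- 0.25
  n_hap <- 10000
  n <- n_hap / 2
  truth_h <- matrix(rbinom(n_hap, 1, p), n, 2)
  resolve <- matrix(runif(n_hap) < 0.6, n, 2)  # each haplotype seen w.p. 0.6
  h_exp <- ifelse(resolve, truth_h, p)
  dos <- data.frame(id = sprintf("S%d", 1:n),
                    theta_hat = h_exp[, 1] + h_exp[, 2],
                    h1 = h_exp[, 1], h2 = h_exp[, 2],
                    typed = resolve[, 1] & resolve[, 2])
  attr(dos, "p") <- p
  class(dos) <- c("dosage_vector", "data.frame")
  info <- imputation_information(dos)
  r2 <- cor(dos$theta_hat, truth_h[, 1] + truth_h[, 2])^2
  expect_lt(abs(info - r2), 0.05)
})
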