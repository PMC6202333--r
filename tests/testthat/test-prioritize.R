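test_that("compute_maf counts alleles and folds to the minor allele", {
  expect_equal(compute_maf(c(0L, 1L, 1L, 2L)), 0.5)
  expect_equal(compute_maf(c(0L, 0L, 0L)), 0)
  # folding oracle: brute-force count of both alleles
  counts <- c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 1L)  # alt frequency 0.9
  alt <- sum(counts); ref <- 2 * length(counts) - alt
  expect_equal(compute_maf(counts), min(alt, ref) / (alt + ref))
  expect_equal(compute_maf(counts), 0.1)
  # males contribute one allele on X
  expect_equal(compute_maf(c(1L, 1L, 0L), ploidy = c(1L, 2L, 2L)), 0.4)
  # missing calls drop out of the denominator
  expect_equal(compute_maf(c(1L, NA, 0L)), 0.25)
  expect_error(compute_maf(c(NA_integer_, NA_integer_)), "undefined")
})

test_that("impact classification is total and matches the class vocabulary", {
  expect_equal(classify_impact("stop_gained"), "high")
  expect_equal(classify_impact("frameshift_variant"), "high")
  expect_equal(classify_impact("missense_variant"), "moderate")
  expect_equal(classify_impact("splice_region_variant"), "moderate")
  expect_equal(classify_impact("synonymous_variant"), "low")
  expect_equal(classify_impact("regulatory_region_variant"), "dhs")
  expect_equal(classify_impact("intergenic_variant"), "remaining")
  expect_equal(classify_impact("unknown"), "remaining")
  expect_equal(classify_impact(c("stop_gained", "nonsense_made_up")),
               c("high", "remaining"))
})

test_that("dominant filter applies het, threshold, and parental-exclusion clauses", {
  ids <- c("fa", "mo", "p1", "p2")
  ped <- new_pedigree(data.frame(
    id = ids, father = c(NA, NA, "fa", "fa"),
    mother = c(NA, NA, "mo", "mo"),
    sex = c("male", "female", "male", "male"),
    affected = c("unaffected", "unaffected", "affected", "affected"),
    stringsAsFactors = FALSE))
  #            fa mo p1 p2
  g <- rbind(c(0, 0, 1, 1),   # qualifies
             c(1, 0, 1, 1),   # carried by unaffected father
             c(0, 0, 1, 1),   # MAF above threshold
             c(0, 0, 1, 0))   # not het in both affecteds
  colnames(g) <- ids
  gs <- make_gs(g, gene = c("G1", "G2", "G3", "G4"))
  freqs <- make_freqs(gs, maf_internal = c(0.0004, 0.0004, 0.0006, 0.0004))
  cands <- filter_dominant(ped, gs, freqs)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$model, "dominant")
  expect_equal(cands[[1]]$gene, "G1")
  expect_error(filter_dominant(make_trio(affected = rep("unaffected", 3)),
                               gs, freqs), "no affected")
})

test_that("recessive filter keeps qualifying homozygotes and drops threshold/segregation failures", {
  fx <- build_proband_family_fixture(tempfile())
  gs <- read_vcf_genotypes(fx$vcf)
  ped <- read_pedigree(fx$ped)
  freqs <- read_frequency_table(fx$freq)
  cands <- filter_recessive(ped, gs, freqs)
  expect_length(cands, 2L)
  expect_setequal(vapply(cands, `[[`, character(1), "gene"),
                  c("FOCAL1", "RCPT1"))
  expect_true(all(vapply(cands, `[[`, character(1), "model") == "recessive_hom"))
  expect_setequal(cands[[1]]$carrier_ids, c("A", "B"))

  # requiring high impact leaves exactly the stop-gained candidate
  high <- Filter(function(cd) all(classify_impact(cd$consequence) == "high"),
                 cands)
  expect_length(high, 1L)
  expect_equal(high[[1]]$gene, "FOCAL1")

  # lowering the threshold never adds candidates (monotonicity)
  for (thr in c(0.01, 0.005, 0.002)) {
    sub <- filter_recessive(ped, gs, freqs, threshold = thr)
    ids_sub <- vapply(sub, function(cd) paste(cd$variants, collapse = "+"),
                      character(1))
    ids_full <- vapply(cands, function(cd) paste(cd$variants, collapse = "+"),
                       character(1))
    expect_true(all(ids_sub %in% ids_full))
  }
  # at 0.5% only the rarer missense genotype survives
  sub5 <- filter_recessive(ped, gs, freqs, threshold = 0.005)
  expect_length(sub5, 1L)
  expect_equal(sub5[[1]]$gene, "RCPT1")
})

test_that("external-frequency absence passes the external clause; missing affected genotype excludes", {
  ids <- c("fa", "mo", "p1")
  ped <- new_pedigree(data.frame(
    id = ids, father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
    sex = c("male", "female", "male"),
    affected = c("unaffected", "unaffected", "affected"),
    stringsAsFactors = FALSE))
  g <- rbind(c(1, 1, 2), c(1, 1, NA))
  colnames(g) <- ids
  gs <- make_gs(g, gene = c("G1", "G2"))
  freqs <- make_freqs(gs, maf_internal = c(0.01, 0.01),
                      maf_external = c(NA, NA))
  cands <- filter_recessive(ped, gs, freqs)
  expect_length(cands, 1L)  # absent external passes; NA affected genotype drops
  expect_equal(cands[[1]]$gene, "G1")
})

test_that("compound-het pairs phase by transmission and in-cis pairs drop", {
  ids <- c("fa", "mo", "p1")
  ped <- new_pedigree(data.frame(
    id = ids, father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
    sex = c("male", "female", "male"),
    affected = c("unaffected", "unaffected", "affected"),
    stringsAsFactors = FALSE))
  # trans pair: father carries v1 only, mother v2 only
  g <- rbind(c(1, 0, 1), c(0, 1, 1))
  colnames(g) <- ids
  gs <- make_gs(g, gene = "G1")
  freqs <- make_freqs(gs, maf_internal = 0.01)
  cands <- filter_recessive(ped, gs, freqs)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$model, "recessive_comphet")
  expect_equal(cands[[1]]$phase, "in_trans")

  # cis pair: father carries both, mother neither
  g2 <- rbind(c(1, 0, 1), c(1, 0, 1))
  colnames(g2) <- ids
  gs2 <- make_gs(g2, gene = "G1")
  expect_length(filter_recessive(ped, gs2, make_freqs(gs2, 0.01)), 0L)

  # ambiguous pair retained but flagged
  g3 <- rbind(c(1, 1, 1), c(1, 1, 1))
  colnames(g3) <- ids
  gs3 <- make_gs(g3, gene = "G1")
  cands3 <- filter_recessive(ped, gs3, make_freqs(gs3, 0.01))
  expect_length(cands3, 1L)
  expect_equal(cands3[[1]]$phase, "ambiguous")

  # intergenic (empty gene) variants never pair
  gs4 <- make_gs(g, gene = "")
  expect_length(filter_recessive(ped, gs4, make_freqs(gs4, 0.01)), 0L)

  # an unaffected sibling demonstrably carrying the pair in trans fails
  ids5 <- c("fa", "mo", "p1", "s1")
  ped5 <- new_pedigree(data.frame(
    id = ids5, father = c(NA, NA, "fa", "fa"),
    mother = c(NA, NA, "mo", "mo"),
    sex = c("male", "female", "male", "female"),
    affected = c("unaffected", "unaffected", "affected", "unaffected"),
    stringsAsFactors = FALSE))
  g5 <- rbind(c(1, 0, 1, 1), c(0, 1, 1, 1))
  colnames(g5) <- ids5
  gs5 <- make_gs(g5, gene = "G1")
  expect_length(filter_recessive(ped5, gs5, make_freqs(gs5, 0.01)), 0L)
})

test_that("compound-het phasing agrees with exhaustive transmission enumeration", {
  set.seed(42)
  for (i in 1:300) {
    father <- sample(c(0:2, NA), 2, replace = TRUE)
    mother <- sample(c(0:2, NA), 2, replace = TRUE)
    expect_equal(phase_compound_het(c(1L, 1L), father, mother),
                 oracle_phase(father, mother),
                 info = paste("father", paste(father, collapse = ","),
                              "mother", paste(mother, collapse = ",")))
  }
  expect_error(phase_compound_het(c(2L, 1L), c(1, 1), c(1, 1)),
               "heterozygous")
})

test_that("segregation check fails on unaffected carriers of the full genotype", {
  fx <- build_proband_family_fixture(tempfile())
  gs <- read_vcf_genotypes(fx$vcf)
  ped <- read_pedigree(fx$ped)
  focal <- "chr17:82449249:C:G"
  cand <- structure(list(model = "recessive_hom", variants = focal,
                         gene = "FOCAL1", carrier_ids = c("A", "B"),
                         phase = "not_applicable", maf_internal = 0.0076,
                         maf_external = NA, chrom = "chr17",
                         pos = 82449249L, consequence = "stop_gained"),
                    class = "candidate_genotype")
  expect_true(check_segregation(cand, ped, gs)$pass)

  # make an unaffected sib homozygous
  gs2 <- gs
  gs2$genotypes[focal, "sib1"] <- 2L
  res <- check_segregation(cand, ped, gs2)
  expect_false(res$pass)
  expect_match(res$reason, "unaffected carrier")

  # dominant candidate carried het by an unaffected sib fails
  cand_dom <- cand
  cand_dom$model <- "dominant"
  expect_false(check_segregation(cand_dom, ped, gs)$pass)
})
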