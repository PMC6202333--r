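# Synthetic founder-population generator. Produces every input the
# pipeline consumes with the statistical structure the analysis assumes:
# a multi-generation genealogy, gene-dropped genotypes with a rare focal
# founder allele, binary and quantitative phenotypes with recessive
# effects, chip-typing masks, and lognormal flow-cytometry event lists.
# Single-site focal model: no linkage disequilibrium and no
# recombination, because the analyses under test are single-variant.

#' Simulation configuration
#'
#' Default parameters emulate the study regime the package targets: a
#' founder loss-of-function allele at MAF 0.76%, a strongly recessive
#' binary outcome (homozygote odds ratio 67.6 on a 1% baseline risk), a
#' -1.24 SD homozygote shift on a standardized quantitative trait, and a
#' chip-typed fraction of 0.46 of the population.
#'
#' @param n_individuals Target population size.
#' @param n_generations Number of generations in the genealogy.
#' @param founder_maf Founder-haplotype frequency of the focal allele.
#' @param chip_typed_fraction Fraction of individuals directly genotyped.
#' @param baseline_risk Binary-outcome risk for non-homozygotes.
#' @param hom_or Homozygote odds ratio for the binary outcome.
#' @param quant_effect_sd Homozygote shift on the standardized trait.
#' @param n_decoy_variants Number of unlinked decoy variants.
#' @param decoy_maf_range MAF range the decoys are drawn from.
#' @param mean_children Mean sibship size per mating.
#' @param seed Master seed; all stochastic operations derive child seeds
#'   from it deterministically.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_individuals = 2000,
                              n_generations = 4,
                              founder_maf = 0.0076,
                              chip_typed_fraction = 0.46,
                              baseline_risk = 0.01,
                              hom_or = 67.6,
                              quant_effect_sd = -1.24,
                              n_decoy_variants = 10,
                              decoy_maf_range = c(0.001, 0.2),
                              mean_children = 2.5,
                              seed = 1L) {
  stopifnot(n_individuals >= 2, n_generations >= 1,
            founder_maf >= 0, founder_maf <= 1,
            chip_typed_fraction >= 0, chip_typed_fraction <= 1,
            baseline_risk > 0, baseline_risk < 1, hom_or > 0,
            mean_children > 0)
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  structure(list(n_individuals = n_individuals,
                 n_generations = n_generations,
                 founder_maf = founder_maf,
                 chip_typed_fraction = chip_typed_fraction,
                 baseline_risk = baseline_risk, hom_or = hom_or,
                 quant_effect_sd = quant_effect_sd,
                 n_decoy_variants = n_decoy_variants,
                 decoy_maf_range = decoy_maf_range,
                 mean_children = mean_children,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic child-seed derivation from the master seed
.child_seed <- function(config, offset) {
  (config$seed * 2654435761 + offset * 97) %% 2147483647
}

#' Simulate a multi-generation founder genealogy
#'
#' Generation 1 consists of founder couples; in each later generation the
#' previous generation's offspring mate monogamously with newly added
#' immigrant founders (keeping the parent graph acyclic) and have
#' Poisson-distributed sibship sizes. Growth stops once the target
#' population size is reached. Reproducible by seed.
#'
#' @param config A `simulation_config`.
#' @return A `pedigree` with a `generation` column.
#' @export
simulate_genealogy <- function(config) {
  set.seed(.child_seed(config, 1L))
  n_target <- config$n_individuals
  n_gen <- config$n_generations
  # founder couples sized so the final population roughly hits the target
  growth <- 1 + config$mean_children / 2
  n_couples <- max(1L, ceiling(n_target / (2 * sum(growth^(0:(n_gen - 1))))))

  id_ctr <- 0L
  new_id <- function(k) {
    ids <- sprintf("I%06d", id_ctr + seq_len(k)); id_ctr <<- id_ctr + k; ids
  }
  rows <- list()
  add <- function(id, father, mother, sex, gen) {
    if (!length(id)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, father = father, mother = mother, sex = sex,
      affected = "unknown", genotyped = TRUE, generation = gen,
      stringsAsFactors = FALSE)
  }
  fathers <- new_id(n_couples); mothers <- new_id(n_couples)
  add(fathers, NA_character_, NA_character_, "male", 1L)
  add(mothers, NA_character_, NA_character_, "female", 1L)
  current <- data.frame(father = fathers, mother = mothers,
                        stringsAsFactors = FALSE)

  for (gen in seq_len(n_gen - 1L)) {
    if (id_ctr >= n_target) break
    nc <- nrow(current)
    k <- 1L + stats::rpois(nc, config$mean_children - 1)
    # truncate sibships so the offspring wave stays within the target
    k <- pmin(k, pmax(0L, n_target - id_ctr - c(0L, cumsum(k))[seq_len(nc)]))
    total <- sum(k)
    if (total <= 0L) break
    offspring_id <- new_id(total)
    offspring_sex <- sample(c("male", "female"), total, replace = TRUE)
    add(offspring_id, rep(current$father, k), rep(current$mother, k),
        offspring_sex, gen + 1L)
    # marry offspring to immigrant founders of the opposite sex, up to
    # the remaining population budget
    n_sp <- min(total, max(0L, n_target - id_ctr))
    if (n_sp == 0L) break
    mated_id <- offspring_id[seq_len(n_sp)]
    mated_sex <- offspring_sex[seq_len(n_sp)]
    spouses <- new_id(n_sp)
    add(spouses, NA_character_, NA_character_,
        ifelse(mated_sex == "male", "female", "male"), gen + 1L)
    current <- data.frame(
      father = ifelse(mated_sex == "male", mated_id, spouses),
      mother = ifelse(mated_sex == "male", spouses, mated_id),
      stringsAsFactors = FALSE)
  }
  ped <- do.call(rbind, rows)
  new_pedigree(ped)
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder haplotypes carry the focal allele at `founder_maf`; each
#' meiosis transmits one of the parent's two haplotypes with equal
#' probability. Decoy variants are dropped independently with MAFs drawn
#' from the configured spectrum. Ground truth (per-haplotype alleles) is
#' returned for every variant.
#'
#' @param ped A `pedigree` (e.g. from [simulate_genealogy()]).
#' @param config A `simulation_config`.
#' @return List with `gs` (a genotype set; focal variant first),
#'   `truth` (list per variant: n x 2 haplotype matrix, realized MAF),
#'   and `focal_id` (variant id of the focal site).
#' @export
gene_drop <- function(ped, config) {
  set.seed(.child_seed(config, 2L))
  n <- nrow(ped)
  depth <- pedigree_depth(ped)
  ord <- order(depth)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)

  mafs <- c(config$founder_maf,
            if (config$n_decoy_variants > 0)
              stats::runif(config$n_decoy_variants,
                           config$decoy_maf_range[1], config$decoy_maf_range[2]))
  drop_one <- function(maf) {
    hap <- matrix(NA_integer_, n, 2)
    for (i in ord) {
      if (is.na(fa[i])) {
        hap[i, ] <- stats::rbinom(2, 1, maf)
      } else {
        hap[i, 1] <- hap[fa[i], sample.int(2, 1)]
        hap[i, 2] <- hap[mo[i], sample.int(2, 1)]
      }
    }
    hap
  }
  truth <- lapply(mafs, drop_one)

  vids <- character(length(mafs))
  vtab <- list()
  for (k in seq_along(mafs)) {
    if (k == 1L) {
      vtab[[k]] <- data.frame(
        variant_id = NA, chrom = "chr17", pos = 82449249L, ref = "C",
        alt = "G", gene = "FOCAL1", consequence = "stop_gained",
        hgvs_p = "p.Tyr2Ter", stringsAsFactors = FALSE)
    } else {
      vtab[[k]] <- data.frame(
        variant_id = NA, chrom = paste0("chr", 1 + (k %% 20)),
        pos = 1000000L + k * 1000L, ref = "A", alt = "T",
        gene = paste0("DECOY", k - 1L),
        consequence = sample(c("missense_variant", "synonymous_variant",
                               "intron_variant"), 1),
        hgvs_p = "", stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, vtab)
  variants$variant_id <- .variant_id(variants$chrom, variants$pos,
                                     variants$ref, variants$alt)
  genotypes <- t(vapply(truth, function(h) as.integer(rowSums(h)),
                        integer(n)))
  rownames(genotypes) <- variants$variant_id
  colnames(genotypes) <- ped$id
  truth <- lapply(seq_along(truth), function(k)
    list(haplotypes = truth[[k]],
         realized_maf = compute_maf(genotypes[k, ])))
  names(truth) <- variants$variant_id
  list(gs = list(variants = variants, genotypes = genotypes,
                 samples = ped$id),
       truth = truth,
       focal_id = variants$variant_id[1])
}

#' Simulate phenotypes with a recessive genetic effect
#'
#' The binary outcome is drawn per individual from a logistic model:
#' baseline log-odds plus `ln(hom_or)` for focal homozygotes plus mild
#' sex / age / region covariate effects. The quantitative trait is
#' standard normal plus covariate effects plus `quant_effect_sd` for
#' homozygotes.
#'
#' @param hom_indicator 0/1 vector: focal-genotype homozygote.
#' @param config A `simulation_config`.
#' @param sex Optional character vector ("male"/"female"); simulated when
#'   absent.
#' @param seed_offset Offset for the derived child seed (lets callers
#'   draw independent replicates from one config).
#' @return data.frame: id, case_status, trait, sex, age, region.
#' @export
simulate_phenotypes <- function(hom_indicator, config, sex = NULL,
                                seed_offset = 0L) {
  set.seed(.child_seed(config, 3L + seed_offset))
  n <- length(hom_indicator)
  if (is.null(sex)) sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- sample(20:90, n, replace = TRUE)
  region <- sample(paste0("R", 1:8), n, replace = TRUE)
  region_eff <- stats::setNames(stats::rnorm(8, 0, 0.1), paste0("R", 1:8))

  eta <- stats::qlogis(config$baseline_risk) +
    log(config$hom_or) * hom_indicator +
    0.1 * (sex == "male") + 0.01 * (age - 55) + region_eff[region]
  case_status <- stats::rbinom(n, 1, stats::plogis(eta))

  trait <- stats::rnorm(n) + config$quant_effect_sd * hom_indicator +
    0.2 * (sex == "male") - 0.005 * (age - 55) + region_eff[region]

  data.frame(id = if (!is.null(names(hom_indicator))) names(hom_indicator)
                  else sprintf("I%06d", seq_len(n)),
             case_status = case_status, trait = trait, sex = sex,
             age = age, region = region, stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Genealogy + gene drop + chip-typing mask + phenotypes, bundled with
#' ground truth.
#'
#' @param config A `simulation_config`.
#' @return List: `ped`, `gs`, `truth`, `focal_id`, `phenotypes`,
#'   `typed_ids` (chip-typed subset), `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  ped <- simulate_genealogy(config)
  gd <- gene_drop(ped, config)
  set.seed(.child_seed(config, 4L))
  typed <- ped$id[stats::runif(nrow(ped)) < config$chip_typed_fraction]
  hom <- as.integer(gd$gs$genotypes[gd$focal_id, ] == 2L)
  names(hom) <- ped$id
  phen <- simulate_phenotypes(hom, config, sex = ped$sex)
  list(ped = ped, gs = gd$gs, truth = gd$truth, focal_id = gd$focal_id,
       phenotypes = phen, typed_ids = typed, config = config)
}

#' Simulate paired flow-cytometry event sets with a known stimulation index
#'
#' Unstimulated events are lognormal; stimulated events are lognormal
#' with the log-mean shifted by `log(si_true)`, so the true
#' geometric-mean ratio equals `si_true` exactly.
#'
#' @param si_true Target stimulation index (> 0).
#' @param n_events Events per condition.
#' @param seed Seed.
#' @param meanlog,sdlog Lognormal parameters of the unstimulated
#'   distribution.
#' @return List with `stim` and `unstim` intensity vectors.
#' @export
simulate_flow_events <- function(si_true, n_events = 10000, seed = 1L,
                                 meanlog = log(100), sdlog = 0.3) {
  if (si_true <= 0) stop("si_true must be positive")
  set.seed(seed)
  list(unstim = stats::rlnorm(n_events, meanlog, sdlog),
       stim = stats::rlnorm(n_events, meanlog + log(si_true), sdlog))
}

#' Build the packaged proband-family fixture
#'
#' Writes a deterministic 7-member nuclear-family bundle (VCF + PED +
#' frequency TSV) emulating the canonical discovery configuration: two
#' affected brothers homozygous for a rare stop-gained allele (MAF
#' 0.76%), heterozygous parents, two heterozygous unaffected siblings and
#' one non-carrier sibling. The bundle also carries a second qualifying
#' homozygous missense genotype (MAF 0.33%), a known recessive
#' missense site absent from the affected brothers (MAF 0.58%), and
#' decoys: a homozygous site above the 2% MAF threshold, a common
#' heterozygous site, a homozygous site also homozygous in an unaffected
#' sibling (segregation failure), and an in-cis heterozygous pair.
#' Running [filter_recessive()] on the bundle yields exactly two
#' candidates.
#'
#' @param dir Output directory (created if needed).
#' @return List of written paths: `vcf`, `ped`, `freq`.
#' @export
build_proband_family_fixture <- function(dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- c("A", "B", "father", "mother", "sib1", "sib2", "sib3")
  ped <- new_pedigree(data.frame(
    id = ids,
    father = c("father", "father", NA, NA, "father", "father", "father"),
    mother = c("mother", "mother", NA, NA, "mother", "mother", "mother"),
    sex = c("male", "male", "male", "female", "female", "male", "female"),
    affected = c("affected", "affected", "unaffected", "unaffected",
                 "unaffected", "unaffected", "unaffected"),
    genotyped = TRUE, stringsAsFactors = FALSE))

  v <- function(chrom, pos, ref, alt, gene, csq, hgvs, g) {
    list(var = data.frame(variant_id = .variant_id(chrom, pos, ref, alt),
                          chrom = chrom, pos = pos, ref = ref, alt = alt,
                          gene = gene, consequence = csq, hgvs_p = hgvs,
                          stringsAsFactors = FALSE),
         g = g)
  }
  #                         A  B  fa mo s1 s2 s3
  sites <- list(
    v("chr17", 82449249L, "C", "G", "FOCAL1", "stop_gained", "p.Tyr2Ter",
      c(2, 2, 1, 1, 1, 1, 0)),                       # qualifying, high impact
    v("chr17", 81811277L, "G", "A", "RCPT1", "missense_variant", "p.Ser150Asn",
      c(2, 2, 1, 1, 1, 0, 1)),                       # qualifying, moderate
    v("chr16", 88643289L, "C", "T", "OXSUB1", "missense_variant", "p.Arg90Trp",
      c(0, 0, 0, 1, 0, 1, 0)),                       # absent from affecteds
    v("chr2", 5000000L, "A", "G", "DECOYC", "missense_variant", "",
      c(2, 2, 1, 1, 1, 1, 1)),                       # MAF above threshold
    v("chr3", 6000000L, "T", "C", "DECOYH", "missense_variant", "",
      c(1, 1, 1, 1, 1, 1, 1)),                       # common het
    v("chr4", 7000000L, "G", "T", "DECOYS", "missense_variant", "",
      c(2, 2, 1, 1, 1, 2, 1)),                       # fails segregation (sib2 hom)
    v("chr5", 8000001L, "C", "A", "DECOYP", "missense_variant", "",
      c(1, 1, 1, 0, 0, 0, 0)),                       # in-cis pair (father only)
    v("chr5", 8000900L, "G", "C", "DECOYP", "missense_variant", "",
      c(1, 1, 1, 0, 0, 0, 0)))
  variants <- do.call(rbind, lapply(sites, `[[`, "var"))
  genotypes <- do.call(rbind, lapply(sites, function(s) as.integer(s$g)))
  rownames(genotypes) <- variants$variant_id
  colnames(genotypes) <- ids
  gs <- list(variants = variants, genotypes = genotypes, samples = ids)

  freq <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt,
    maf_internal = c(0.0076, 0.0033, 0.0058, 0.025, 0.20, 0.01,
                     0.005, 0.005),
    maf_external = c(NA, 0.003, 0.005, 0.03, 0.21, 0.009, 0.004, 0.004))

  paths <- list(vcf = file.path(dir, "family.vcf"),
                ped = file.path(dir, "family.ped"),
                freq = file.path(dir, "family_freqs.tsv"))
  write_vcf_genotypes(gs, paths$vcf)
  write_pedigree(ped, paths$ped)
  utils::write.table(freq, paths$freq, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  paths
}
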