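# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Brute-force compound-het phasing oracle: enumerate every phased
# parental diplotype pair consistent with the genotype counts and every
# transmission, keep outcomes producing a double-het child, and report
# whether the child's two alternate alleles land in trans, in cis, or
# either. NA parental counts enumerate all genotypes.
oracle_phase <- function(father, mother) {
  diplotypes <- function(g1, g2) {
    g1s <- if (is.na(g1)) 0:2 else g1
    g2s <- if (is.na(g2)) 0:2 else g2
    out <- list()
    for (a in g1s) for (b in g2s) {
      # haplotype pairs (h1, h2), each h = c(allele at site1, site2),
      # consistent with counts a (site1) and b (site2)
      s1 <- switch(as.character(a), "0" = list(c(0, 0)), "1" = list(c(0, 1), c(1, 0)),
                   "2" = list(c(1, 1)))
      s2 <- switch(as.character(b), "0" = list(c(0, 0)), "1" = list(c(0, 1), c(1, 0)),
                   "2" = list(c(1, 1)))
      for (x in s1) for (y in s2)
        out[[length(out) + 1L]] <- rbind(h1 = c(x[1], y[1]), h2 = c(x[2], y[2]))
    }
    out
  }
  outcomes <- character(0)
  for (fd in diplotypes(father[1], father[2]))
    for (md in diplotypes(mother[1], mother[2]))
      for (ft in 1:2) for (mt in 1:2) {
        hf <- fd[ft, ]; hm <- md[mt, ]
        child <- hf + hm
        if (!all(child == 1L)) next
        outcomes <- c(outcomes,
                      if (all(hf == c(1, 0)) || all(hf == c(0, 1))) "trans"
                      else "cis")
      }
  outcomes <- unique(outcomes)
  if (length(outcomes) == 1L && outcomes == "trans") "in_trans"
  else if (length(outcomes) == 1L && outcomes == "cis") "in_cis"
  else "ambiguous"
}

# Exhaustive posterior dosage oracle for tiny pedigrees: enumerate
# founder genotypes under HWE priors and all Mendelian transmissions,
# condition on the typed observations, and return posterior expected
# allele counts.
oracle_posterior_dosage <- function(ped, observed, p) {
  ids <- ped$id
  n <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  depth_ord <- order(founderseek::pedigree_depth(ped))
  founders <- which(is.na(fa))
  nonf <- setdiff(depth_ord, founders)
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)

  post <- rep(0, n); z <- 0
  enum <- function(level, geno, prob) {
    if (level > length(nonf)) {
      ok <- all(is.na(observed[ids]) | observed[ids] == geno)
      if (ok) { post <<- post + prob * geno; z <<- z + prob }
      return(invisible(NULL))
    }
    i <- nonf[level]
    gf <- geno[fa[i]]; gm <- geno[mo[i]]
    # transmission distribution of one allele from a parent with count g
    tr <- function(g) c(`0` = 1 - g / 2, `1` = g / 2)
    pf <- tr(gf); pm <- tr(gm)
    for (af in 0:1) for (am in 0:1) {
      pr <- pf[af + 1] * pm[am + 1]
      if (pr == 0) next
      geno[i] <- af + am
      enum(level + 1L, geno, prob * pr)
    }
  }
  enum_founders <- function(k, geno, prob) {
    if (k > length(founders)) return(enum(1L, geno, prob))
    i <- founders[k]
    for (g in 0:2) {
      geno[i] <- g
      enum_founders(k + 1L, geno, prob * hwe[g + 1])
    }
  }
  enum_founders(1L, rep(NA_integer_, n), 1)
  stats::setNames(post / z, ids)
}

# Small helper: a validated nuclear family pedigree
make_trio <- function(ids = c("fa", "mo", "ch"),
                      affected = c("unaffected", "unaffected", "affected")) {
  new_pedigree(data.frame(
    id = ids,
    father = c(NA, NA, ids[1]),
    mother = c(NA, NA, ids[2]),
    sex = c("male", "female", "male"),
    affected = affected,
    stringsAsFactors = FALSE))
}

# genotype set from a bare matrix (rows = variants) for filter tests
make_gs <- function(genotypes, chrom = "chr1", gene = "G1",
                    consequence = "missense_variant") {
  k <- nrow(genotypes)
  variants <- data.frame(
    chrom = rep(chrom, length.out = k),
    pos = seq(1000L, by = 1000L, length.out = k),
    ref = "A", alt = "T",
    gene = rep(gene, length.out = k),
    consequence = rep(consequence, length.out = k),
    hgvs_p = "", stringsAsFactors = FALSE)
  variants$variant_id <- paste(variants$chrom, variants$pos,
                               variants$ref, variants$alt, sep = ":")
  rownames(genotypes) <- variants$variant_id
  list(variants = variants, genotypes = genotypes,
       samples = colnames(genotypes))
}

make_freqs <- function(gs, maf_internal, maf_external = maf_internal) {
  data.frame(chrom = gs$variants$chrom, pos = gs$variants$pos,
             ref = gs$variants$ref, alt = gs$variants$alt,
             maf_internal = maf_internal, maf_external = maf_external,
             variant_id = gs$variants$variant_id,
             stringsAsFactors = FALSE)
}
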