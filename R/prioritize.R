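# Rare-genotype prioritization: impact classes, MAF computation, dominant
# and recessive (homozygous + compound-heterozygous) candidate selection,
# trio phasing and family segregation checks.

# Consequence vocabulary -> impact class. Every term maps to exactly one
# class; unrecognised terms (and "unknown") fall through to "remaining".
.impact_map <- list(
  high = c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
           "splice_donor_variant", "stop_lost", "start_lost",
           "transcript_ablation"),
  moderate = c("missense_variant", "splice_region_variant",
               "inframe_insertion", "inframe_deletion",
               "protein_altering_variant"),
  low = c("synonymous_variant", "stop_retained_variant",
          "5_prime_UTR_variant", "3_prime_UTR_variant",
          "upstream_gene_variant", "downstream_gene_variant"),
  dhs = c("dhs_variant", "regulatory_region_variant", "TF_binding_site_variant")
)

#' Classify a consequence term into an impact class
#'
#' Maps a controlled-vocabulary consequence term to one of five impact
#' classes used for class-weighted significance thresholds: `high`
#' (stop-gained, frameshift, splice acceptor/donor and similar
#' loss-of-function terms), `moderate` (missense, splice-region, in-frame
#' indels), `low` (synonymous, UTR, near-gene), `dhs` (DNase
#' hypersensitivity / regulatory), and `remaining` for everything else.
#' Total function: unknown terms classify as `remaining`.
#'
#' @param consequence Character vector of consequence terms.
#' @return Character vector of class labels.
#' @export
classify_impact <- function(consequence) {
  vapply(consequence, function(term) {
    for (cls in names(.impact_map))
      if (term %in% .impact_map[[cls]]) return(cls)
    "remaining"
  }, character(1), USE.NAMES = FALSE)
}

#' Minor allele frequency from genotype calls
#'
#' Alternate-allele count over called alleles, folded to the minor allele
#' (result \eqn{\le 0.5}; at exactly 0.5 the alternate allele is treated
#' as minor). On the X chromosome males contribute one allele.
#'
#' @param counts Integer vector of per-individual alternate-allele counts
#'   (0/1/2, NA = missing).
#' @param ploidy Integer vector of called alleles per individual
#'   (default 2; use 1 for males on X).
#' @return Minor allele frequency in `[0, 0.5]`.
#' @export
compute_maf <- function(counts, ploidy = rep(2L, length(counts))) {
  keep <- !is.na(counts)
  total <- sum(ploidy[keep])
  if (total == 0L) stop("no called alleles: frequency undefined")
  f <- sum(counts[keep]) / total
  min(f, 1 - f)
}

.candidate <- function(model, variants, gene, carrier_ids, phase,
                       maf_internal, maf_external, chrom, pos,
                       consequence) {
  structure(list(model = model, variants = variants, gene = gene,
                 carrier_ids = carrier_ids, phase = phase,
                 maf_internal = maf_internal, maf_external = maf_external,
                 chrom = chrom, pos = pos, consequence = consequence),
            class = "candidate_genotype")
}

#' @export
format.candidate_genotype <- function(x, ...) {
  paste0("[", x$model, "] ", x$gene, " ", paste(x$variants, collapse = " + "),
         " (", paste(x$consequence, collapse = ","), "; phase=", x$phase, ")")
}

#' @export
print.candidate_genotype <- function(x, ...) cat(format(x), "\n")

# MAF-threshold clause shared by both filters: internal MAF below the
# threshold AND (external below threshold OR absent -- absence from the
# external database is evidence of rarity, not of failure).
.maf_passes <- function(freqs, vid, threshold) {
  row <- match(vid, freqs$variant_id)
  if (is.na(row)) return(FALSE)
  int_ok <- !is.na(freqs$maf_internal[row]) && freqs$maf_internal[row] < threshold
  ext <- freqs$maf_external[row]
  ext_ok <- is.na(ext) || ext < threshold
  int_ok && ext_ok
}

.freq_at <- function(freqs, vid, col) {
  row <- match(vid, freqs$variant_id)
  if (is.na(row)) NA_real_ else freqs[[col]][row]
}

.affected_ids <- function(ped) ped$id[ped$affected == "affected"]
.unaffected_ids <- function(ped) ped$id[ped$affected == "unaffected"]

.is_male_x <- function(ped, id, chrom, x_chrom) {
  chrom == x_chrom && ped$sex[match(id, ped$id)] == "male"
}

#' Dominant-model rare-variant filter
#'
#' Retains variants heterozygous in every affected individual, with
#' minor allele frequency below `threshold` in the internal reference and
#' (where present) the external database, and absent from both unaffected
#' parents. A missing genotype in an affected individual excludes the
#' variant (conservative).
#'
#' @param ped A `pedigree` containing the family.
#' @param gs A genotype set over the family.
#' @param freqs Frequency table from [read_frequency_table()].
#' @param threshold MAF threshold (default 0.0005 = 0.05%).
#' @return List of `candidate_genotype` objects.
#' @export
filter_dominant <- function(ped, gs, freqs, threshold = 0.0005) {
  aff <- .affected_ids(ped)
  if (!length(aff)) stop("no affected individuals in pedigree")
  parents <- unique(stats::na.omit(c(ped$father[match(aff, ped$id)],
                                     ped$mother[match(aff, ped$id)])))
  unaff_parents <- intersect(parents, .unaffected_ids(ped))
  out <- list()
  for (i in seq_len(nrow(gs$variants))) {
    vid <- gs$variants$variant_id[i]
    g <- gs$genotypes[vid, ]
    if (any(is.na(g[aff])) || !all(g[aff] == 1L)) next
    if (length(unaff_parents) && any(g[unaff_parents] >= 1L, na.rm = TRUE)) next
    if (!.maf_passes(freqs, vid, threshold)) next
    cand <- .candidate("dominant", vid, gs$variants$gene[i], aff,
                       "not_applicable",
                       .freq_at(freqs, vid, "maf_internal"),
                       .freq_at(freqs, vid, "maf_external"),
                       gs$variants$chrom[i], gs$variants$pos[i],
                       gs$variants$consequence[i])
    out[[length(out) + 1L]] <- cand
  }
  out
}

#' Recessive-model rare-genotype filter
#'
#' Retains (a) variants homozygous (hemizygous for males on X) in every
#' affected individual with MAF below `threshold` in both the internal
#' reference and, where present, the external database; and (b) gene-level
#' pairs of heterozygous variants (potential compound heterozygotes), each
#' below the threshold, carried by every affected individual. Pairs are
#' phased by parental transmission ([phase_compound_het()]); pairs forced
#' in cis are dropped, unphaseable pairs are retained with
#' `phase = "ambiguous"`. Candidates failing the family segregation check
#' are dropped.
#'
#' @inheritParams filter_dominant
#' @param threshold MAF threshold (default 0.02 = 2%).
#' @param x_chrom X chromosome label for hemizygous handling.
#' @return List of `candidate_genotype` objects.
#' @export
filter_recessive <- function(ped, gs, freqs, threshold = 0.02,
                             x_chrom = "chrX") {
  aff <- .affected_ids(ped)
  if (!length(aff)) stop("no affected individuals in pedigree")
  out <- list()

  hom_in <- function(vid, id) {
    g <- gs$genotypes[vid, id]
    if (is.na(g)) return(NA)
    chrom <- gs$variants$chrom[match(vid, gs$variants$variant_id)]
    if (.is_male_x(ped, id, chrom, x_chrom)) g == 1L else g == 2L
  }

  # (a) homozygous recessive
  for (i in seq_len(nrow(gs$variants))) {
    vid <- gs$variants$variant_id[i]
    hom <- vapply(aff, hom_in, logical(1), vid = vid)
    if (any(is.na(hom)) || !all(hom)) next
    if (!.maf_passes(freqs, vid, threshold)) next
    chrom <- gs$variants$chrom[i]
    model <- if (chrom == x_chrom) "x_linked" else "recessive_hom"
    cand <- .candidate(model, vid, gs$variants$gene[i], aff,
                       "not_applicable",
                       .freq_at(freqs, vid, "maf_internal"),
                       .freq_at(freqs, vid, "maf_external"),
                       chrom, gs$variants$pos[i],
                       gs$variants$consequence[i])
    if (check_segregation(cand, ped, gs, x_chrom = x_chrom)$pass)
      out[[length(out) + 1L]] <- cand
  }

  # (b) compound heterozygotes: gene-level trans pairs of rare hets.
  genes <- unique(gs$variants$gene[gs$variants$gene != ""])
  for (gn in genes) {
    vids <- gs$variants$variant_id[gs$variants$gene == gn]
    if (length(vids) < 2L) next
    rare <- vids[vapply(vids, .maf_passes, logical(1), freqs = freqs,
                        threshold = threshold)]
    if (length(rare) < 2L) next
    pairs <- utils::combn(rare, 2L, simplify = FALSE)
    for (pr in pairs) {
      het_all <- vapply(aff, function(id) {
        g <- gs$genotypes[pr, id]
        !anyNA(g) && all(g == 1L)
      }, logical(1))
      if (!all(het_all)) next
      phases <- vapply(aff, function(id) {
        fa <- ped$father[match(id, ped$id)]
        mo <- ped$mother[match(id, ped$id)]
        fg <- if (!is.na(fa) && fa %in% gs$samples) gs$genotypes[pr, fa] else c(NA, NA)
        mg <- if (!is.na(mo) && mo %in% gs$samples) gs$genotypes[pr, mo] else c(NA, NA)
        phase_compound_het(gs$genotypes[pr, id], fg, mg)
      }, character(1))
      phase <- if (any(phases == "in_cis")) "in_cis"
               else if (all(phases == "in_trans")) "in_trans"
               else "ambiguous"
      if (phase == "in_cis") next
      i1 <- match(pr[1], gs$variants$variant_id)
      cand <- .candidate("recessive_comphet", pr, gn, aff, phase,
                         c(.freq_at(freqs, pr[1], "maf_internal"),
                           .freq_at(freqs, pr[2], "maf_internal")),
                         c(.freq_at(freqs, pr[1], "maf_external"),
                           .freq_at(freqs, pr[2], "maf_external")),
                         gs$variants$chrom[c(i1, match(pr[2], gs$variants$variant_id))],
                         gs$variants$pos[c(i1, match(pr[2], gs$variants$variant_id))],
                         gs$variants$consequence[c(i1, match(pr[2], gs$variants$variant_id))])
      if (check_segregation(cand, ped, gs, x_chrom = x_chrom)$pass)
        out[[length(out) + 1L]] <- cand
    }
  }
  out
}

#' Phase a candidate compound-heterozygous pair by parental transmission
#'
#' Given a child heterozygous at two sites in one gene and the parental
#' genotypes, enumerates the four possible assignments of the two
#' alternate alleles to parental origins and reports `in_trans` if every
#' consistent assignment places them on opposite parental haplotypes,
#' `in_cis` if every consistent assignment places them on the same, and
#' `ambiguous` otherwise (including missing parental genotypes).
#'
#' @param child Integer vector length 2: child's allele counts at the two
#'   sites (must both be 1).
#' @param father,mother Integer vectors length 2 of parental counts
#'   (NA = missing).
#' @return `"in_trans"`, `"in_cis"` or `"ambiguous"`.
#' @export
phase_compound_het <- function(child, father, mother) {
  if (length(child) != 2L || anyNA(child) || !all(child == 1L))
    stop("child must be heterozygous at both sites")
  # can parent P have donated allele a (0 = ref, 1 = alt) at a site where
  # its count is g?  alt requires g >= 1; ref requires g <= 1; NA allows both.
  can_donate <- function(g, a) is.na(g) || (if (a == 1L) g >= 1L else g <= 1L)
  consistent <- logical(0)
  # config: which parent donates the alt at site 1 / site 2 (TRUE = father)
  for (alt1_pat in c(TRUE, FALSE)) for (alt2_pat in c(TRUE, FALSE)) {
    ok <- can_donate(father[1], as.integer(alt1_pat)) &&
          can_donate(mother[1], as.integer(!alt1_pat)) &&
          can_donate(father[2], as.integer(alt2_pat)) &&
          can_donate(mother[2], as.integer(!alt2_pat))
    if (ok) consistent <- c(consistent, alt1_pat == alt2_pat)
  }
  if (!length(consistent)) return("ambiguous")  # Mendelian conflict; unphaseable
  if (all(consistent)) "in_cis"
  else if (all(!consistent)) "in_trans"
  else "ambiguous"
}

#' Family segregation check for a candidate genotype
#'
#' A recessive candidate fails if any unaffected family member carries the
#' full genotype: homozygous (hemizygous on X) for a single-variant
#' candidate, or both variants of a compound-het pair demonstrably in
#' trans (phased through that member's own parents; members whose phase
#' is ambiguous or in cis cannot be shown to carry the recessive genotype
#' and do not fail the check). A dominant candidate fails if any
#' unaffected member carries the variant at all.
#'
#' @param candidate A `candidate_genotype`.
#' @param ped The family `pedigree`.
#' @param gs Genotype set over the family.
#' @param x_chrom X chromosome label.
#' @return List with `pass` (logical) and `reason` (character).
#' @export
check_segregation <- function(candidate, ped, gs, x_chrom = "chrX") {
  unaff <- intersect(.unaffected_ids(ped), gs$samples)
  for (id in unaff) {
    g <- gs$genotypes[candidate$variants, id]
    carries_full <- switch(candidate$model,
      dominant = any(g >= 1L, na.rm = TRUE),
      recessive_comphet = {
        if (anyNA(g) || !all(g == 1L)) {
          !anyNA(g) && all(g >= 1L) && any(g == 2L)
        } else {
          fa <- ped$father[match(id, ped$id)]
          mo <- ped$mother[match(id, ped$id)]
          fg <- if (!is.na(fa) && fa %in% gs$samples)
            gs$genotypes[candidate$variants, fa] else c(NA, NA)
          mg <- if (!is.na(mo) && mo %in% gs$samples)
            gs$genotypes[candidate$variants, mo] else c(NA, NA)
          phase_compound_het(g, fg, mg) == "in_trans"
        }
      },
      { # recessive_hom / x_linked
        hemi <- .is_male_x(ped, id, candidate$chrom[1], x_chrom)
        !is.na(g) && g >= (if (hemi) 1L else 2L)
      })
    if (isTRUE(carries_full))
      return(list(pass = FALSE,
                  reason = paste0("unaffected carrier of full genotype: ", id)))
  }
  list(pass = TRUE, reason = "segregates with affection status")
}
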