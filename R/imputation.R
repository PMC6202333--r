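# Genealogical genotype imputation. A single biallelic site is phased by
# Mendelian transmission through the pedigree; haplotypes whose value is
# forced by typed relatives along a transmission chain are assigned, and
# unresolved haplotypes contribute the population expectation p, so the
# per-individual dosage is a calibrated expected minor-allele count.
#
# Internal representation: one transmission allele t(parent -> child) per
# parent-child edge, values 0/1/NA. An individual's received haplotypes
# are the transmissions from its father and mother (founder haplotypes
# stay NA unless typing forces them).

#' Phase one variant by Mendelian transmission
#'
#' Assigns the parental origin of alleles wherever transmission logic
#' forces it: homozygous individuals resolve both haplotypes, and a
#' heterozygote resolves when one parent is homozygous. Sites with a
#' Mendelian inconsistency between a typed child and a typed parent are
#' flagged.
#'
#' @param ped A `pedigree`.
#' @param counts Named integer vector of allele counts (NA = untyped),
#'   names matching pedigree ids.
#' @return List with `haplotypes` (data.frame id, paternal_allele,
#'   maternal_allele with NA = unknown) and `mendelian_errors`
#'   (character vector of offending child ids).
#' @export
phase_by_transmission <- function(ped, counts) {
  st <- .transmission_fixpoint(ped, counts)
  hap <- data.frame(id = ped$id,
                    paternal_allele = st$pat,
                    maternal_allele = st$mat,
                    stringsAsFactors = FALSE)
  list(haplotypes = hap, mendelian_errors = st$errors)
}

# Fixed-point propagation of forced haplotype values through the pedigree.
.transmission_fixpoint <- function(ped, counts) {
  n <- nrow(ped)
  if (n == 0L) stop("empty pedigree")
  ids <- ped$id
  counts <- counts[ids]
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)
  pat <- rep(NA_integer_, n)  # allele received from father
  mat <- rep(NA_integer_, n)  # allele received from mother
  errors <- character(0)

  # Mendelian consistency between typed child and typed parents
  for (i in seq_len(n)) {
    g <- counts[i]
    if (is.na(g)) next
    for (p in c(fa[i], mo[i])) {
      if (is.na(p) || is.na(counts[p])) next
      gp <- counts[p]
      bad <- (g == 2L && gp == 0L) || (g == 0L && gp == 2L)
      if (bad) errors <- c(errors, ids[i])
    }
    if (g == 1L && !is.na(fa[i]) && !is.na(mo[i]) &&
        !is.na(counts[fa[i]]) && !is.na(counts[mo[i]]) &&
        counts[fa[i]] == counts[mo[i]] &&
        counts[fa[i]] %in% c(0L, 2L))
      errors <- c(errors, ids[i])
  }
  if (length(errors))
    return(list(pat = rep(NA_integer_, n), mat = rep(NA_integer_, n),
                errors = unique(errors)))

  # typed homozygotes resolve both received haplotypes up front
  hom <- !is.na(counts) & counts %in% c(0L, 2L)
  pat[hom] <- counts[hom] %/% 2L
  mat[hom] <- counts[hom] %/% 2L
  het <- !is.na(counts) & counts == 1L

  repeat {
    before <- sum(is.na(pat)) + sum(is.na(mat))
    # typed het: one known haplotype determines the other
    idx <- het & !is.na(pat) & is.na(mat)
    mat[idx] <- 1L - pat[idx]
    idx <- het & !is.na(mat) & is.na(pat)
    pat[idx] <- 1L - mat[idx]
    # parent -> child: a parent whose two haplotypes are equal transmits
    # that value (homozygous-typed parents are covered by resolution)
    pv <- ifelse(!is.na(pat) & !is.na(mat) & pat == mat, pat, NA_integer_)
    idx <- is.na(pat) & !is.na(fa) & !is.na(pv[ifelse(is.na(fa), 1L, fa)])
    pat[idx] <- pv[fa[idx]]
    idx <- is.na(mat) & !is.na(mo) & !is.na(pv[ifelse(is.na(mo), 1L, mo)])
    mat[idx] <- pv[mo[idx]]
    if (sum(is.na(pat)) + sum(is.na(mat)) == before) break
  }
  list(pat = pat, mat = mat, errors = errors)
}

#' Impute untyped individuals through the pedigree
#'
#' For each untyped individual, haplotypes forced by transmission chains
#' from typed relatives are assigned their allele; in addition, an
#' untyped individual whose typed child demonstrably received a minor
#' allele from them (because the other parent cannot have donated it)
#' has one haplotype resolved to carry it. Unresolved haplotypes
#' contribute their conditional expectation: half the parent's expected
#' dosage when the parent is known (fair segregation), and the
#' population frequency `p` for founder haplotypes. The expected count
#' is the sum of the two per-haplotype expectations, so dosages are
#' calibrated. Typed individuals keep their observed counts.
#'
#' @param ped A `pedigree`.
#' @param counts Named integer allele-count vector (NA = untyped).
#' @param p Minor allele frequency of the variant, in (0, 1).
#' @return A dosage data.frame (`dosage_vector`): columns `id`,
#'   `theta_hat`, `h1`, `h2` (per-haplotype expectations), `typed`;
#'   attribute `p` carries the allele frequency; attribute
#'   `mendelian_errors` any inconsistent child ids (in which case
#'   phasing information is not used).
#' @export
impute_untyped <- function(ped, counts, p) {
  if (nrow(ped) == 0L) stop("empty pedigree")
  if (!any(!is.na(counts[ped$id]))) stop("no typed individuals")
  st <- .transmission_fixpoint(ped, counts)
  ids <- ped$id
  counts <- counts[ids]
  n <- length(ids)
  fa <- match(ped$father, ids)
  mo <- match(ped$mother, ids)

  # child -> untyped parent: if the child's haplotype received from this
  # parent is resolved, the parent carries that allele on one haplotype.
  # Distinct forced values fill unresolved slots (one slot per value; two
  # children forcing the same value are conservatively attributed to the
  # same parental haplotype).
  if (!length(st$errors)) {
    # parents for whom some child's received haplotype resolved to 0 / 1
    donors <- function(val) unique(c(
      fa[!is.na(fa) & !is.na(st$pat) & st$pat == val],
      mo[!is.na(mo) & !is.na(st$mat) & st$mat == val]))
    has0 <- has1 <- logical(n)
    has0[donors(0L)] <- TRUE; has1[donors(1L)] <- TRUE
    untyped_idx <- which(is.na(counts))
    for (i in untyped_idx) {
      forced <- c(if (has0[i]) 0L, if (has1[i]) 1L)
      known <- c(if (!is.na(st$pat[i])) st$pat[i], if (!is.na(st$mat[i])) st$mat[i])
      extra <- setdiff(forced, known)
      for (val in extra) {
        if (is.na(st$pat[i])) st$pat[i] <- val
        else if (is.na(st$mat[i])) st$mat[i] <- val
      }
    }
  }

  # Per-haplotype expectations, top-down in pedigree depth order: a
  # forced haplotype keeps its allele; an unresolved haplotype received
  # from a known parent takes that parent's expected transmitted allele
  # (half its dosage expectation, by fair segregation); an unresolved
  # founder haplotype takes the population frequency p.
  h1 <- rep(NA_real_, n); h2 <- rep(NA_real_, n)
  ord <- order(pedigree_depth(ped))
  for (i in ord) {
    h1[i] <- if (!is.na(st$pat[i])) as.numeric(st$pat[i])
             else if (!is.na(fa[i])) (h1[fa[i]] + h2[fa[i]]) / 2
             else p
    h2[i] <- if (!is.na(st$mat[i])) as.numeric(st$mat[i])
             else if (!is.na(mo[i])) (h1[mo[i]] + h2[mo[i]]) / 2
             else p
    # a typed heterozygote's haplotypes are one 0 and one 1 regardless
    # of phase resolution
    if (!is.na(counts[i]) && counts[i] == 1L) { h1[i] <- 0; h2[i] <- 1 }
  }

  typed <- !is.na(counts)
  theta <- h1 + h2
  # typed individuals keep observed counts exactly
  theta[typed] <- counts[typed]
  h1[typed & counts == 0L] <- 0; h2[typed & counts == 0L] <- 0
  h1[typed & counts == 2L] <- 1; h2[typed & counts == 2L] <- 1
  h1[typed & counts == 1L] <- 0; h2[typed & counts == 1L] <- 1

  out <- data.frame(id = ids, theta_hat = theta, h1 = h1, h2 = h2,
                    typed = typed, stringsAsFactors = FALSE)
  attr(out, "p") <- p
  attr(out, "mendelian_errors") <- st$errors
  class(out) <- c("dosage_vector", "data.frame")
  out
}

#' Imputation informativeness (variance-ratio information score)
#'
#' Ratio of the variance of per-haplotype imputed allele expectations to
#' the binomial haplotype variance `p(1-p)`: 0 when the imputation is
#' completely uninformative (the same value is always imputed), about 1
#' when fully informative, and asymptotically the squared correlation
#' between imputed and true allele counts in between. When haplotype
#' resolution is unavailable (a bare dosage vector), per-haplotype
#' expectations fall back to `theta_hat / 2`.
#'
#' @param dosages A `dosage_vector` from [impute_untyped()], or a numeric
#'   vector of expected counts (then `p` must be given).
#' @param p Allele frequency; taken from the dosage attribute when absent.
#' @return Information score (non-negative; may marginally exceed 1 from
#'   sampling noise).
#' @export
imputation_information <- function(dosages, p = NULL) {
  if (inherits(dosages, "dosage_vector")) {
    if (is.null(p)) p <- attr(dosages, "p")
    h <- c(dosages$h1, dosages$h2)
  } else {
    if (is.null(p)) stop("p must be supplied for a bare dosage vector")
    h <- rep(dosages / 2, 2L)
  }
  if (length(h) < 4L) stop("need at least 2 individuals")
  if (is.null(p) || p <= 0 || p >= 1)
    stop("information undefined for p outside (0, 1)")
  m <- length(h)
  v_obs <- sum((h - mean(h))^2) / m   # observed variance of imputations
  v_obs / (p * (1 - p))
}
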