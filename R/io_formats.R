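# Coordinate convention: 1-based inclusive throughout (VCF convention).
# Genotypes are integer alternate-allele counts 0/1/2 (0/1 for males on X),
# NA for missing. A "genotype set" is a list with components
#   variants:  data.frame(variant_id, chrom, pos, ref, alt, gene,
#                         consequence, hgvs_p)
#   genotypes: integer matrix, rows = variant_id, cols = sample id
#   samples:   character vector of sample ids (column order)

.variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF v4.x file into the package's genotype-set representation:
#' one biallelic record per (site, alternate allele), with diploid GT
#' fields mapped to integer alternate-allele counts and `./.` mapped to
#' `NA`. Functional consequence is read from a single INFO key (default
#' `CSQ_TERM`), falling back to `"unknown"` where absent; the gene symbol
#' comes from the `GENE` INFO key.
#'
#' Multi-allelic sites are decomposed into one record per alternate allele
#' by default. With `decompose = FALSE` a multi-allelic site raises an
#' error, because every downstream filter in this package operates per
#' alternate allele.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_subset Optional character vector of sample ids to retain.
#' @param consequence_key INFO key holding the consequence term.
#' @param gene_key INFO key holding the gene symbol.
#' @param decompose Decompose multi-allelic sites into biallelic records?
#' @param x_chrom Chromosome label treated as X (males carry 0/1 there).
#' @return A genotype set: list with `variants`, `genotypes`, `samples`.
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL,
                               consequence_key = "CSQ_TERM",
                               gene_key = "GENE",
                               decompose = TRUE,
                               x_chrom = "chrX") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(list(variants = .empty_variant_table(),
                genotypes = matrix(integer(0), 0, 0),
                samples = character(0)))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT genotype field: ", path)
  samples <- colnames(gt_raw)
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s))
      stop("samples not present in VCF: ", paste(missing_s, collapse = ", "))
    gt_raw <- gt_raw[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  csq <- .extract_info_key(vcf, consequence_key)
  gene <- .extract_info_key(vcf, gene_key)
  hgvs <- .extract_info_key(vcf, "HGVSP")

  out_var <- list(); out_gt <- list()
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1L && !decompose)
      stop("multi-allelic site at ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " (decomposition disabled)")
    for (k in seq_along(alts)) {
      counts <- vapply(gt_raw[i, ], .gt_to_count, integer(1), allele = k,
                       line = i)
      rec <- data.frame(
        variant_id = .variant_id(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k]),
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[k],
        gene = if (is.na(gene[i])) "" else gene[i],
        consequence = if (is.na(csq[i])) "unknown" else csq[i],
        hgvs_p = if (is.na(hgvs[i])) "" else hgvs[i],
        stringsAsFactors = FALSE)
      out_var[[length(out_var) + 1L]] <- rec
      out_gt[[length(out_gt) + 1L]] <- counts
    }
  }
  variants <- do.call(rbind, out_var)
  genotypes <- do.call(rbind, out_gt)
  rownames(genotypes) <- variants$variant_id
  colnames(genotypes) <- samples
  .validate_variants(variants)
  list(variants = variants, genotypes = genotypes, samples = samples)
}

.empty_variant_table <- function() {
  data.frame(variant_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             gene = character(0), consequence = character(0),
             hgvs_p = character(0), stringsAsFactors = FALSE)
}

.validate_variants <- function(variants) {
  if (any(variants$pos < 1L)) stop("variant position < 1")
  if (any(variants$ref == variants$alt)) stop("REF equals ALT for a variant")
  invisible(TRUE)
}

.extract_info_key <- function(vcf, key) {
  info <- vcf@fix[, "INFO"]
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

# Map one GT string to the count of alternate allele number `allele`.
.gt_to_count <- function(gt, allele, line) {
  if (is.na(gt)) return(NA_integer_)
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".")) return(NA_integer_)
  ial <- suppressWarnings(as.integer(al))
  if (anyNA(ial)) stop("malformed GT field '", gt, "' at VCF record ", line)
  sum(ial == allele)
}

#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited PLINK-style PED: family, id, father, mother, sex,
#' phenotype. Sex 1 = male, 2 = female, other = unknown; phenotype
#' 2 = affected, 1 = unaffected, 0 or -9 = unknown. `0` parent ids mean
#' founder. Structural invariants (acyclic parent graph, father male,
#' mother female, referenced parents present) are enforced.
#'
#' @param path Path to the PED file.
#' @return A `pedigree` object (data.frame with columns `id`, `father`,
#'   `mother`, `sex`, `affected`, `genotyped`).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  tab <- tryCatch(utils::read.table(path, header = FALSE,
                                    stringsAsFactors = FALSE,
                                    col.names = c("family", "id", "father",
                                                  "mother", "sex", "phenotype")),
                  error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) {
    warning("empty PED file: ", path)
    return(new_pedigree(data.frame(id = character(0), father = character(0),
                                   mother = character(0), sex = character(0),
                                   affected = character(0),
                                   genotyped = logical(0),
                                   stringsAsFactors = FALSE)))
  }
  ped <- data.frame(
    id = as.character(tab$id),
    father = ifelse(tab$father %in% c("0", 0), NA_character_, as.character(tab$father)),
    mother = ifelse(tab$mother %in% c("0", 0), NA_character_, as.character(tab$mother)),
    sex = c("male", "female")[match(tab$sex, 1:2)],
    affected = c("unaffected", "affected")[match(tab$phenotype, 1:2)],
    genotyped = TRUE,
    stringsAsFactors = FALSE)
  ped$sex[is.na(ped$sex)] <- "unknown"
  ped$affected[is.na(ped$affected)] <- "unknown"
  new_pedigree(ped)
}

#' Construct and validate a pedigree object
#'
#' @param df data.frame with columns `id`, `father`, `mother`, `sex`,
#'   `affected` and optionally `genotyped`, `birth_year`.
#' @return The validated data.frame with class `pedigree`.
#' @export
new_pedigree <- function(df) {
  stopifnot(all(c("id", "father", "mother", "sex", "affected") %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate individual ids in pedigree")
  if (!"genotyped" %in% names(df)) df$genotyped <- TRUE
  for (role in c("father", "mother")) {
    ref <- df[[role]]
    bad <- !is.na(ref) & !(ref %in% df$id)
    if (any(bad))
      stop("referenced ", role, " not in pedigree: ",
           paste(unique(ref[bad]), collapse = ", "))
    want <- if (role == "father") "male" else "female"
    present <- stats::na.omit(unique(ref))
    conflict <- present[df$sex[match(present, df$id)] != want &
                        df$sex[match(present, df$id)] != "unknown"]
    if (length(conflict))
      stop("individual listed as ", role, " but recorded with wrong sex: ",
           paste(conflict, collapse = ", "))
  }
  .check_acyclic(df)
  class(df) <- c("pedigree", "data.frame")
  df
}

# Vectorized founder-relative depth: iterate until every individual whose
# parents are resolved gets depth max(parent depths) + 1. Individuals that
# never resolve sit on a cycle of the parent graph.
.parent_depths <- function(df) {
  n <- nrow(df)
  depth <- rep(NA_integer_, n)
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  par_depth <- function(p) {
    out <- rep(-1L, n)
    ok <- !is.na(p)
    out[ok] <- depth[p[ok]]
    out
  }
  repeat {
    df_ <- par_depth(fa); dm_ <- par_depth(mo)
    ready <- is.na(depth) & !is.na(df_) & !is.na(dm_)
    if (!any(ready)) break
    depth[ready] <- pmax(df_[ready], dm_[ready]) + 1L
  }
  stats::setNames(depth, df$id)
}

# Acyclicity check via depth resolution; stops naming cycle members.
.check_acyclic <- function(df) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  depth <- .parent_depths(df)
  if (anyNA(depth)) {
    bad <- names(depth)[is.na(depth)]
    stop("pedigree cycle involving individual(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "individuals (",
      sum(x$affected == "affected"), "affected )\n")
  NextMethod()
}

#' Generation-sorted parent depth for each individual
#' @param ped A `pedigree`.
#' @return Integer vector of founder-relative depths, named by id.
#' @export
pedigree_depth <- function(ped) {
  .parent_depths(ped)
}

#' Write prioritized candidate genotypes to a TSV report
#'
#' Deterministic output: rows sorted by (chrom, pos, model) with a fixed
#' header, so identical candidate sets produce byte-identical files.
#'
#' @param candidates A candidate list as returned by [filter_recessive()]
#'   or [filter_dominant()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  header <- c("gene", "variants", "model", "maf_internal", "maf_external",
              "carriers", "phase")
  rows <- lapply(candidates, function(cd) {
    data.frame(
      gene = cd$gene,
      variants = paste(cd$variants, collapse = ","),
      model = cd$model,
      maf_internal = paste(signif(cd$maf_internal, 6), collapse = ","),
      maf_external = paste(ifelse(is.na(cd$maf_external), "NA",
                                  signif(cd$maf_external, 6)), collapse = ","),
      carriers = paste(cd$carrier_ids, collapse = ","),
      phase = cd$phase,
      chrom = cd$chrom[1], pos = cd$pos[1],
      stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(character(0), 0, 9)), c(header, "chrom", "pos"))
  if (nrow(tab)) tab <- tab[order(tab$chrom, as.integer(tab$pos), tab$model), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(tab))
    utils::write.table(tab[, header], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant frequency table
#'
#' TSV with columns chrom, pos, ref, alt, maf_internal, maf_external
#' (maf_external may be empty = absent from the external database).
#' Frequencies must already be minor-allele folded (\eqn{\le 0.5}).
#'
#' @param path Path to the TSV.
#' @return data.frame with an added `variant_id` key column.
#' @export
read_frequency_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "maf_internal", "maf_external")
  if (!all(need %in% names(tab)))
    stop("frequency table must have columns: ", paste(need, collapse = ", "))
  if (any(tab$maf_internal > 0.5 | tab$maf_internal < 0, na.rm = TRUE) ||
      any(tab$maf_external > 0.5 | tab$maf_external < 0, na.rm = TRUE))
    stop("frequencies must be minor-allele folded into [0, 0.5]")
  tab$variant_id <- .variant_id(tab$chrom, tab$pos, tab$ref, tab$alt)
  tab
}

#' Write a genotype set to a plain-text VCF v4.2 file
#'
#' Emits one biallelic record per variant with `GENE`, `CSQ_TERM` and
#' `HGVSP` INFO keys and unphased diploid GT fields (`./.` for missing).
#'
#' @param gs A genotype set (see [read_vcf_genotypes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gs, path) {
  v <- gs$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_TERM,Number=1,Type=String,Description=\"Consequence term\">",
    "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"Protein notation\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gs$samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gs$genotypes + 1L],
                   nrow = nrow(gs$genotypes))
  gt_str[is.na(gt_str)] <- "./."
  for (i in seq_len(nrow(v))) {
    info <- paste0("GENE=", ifelse(v$gene[i] == "", ".", v$gene[i]),
                   ";CSQ_TERM=", v$consequence[i],
                   ";HGVSP=", ifelse(v$hgvs_p[i] == "", ".", v$hgvs_p[i]))
    writeLines(paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i],
                       v$alt[i], ".", "PASS", info, "GT", gt_str[i, ]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a pedigree to a 6-column PED file
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @param family Family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  sex <- match(ped$sex, c("male", "female"))
  sex[is.na(sex)] <- 0L
  phe <- match(ped$affected, c("unaffected", "affected"))
  phe[is.na(phe)] <- 0L
  tab <- data.frame(family, ped$id,
                    ifelse(is.na(ped$father), "0", ped$father),
                    ifelse(is.na(ped$mother), "0", ped$mother),
                    sex, phe)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
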