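#' Read a PLINK-style PED/FAM pedigree file
#'
#' Expects at least six whitespace-separated columns: family ID, individual
#' ID, father ID, mother ID, sex, phenotype placeholder.  Parent IDs of `0`
#' mean "unknown".  Extra columns are ignored.
#'
#' @param path path to the PED/FAM file.
#' @return A validated [Pedigree].
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6L)
    stop("PED file must have at least 6 columns, found ", ncol(df))
  names(df)[1:6] <- c("fid", "iid", "father", "mother", "sex", "phen")
  Pedigree(df[, c("fid", "iid", "father", "mother", "sex")])
}

#' Read a long-format phenotype/covariate table
#'
#' Tab-separated with a header; required columns `iid`, `exam`, `trait`;
#' any further columns are treated as covariates (e.g. `age`, `sex`, `med`).
#' One row per individual and exam.
#'
#' @param path path to the TSV file.
#' @return A `PhenotypeTable` data frame.
#' @export
read_pheno <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  PhenotypeTable(df)
}

#' @rdname read_pheno
#' @param df data frame with columns `iid`, `exam`, `trait`, covariates.
#' @export
PhenotypeTable <- function(df) {
  need <- c("iid", "exam", "trait")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "))
  df$iid <- as.character(df$iid)
  df$exam <- as.integer(df$exam)
  if (anyDuplicated(df[, c("iid", "exam")]))
    stop("duplicated (iid, exam) rows in phenotype table")
  structure(df, class = c("PhenotypeTable", "data.frame"))
}

#' Read a per-variant functional-score table
#'
#' Tab-separated with a header and columns `variant_id`, `gene`,
#' `annotation` (e.g. `nonsynonymous` / `other`) and `score` in `[0, 1]`
#' (may be `NA`), as produced by annotation pipelines.
#'
#' @param path path to the TSV file.
#' @return A `FunctionalScoreTable` data frame.
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  FunctionalScoreTable(df)
}

#' @rdname read_scores
#' @param df data frame with columns `variant_id`, `gene`, `annotation`, `score`.
#' @export
FunctionalScoreTable <- function(df) {
  need <- c("variant_id", "gene", "annotation", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("score table is missing columns: ", paste(miss, collapse = ", "))
  df$variant_id <- as.character(df$variant_id)
  df$score <- as.numeric(df$score)
  bad <- !is.na(df$score) & (df$score < 0 | df$score > 1)
  if (any(bad))
    stop("functional scores outside [0, 1] for: ",
         paste(df$variant_id[bad], collapse = ", "))
  structure(df, class = c("FunctionalScoreTable", "data.frame"))
}

#' Genotype matrix with variant metadata
#'
#' `x` holds minor-allele counts (0/1/2, `NA` = missing) with one row per
#' individual (rownames = IDs) and one column per variant.  `variants` is a
#' data frame with columns `id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `annotation`, `flipped` and `maf` (founder minor-allele frequency,
#' always in `[0, 0.5]`).  `flipped` records variants whose VCF alt allele
#' was the major allele in founders, so the counts were recoded.
#'
#' @param x integer matrix of minor-allele counts.
#' @param variants variant metadata data frame.
#' @return A `GenotypeMatrix` object.
#' @export
GenotypeMatrix <- function(x, variants) {
  stopifnot(is.matrix(x), nrow(variants) == ncol(x))
  if (!all(x[!is.na(x)] %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA")
  for (col in c("gene", "annotation"))
    if (is.null(variants[[col]])) variants[[col]] <- NA_character_
  if (is.null(variants$flipped)) variants$flipped <- FALSE
  colnames(x) <- variants$id
  structure(list(x = x, variants = variants, samples = rownames(x)),
            class = "GenotypeMatrix")
}

#' @exportS3Method base::print
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d variants (founder MAF range %s)\n",
              nrow(x$x), ncol(x$x),
              paste(signif(range(x$variants$maf), 3), collapse = "-")))
  invisible(x)
}

#' Founder minor-allele frequency
#'
#' Recomputes, from the stored counts, each variant's allele frequency among
#' the founders of `ped` (the definition under which the minor allele was
#' chosen).
#'
#' @param geno a [GenotypeMatrix].
#' @param ped a [Pedigree].
#' @return Numeric vector of founder frequencies of the coded allele.
#' @export
founder_maf <- function(geno, ped) {
  fo <- intersect(founders(ped), rownames(geno$x))
  xf <- geno$x[fo, , drop = FALSE]
  colSums(xf, na.rm = TRUE) / (2 * colSums(!is.na(xf)))
}

# vectorized Mendelian consistency given parental and offspring dosages;
# NA anywhere -> NA (not checkable)
mendelian_consistent <- function(gf, gm, go) {
  lo <- (gf == 2L) + (gm == 2L)
  hi <- (gf >= 1L) + (gm >= 1L)
  go >= lo & go <= hi
}

#' Read an aligned family cohort from VCF + PED + phenotype files
#'
#' Reads genotypes (GT field only; biallelic records), pedigree and
#' phenotypes, aligns them by individual ID, recodes each variant so that
#' counts refer to the allele that is minor among *founders* (ties at 0.5
#' keep the VCF alt allele), and screens complete parent-offspring trios for
#' Mendelian inconsistencies.
#'
#' @param vcf_path,ped_path,pheno_path input file paths.
#' @param scores_path optional functional-score TSV.
#' @param mendel_action `"error"` (default) to fail when more than
#'   `mendel_max` inconsistent trio-variant pairs are found, or `"drop"` to
#'   set the offending offspring genotypes to missing.
#' @param mendel_max tolerated number of Mendelian-inconsistent
#'   trio-variant pairs before `mendel_action` applies (default 0).
#' @return An object of class `FbatvCohort`: a list with elements `ped`,
#'   `geno`, `pheno` and optionally `scores`.
#' @export
read_cohort <- function(vcf_path, ped_path, pheno_path, scores_path = NULL,
                        mendel_action = c("error", "drop"), mendel_max = 0L) {
  mendel_action <- match.arg(mendel_action)
  ped <- read_ped(ped_path)
  pheno <- read_pheno(pheno_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  if (!all(biallelic)) {
    warning(sum(!biallelic), " multi-allelic record(s) skipped")
    fix <- fix[biallelic, , drop = FALSE]
    gt <- gt[biallelic, , drop = FALSE]
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  x <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  x[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  x <- t(x)  # individuals x variants

  missing_ids <- setdiff(ped$iid, rownames(x))
  if (length(missing_ids) > 0L) {
    pad <- matrix(NA_integer_, nrow = length(missing_ids), ncol = ncol(x),
                  dimnames = list(missing_ids, colnames(x)))
    x <- rbind(x, pad)
  }
  x <- x[ped$iid, , drop = FALSE]

  id <- fix$ID
  auto <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  id[is.na(id) | id == "."] <- auto[is.na(id) | id == "."]
  variants <- data.frame(id = id, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         gene = NA_character_, annotation = NA_character_,
                         flipped = FALSE, maf = NA_real_,
                         stringsAsFactors = FALSE)

  # minor allele defined on founders; tie at 0.5 keeps alt as minor
  fo <- intersect(founders(ped), rownames(x))
  xf <- x[fo, , drop = FALSE]
  p_alt <- colSums(xf, na.rm = TRUE) / pmax(2 * colSums(!is.na(xf)), 1L)
  flip <- !is.na(p_alt) & p_alt > 0.5
  x[, flip] <- 2L - x[, flip]
  variants$flipped <- flip
  variants$maf <- ifelse(flip, 1 - p_alt, p_alt)

  geno <- GenotypeMatrix(x, variants)
  geno <- check_mendelian(geno, ped, action = mendel_action,
                          max_errors = mendel_max)
  cohort <- list(ped = ped, geno = geno, pheno = pheno)
  if (!is.null(scores_path)) {
    cohort$scores <- read_scores(scores_path)
    hit <- match(geno$variants$id, cohort$scores$variant_id)
    fill <- is.na(geno$variants$gene) & !is.na(hit)
    cohort$geno$variants$gene[fill] <- cohort$scores$gene[hit[fill]]
    cohort$geno$variants$annotation <- cohort$scores$annotation[hit]
  }
  structure(cohort, class = "FbatvCohort")
}

#' @exportS3Method base::print
print.FbatvCohort <- function(x, ...) {
  cat(sprintf("FbatvCohort: %d individuals, %d variants, %d pedigrees\n",
              nrow(x$ped), ncol(x$geno$x), length(unique(x$ped$fid))))
  invisible(x)
}

# screen complete trios for Mendelian inconsistencies
check_mendelian <- function(geno, ped, action = c("error", "drop"),
                            max_errors = 0L) {
  action <- match.arg(action)
  fams <- decompose_nuclear(ped)
  fams <- Filter(function(f) f$complete, fams)
  if (length(fams) == 0L) return(geno)
  x <- geno$x
  bad <- list()
  for (f in fams) {
    if (!(f$father %in% rownames(x)) || !(f$mother %in% rownames(x))) next
    gf <- x[f$father, ]
    gm <- x[f$mother, ]
    for (o in f$offspring) {
      if (!(o %in% rownames(x))) next
      cons <- mendelian_consistent(gf, gm, x[o, ])
      idx <- which(!is.na(cons) & !cons)
      if (length(idx) > 0L)
        bad[[length(bad) + 1L]] <- data.frame(
          father = f$father, mother = f$mother, offspring = o,
          variant = geno$variants$id[idx], col = idx,
          stringsAsFactors = FALSE)
    }
  }
  if (length(bad) == 0L) return(geno)
  bad <- do.call(rbind, bad)
  if (nrow(bad) > max_errors) {
    if (action == "error")
      stop("Mendelian inconsistencies in ", nrow(bad),
           " trio-variant pair(s), e.g. offspring ", bad$offspring[1L],
           " at ", bad$variant[1L])
    warning(nrow(bad), " Mendelian-inconsistent offspring genotype(s) set ",
            "to missing")
    geno$x[cbind(match(bad$offspring, rownames(geno$x)), bad$col)] <-
      NA_integer_
  }
  geno
}

#' Write genotypes as a plain-text VCF 4.2 file (GT only)
#'
#' Counts are written back in the original VCF ref/alt orientation
#' (variants recoded at read time are un-flipped).
#'
#' @param geno a [GenotypeMatrix].
#' @param path output path.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  x <- geno$x
  x[, v$flipped] <- 2L - x[, v$flipped]
  gt <- matrix(c("0/0", "0/1", "1/1")[x + 1L], nrow = nrow(x))
  gt[is.na(x)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(x)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated (or loaded) cohort to standard files
#'
#' Emits `genotypes.vcf`, `pedigree.ped`, `phenotypes.tsv` and, when
#' present, `scores.tsv` and a `truth.json` record of the generative model.
#'
#' @param cohort an `FbatvCohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$geno, file.path(dir, "genotypes.vcf"))
  ped <- cohort$ped
  ped_out <- data.frame(ped$fid, ped$iid,
                        ifelse(is.na(ped$father), "0", ped$father),
                        ifelse(is.na(ped$mother), "0", ped$mother),
                        ifelse(is.na(ped$sex), 0L, ped$sex), 0L)
  utils::write.table(ped_out, file.path(dir, "pedigree.ped"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$pheno, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$scores))
    utils::write.table(cohort$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Assign gene labels to variants from a BED file
#'
#' BED intervals are 0-based half-open; a variant at 1-based position `pos`
#' falls in `[start, end)` when `start < pos <= end`.
#'
#' @param geno a [GenotypeMatrix].
#' @param bed_path BED file with columns chrom, start, end, name.
#' @return The genotype matrix with `variants$gene` filled in.
#' @export
assign_regions <- function(geno, bed_path) {
  bed <- utils::read.table(bed_path, header = FALSE,
                           stringsAsFactors = FALSE)[, 1:4]
  names(bed) <- c("chrom", "start", "end", "name")
  v <- geno$variants
  for (i in seq_len(nrow(bed))) {
    hit <- v$chrom == bed$chrom[i] & v$pos > bed$start[i] & v$pos <= bed$end[i]
    v$gene[hit] <- bed$name[i]
  }
  geno$variants <- v
  geno
}

#' Subset a genotype matrix by variant
#'
#' @param geno a [GenotypeMatrix].
#' @param idx logical/integer index or character vector of variant IDs.
#' @export
subset_variants <- function(geno, idx) {
  if (is.character(idx)) idx <- match(idx, geno$variants$id)
  GenotypeMatrix(geno$x[, idx, drop = FALSE],
                 geno$variants[idx, , drop = FALSE])
}
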