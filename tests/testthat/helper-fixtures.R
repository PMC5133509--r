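# shared in-code fixtures

# one trio: father F, mother M, offspring O
trio_ped <- function(fid = "T1", father = "F", mother = "M",
                     offspring = "O") {
  Pedigree(data.frame(
    fid = fid,
    iid = c(father, mother, offspring),
    father = c(NA, NA, father),
    mother = c(NA, NA, mother),
    sex = c(1L, 2L, 1L), stringsAsFactors = FALSE))
}

# three-generation pedigree: grandparents G1 x G2 -> parent P1;
# P2 marries in; P1 x P2 -> children C1, C2
threegen_ped <- function() {
  Pedigree(data.frame(
    fid = "X",
    iid = c("G1", "G2", "P1", "P2", "C1", "C2"),
    father = c(NA, NA, "G1", NA, "P1", "P1"),
    mother = c(NA, NA, "G2", NA, "P2", "P2"),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L), stringsAsFactors = FALSE))
}

# pedigree of unrelated individuals (all founders)
trivial_ped <- function(ids) {
  Pedigree(data.frame(fid = ids, iid = ids, father = NA, mother = NA,
                      sex = 1L, stringsAsFactors = FALSE))
}

# genotype matrix from a plain matrix; founder MAF filled from `maf`
toy_geno <- function(x, ids, maf = rep(0.1, ncol(x))) {
  rownames(x) <- ids
  GenotypeMatrix(x, data.frame(
    id = sprintf("v%d", seq_len(ncol(x))),
    chrom = "1", pos = seq_len(ncol(x)), ref = "A", alt = "C",
    gene = "G", annotation = NA_character_,
    flipped = FALSE, maf = maf, stringsAsFactors = FALSE))
}

# single-exam phenotype table with no covariates beyond what is given
toy_pheno <- function(ids, trait, age = NULL, sex = NULL, med = NULL) {
  df <- data.frame(iid = ids, exam = 1L, trait = trait,
                   stringsAsFactors = FALSE)
  if (!is.null(age)) df$age <- age
  if (!is.null(sex)) df$sex <- sex
  if (!is.null(med)) df$med <- med
  PhenotypeTable(df)
}

toy_cohort <- function(ped, geno, pheno, scores = NULL) {
  structure(list(ped = ped, geno = geno, pheno = pheno, scores = scores),
            class = "FbatvCohort")
}

# fabricate an FbatvScores object directly (for combine/variance tests)
toy_scores <- function(contrib, fid, fkey = fid,
                       xo = NULL, informative = NULL) {
  if (is.null(xo)) xo <- matrix(1L, nrow(contrib), ncol(contrib))
  if (is.null(informative))
    informative <- matrix(TRUE, nrow(contrib), ncol(contrib))
  structure(list(U = colSums(contrib), contrib = contrib,
                 offspring = paste0("o", seq_len(nrow(contrib))),
                 fid = fid, fkey = fkey, xo = xo,
                 xf = matrix(1L, nrow(contrib), ncol(contrib)),
                 xm = matrix(1L, nrow(contrib), ncol(contrib)),
                 informative = informative, mu = 0,
                 n_families = length(unique(fkey))),
            class = "FbatvScores")
}

expect_weight_vector <- function(w, scheme) {
  expect_s3_class(w, "WeightVector")
  expect_identical(attr(w, "scheme"), scheme)
  expect_true(all(is.finite(w)))
}
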