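#' Pedigree objects
#'
#' A `Pedigree` is a data frame with one row per individual and columns
#' `fid` (pedigree/family ID), `iid` (individual ID), `father`, `mother`
#' (IDs of the parents, `NA` when unknown) and `sex` (1 = male, 2 = female,
#' 0/NA = unknown), following the PLINK PED/FAM convention.  Validation
#' enforces that IDs are unique, that every stated parent belongs to the
#' same pedigree, that the parent graph is acyclic, and that every pedigree
#' has at least one founder (an individual with both parents unknown).
#'
#' @param df data frame with columns `fid`, `iid`, `father`, `mother`, `sex`.
#' @return A validated object of class `Pedigree` (a data frame).
#' @export
Pedigree <- function(df) {
  need <- c("fid", "iid", "father", "mother", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  for (col in c("fid", "iid", "father", "mother"))
    df[[col]] <- as.character(df[[col]])
  df$father[df$father %in% c("0", "", "NA")] <- NA_character_
  df$mother[df$mother %in% c("0", "", "NA")] <- NA_character_
  df$sex <- suppressWarnings(as.integer(df$sex))
  rownames(df) <- NULL
  ped <- structure(df, class = c("Pedigree", "data.frame"))
  validate_pedigree(ped)
  ped
}

#' @rdname Pedigree
#' @param ped a `Pedigree`.
#' @export
validate_pedigree <- function(ped) {
  if (nrow(ped) == 0L) stop("pedigree is empty")
  if (anyDuplicated(ped$iid))
    stop("duplicated individual IDs in pedigree: ",
         paste(unique(ped$iid[duplicated(ped$iid)]), collapse = ", "))
  fam_of <- stats::setNames(ped$fid, ped$iid)
  for (col in c("father", "mother")) {
    p <- ped[[col]]
    known <- !is.na(p)
    bad <- known & !(p %in% ped$iid)
    if (any(bad))
      stop("unknown ", col, " ID(s): ", paste(unique(p[bad]), collapse = ", "))
    cross <- known & fam_of[p] != ped$fid
    cross[is.na(cross)] <- FALSE
    if (any(cross))
      stop(col, " in a different pedigree for individual(s): ",
           paste(ped$iid[cross], collapse = ", "))
  }
  # acyclicity: vectorized peel by generation depth
  fa_idx <- match(ped$father, ped$iid)
  mo_idx <- match(ped$mother, ped$iid)
  resolved <- is.na(fa_idx) & is.na(mo_idx)
  repeat {
    fa_ok <- is.na(fa_idx)
    fa_ok[!fa_ok] <- resolved[fa_idx[!fa_ok]]
    mo_ok <- is.na(mo_idx)
    mo_ok[!mo_ok] <- resolved[mo_idx[!mo_ok]]
    newly <- !resolved & fa_ok & mo_ok
    if (!any(newly)) break
    resolved <- resolved | newly
  }
  if (!all(resolved))
    stop("parent graph contains a cycle involving: ",
         paste(ped$iid[!resolved], collapse = ", "))
  has_founder <- tapply(is.na(ped$father) & is.na(ped$mother), ped$fid, any)
  if (!all(has_founder))
    stop("pedigree(s) without founders: ",
         paste(names(has_founder)[!has_founder], collapse = ", "))
  invisible(ped)
}

#' Founders of a pedigree
#'
#' Founders are the individuals with both parents unspecified; they are
#' mutually unrelated and supply the population-level quantities used by the
#' weighting schemes (minor-allele frequencies, odds ratios, optimal weights).
#'
#' @param ped a `Pedigree`.
#' @return Sorted character vector of founder individual IDs.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  validate_pedigree(ped)
  sort(ped$iid[is.na(ped$father) & is.na(ped$mother)])
}

#' Decompose pedigrees into nuclear families
#'
#' Extended pedigrees are decomposed into nuclear families (one father, one
#' mother, and their common offspring), the units over which the test
#' statistic is assembled.  Every parent-offspring edge appears in exactly
#' one nuclear family.  Offspring with exactly one known parent are collected
#' into families flagged `complete = FALSE`; such families are retained for
#' bookkeeping but excluded from testing.
#'
#' @param ped a `Pedigree`.
#' @return A list of `NuclearFamily` objects, each a list with elements
#'   `fid`, `father`, `mother`, `offspring` (character vector) and
#'   `complete` (both parents known).  Ordered by father then mother ID.
#' @export
decompose_nuclear <- function(ped) {
  stopifnot(inherits(ped, "Pedigree"))
  kids <- ped[!(is.na(ped$father) & is.na(ped$mother)), , drop = FALSE]
  if (nrow(kids) == 0L) return(list())
  key <- paste(ifelse(is.na(kids$father), "<NA>", kids$father),
               ifelse(is.na(kids$mother), "<NA>", kids$mother), sep = "\r")
  fams <- lapply(split(seq_len(nrow(kids)), key), function(idx) {
    r1 <- kids[idx[1L], ]
    structure(list(fid = r1$fid,
                   father = r1$father,
                   mother = r1$mother,
                   offspring = sort(kids$iid[idx]),
                   complete = !is.na(r1$father) && !is.na(r1$mother)),
              class = "NuclearFamily")
  })
  ord <- order(vapply(fams, function(f) is.na(f$father), logical(1)),
               vapply(fams, function(f) ifelse(is.na(f$father), "", f$father),
                      character(1)),
               vapply(fams, function(f) is.na(f$mother), logical(1)),
               vapply(fams, function(f) ifelse(is.na(f$mother), "", f$mother),
                      character(1)))
  unname(fams[ord])
}

#' @exportS3Method base::print
print.NuclearFamily <- function(x, ...) {
  cat(sprintf("<NuclearFamily %s x %s: %d offspring%s>\n",
              ifelse(is.na(x$father), "?", x$father),
              ifelse(is.na(x$mother), "?", x$mother),
              length(x$offspring),
              if (x$complete) "" else ", incomplete"))
  invisible(x)
}

#' @exportS3Method base::print
print.Pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d famil%s, %d founders\n",
              nrow(x), length(unique(x$fid)),
              if (length(unique(x$fid)) == 1L) "y" else "ies",
              sum(is.na(x$father) & is.na(x$mother))))
  NextMethod()
}
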