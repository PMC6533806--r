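#' @importFrom data.table data.table setDT setkey := .N .SD setorder setnames
#' @importFrom stats median rbinom rpois runif rnorm prcomp kmeans cor setNames
#' @importFrom utils write.table read.table head modifyList
NULL

# Genotypes are coded as alternate-allele dose: 0 = hom-ref, 1 = het,
# 2 = hom-alt; NA = missing. A parent with dose g can transmit an alt allele
# iff g >= 1 and a ref allele iff g <= 1.

.DEL_CATEGORIES <- c("MATERNAL_DEL", "NONE", "PATERNAL_DEL")

# Fixed ordinal <-> triple map. Ordinals 1-4 are compatible with a maternally
# inherited hemizygous deletion, 5-8 with no deletion, 9-12 with a paternally
# inherited one.
.SIGNATURES <- local({
  s <- data.table::data.table(
    ordinal = 1:12,
    child  = c(0L, 0L, 2L, 2L, 0L, 1L, 1L, 2L, 0L, 0L, 2L, 2L),
    mother = c(2L, 2L, 0L, 0L, 2L, 0L, 2L, 0L, 0L, 1L, 1L, 2L),
    father = c(0L, 1L, 1L, 2L, 2L, 0L, 2L, 0L, 2L, 2L, 0L, 0L),
    deletion_category = rep(c("MATERNAL_DEL", "NONE", "PATERNAL_DEL"), each = 4L)
  )
  s$signature <- paste(s$child, s$mother, s$father, sep = ",")
  s
})

#' Table of the twelve Mendelian-inconsistent trio genotype signatures
#'
#' Each signature is an ordered (child, mother, father) genotype triple coded
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate, that
#' violates Mendelian transmission at a biallelic diploid autosomal locus.
#' Ordinals 1-4 can arise from a maternally inherited hemizygous deletion
#' (the hemizygous carrier is called homozygous for its remaining allele),
#' 5-8 cannot arise from a single inherited deletion, and 9-12 mirror 1-4
#' for a paternally inherited deletion.
#'
#' @return A `data.table` with columns `ordinal`, `child`, `mother`, `father`,
#'   `signature` (the "c,m,f" string) and `deletion_category` (one of
#'   `"MATERNAL_DEL"`, `"NONE"`, `"PATERNAL_DEL"`).
#' @export
#' @examples
#' signature_table()
signature_table <- function() {
  data.table::copy(.SIGNATURES)
}

.check_geno_codes <- function(..., what = "genotype") {
  for (g in list(...)) {
    if (anyNA(g)) {
      stop("missing (NA) ", what, " codes are not allowed here; drop or skip them first")
    }
    if (!all(g %in% 0:2)) {
      stop(what, " codes must be 0, 1 or 2")
    }
  }
  invisible(NULL)
}

#' Test trio genotype triples for Mendelian consistency
#'
#' A triple is consistent iff the child genotype can be formed by transmitting
#' one allele from each parent: a parent coded 0 transmits a reference allele,
#' 2 an alternate allele, and 1 either.
#'
#' @param child,mother,father integer vectors of genotype codes (0/1/2),
#'   recycled to a common length. `NA` codes are rejected.
#' @return Logical vector, `TRUE` where the triple is Mendelian-consistent.
#' @export
#' @examples
#' mendelian_consistent(1, 0, 0)  # child het, both parents hom-ref: FALSE
#' mendelian_consistent(1, 1, 1)  # TRUE
mendelian_consistent <- function(child, mother, father) {
  n <- max(length(child), length(mother), length(father))
  child <- rep_len(as.integer(child), n)
  mother <- rep_len(as.integer(mother), n)
  father <- rep_len(as.integer(father), n)
  .check_geno_codes(child, mother, father)
  # child dose must be expressible as a + b with a in tr(mother), b in tr(father)
  # where tr(0) = {0}, tr(1) = {0,1}, tr(2) = {1} (alt-allele dose transmitted)
  min_dose <- (mother == 2L) + (father == 2L)
  max_dose <- (mother >= 1L) + (father >= 1L)
  child >= min_dose & child <= max_dose
}

#' Classify trio genotype triples into Mendelian-inconsistent signatures
#'
#' @inheritParams mendelian_consistent
#' @return A `data.table` with one row per input triple: `child`, `mother`,
#'   `father`, `consistent` (logical), `ordinal` (1-12, `NA` when consistent),
#'   `signature` ("c,m,f" string) and `deletion_category` (`NA` when
#'   consistent).
#' @export
#' @examples
#' classify_signature(c(0, 0), c(2, 1), c(1, 2))
classify_signature <- function(child, mother, father) {
  n <- max(length(child), length(mother), length(father))
  child <- rep_len(as.integer(child), n)
  mother <- rep_len(as.integer(mother), n)
  father <- rep_len(as.integer(father), n)
  .check_geno_codes(child, mother, father)
  out <- data.table::data.table(child = child, mother = mother, father = father)
  out[, consistent := mendelian_consistent(child, mother, father)]
  out[, signature := paste(child, mother, father, sep = ",")]
  idx <- match(out$signature, .SIGNATURES$signature)
  out[, ordinal := .SIGNATURES$ordinal[idx]]
  out[, deletion_category := .SIGNATURES$deletion_category[idx]]
  stopifnot(all(is.na(out$ordinal) == out$consistent))
  out[]
}

#' The eight deletion-compatible Mendelian-inconsistent signatures
#'
#' Signatures explainable by a hemizygous deletion inherited by the child from
#' exactly one parent, under the convention that a hemizygous sample is called
#' homozygous for its remaining allele.
#'
#' @return Subset of [signature_table()] with `deletion_category != "NONE"`
#'   (ordinals 1-4 maternal, 9-12 paternal).
#' @export
deletion_compatible_set <- function() {
  .SIGNATURES[deletion_category != "NONE"]
}

#' Classify a biallelic variant by allele lengths
#'
#' @param ref,alt character vectors of REF/ALT allele strings (recycled).
#' @return `data.table` with `var_class` (`"SNV"`, `"INSERTION"`,
#'   `"DELETION"`, or `NA` for symbolic/unsupported alleles such as `<DEL>`,
#'   breakends or `*`) and `indel_len` (absolute length difference; 0 for
#'   SNVs, `NA` for symbolic).
#' @export
#' @examples
#' classify_variant(c("A", "A", "ATT"), c("G", "AT", "A"))
classify_variant <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele strings")
  symbolic <- grepl("[<>\\[\\]*]", ref, perl = TRUE) |
    grepl("[<>\\[\\]*]", alt, perl = TRUE) | ref == "." | alt == "."
  dl <- nchar(alt) - nchar(ref)
  var_class <- ifelse(dl > 0, "INSERTION", ifelse(dl < 0, "DELETION", "SNV"))
  # equal-length multi-nucleotide substitutions are treated as SNV-class
  # point events (length difference 0), matching length-based classification
  var_class[symbolic] <- NA_character_
  indel_len <- abs(dl)
  indel_len[symbolic] <- NA_integer_
  data.table::data.table(var_class = var_class, indel_len = as.integer(indel_len))
}

#' Swap maternal and paternal roles of a signature triple
#'
#' Utility for the mirror symmetry of the signature taxonomy: exchanging the
#' parents maps each maternal-deletion signature onto a paternal-deletion one
#' and permutes the non-deletion set within itself.
#'
#' @inheritParams mendelian_consistent
#' @return `data.table` as from [classify_signature()] for the swapped triples.
#' @export
swap_parents <- function(child, mother, father) {
  classify_signature(child, father, mother)
}
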