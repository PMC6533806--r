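# Independent brute-force oracles, kept free of the package's classifier
# internals: transmission is enumerated allele by allele.

# alleles carried by a diploid genotype code (0 = ref allele, 1 = alt allele)
oracle_alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

# Mendelian consistency by exhaustive enumeration of transmitted allele pairs
oracle_consistent <- function(child, mother, father) {
  poss <- as.vector(outer(oracle_alleles(mother), oracle_alleles(father), "+"))
  child %in% poss
}

# all 27 genotype triples
all_triples <- function() {
  g <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  g[order(g$child, g$mother, g$father), ]
}

# Enumerate every single-parent hemizygous-deletion scenario: the carrier
# parent keeps remaining allele r (called homozygous 2r), the child inherits
# the deleted haplotype and so is hemizygous for the other parent's
# transmitted allele b (called 2b); keep the Mendelian-inconsistent triples.
oracle_deletion_signatures <- function() {
  out <- list()
  for (carrier in c("mother", "father")) {
    for (r in 0:1) {
      for (g_other in 0:2) {
        for (b in unique(oracle_alleles(g_other))) {
          child <- 2L * b
          mother <- if (carrier == "mother") 2L * r else g_other
          father <- if (carrier == "father") 2L * r else g_other
          if (!oracle_consistent(child, mother, father)) {
            out[[length(out) + 1L]] <- data.frame(
              child = child, mother = mother, father = father,
              carrier = carrier)
          }
        }
      }
    }
  }
  unique(do.call(rbind, out))
}
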