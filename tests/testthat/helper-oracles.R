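# Independent oracles and small fixture builders shared across test files.
# The oracles deliberately use brute-force enumeration, not the package's
# closed forms.

# exact probability that a UMI family of size m, with per-read error e to a
# single fixed alternative base, yields the wrong consensus (strict
# majority; even-split ties are ambiguous, not errors)
exact_consensus_error <- function(m, e) {
  k <- seq_len(m)
  sum(choose(m, k[k > m / 2]) * e^k[k > m / 2] * (1 - e)^(m - k[k > m / 2]))
}

.oracle_alleles <- function(g) if (g == 0) c(0, 0) else if (g == 1) c(0, 1) else c(1, 1)

oracle_hwe <- function(g, q) {
  p <- 1 - q
  c(p^2, 2 * p * q, q^2)[g + 1]
}

# P(g2 | g1 share one allele IBD): enumerate the IBD allele over g1's
# ordered alleles and the non-IBD allele over the population
oracle_ibd1 <- function(g1, g2, q) {
  tot <- 0
  for (a in .oracle_alleles(g1)) {
    for (b in 0:1) {
      w <- 0.5 * if (b == 1) q else 1 - q
      if (a + b == g2) tot <- tot + w
    }
  }
  tot
}

oracle_duo_lr <- function(parent, child, q)
  oracle_ibd1(parent, child, q) / oracle_hwe(child, q)

oracle_pairwise_lr <- function(g1, g2, q, kappa) {
  (kappa[1] * oracle_hwe(g2, q) + kappa[2] * oracle_ibd1(g1, g2, q) +
     kappa[3] * as.numeric(g1 == g2)) / oracle_hwe(g2, q)
}

# enumerate maternal and paternal transmitted alleles
oracle_trio_lr <- function(mother, child, father, q) {
  num <- 0
  den <- 0
  for (m in .oracle_alleles(mother)) {
    for (f in .oracle_alleles(father))
      if (m + f == child) num <- num + 0.25
    for (b in 0:1) {
      w <- 0.5 * if (b == 1) q else 1 - q
      if (m + b == child) den <- den + w
    }
  }
  if (den == 0) 0 else num / den
}

# -- fixtures ----------------------------------------------------------------

tiny_panel <- function(n = 4, category = "identity", chrom = "1",
                       ref = "A", alt = "G") {
  as_panel(data.frame(locus_id = paste0("rs", seq_len(n)),
                      chrom = chrom, pos = 100L * seq_len(n),
                      ref = ref, alt = alt, category = category,
                      stringsAsFactors = FALSE))
}

write_freq_tsv <- function(freqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(freqs), collapse = "\t"), con)
  writeLines(do.call(paste, c(freqs, sep = "\t")), con)
  path
}

make_reads <- function(locus_id, allele, umi, qual = 30L) {
  data.table::data.table(locus_id = locus_id, allele = allele,
                         umi = umi, qual = as.integer(qual))
}

depth_table <- function(locus_id, A = 0, C = 0, G = 0, T = 0, other = 0,
                        mode = "umi") {
  allele_depths(locus_id, data.frame(A = A, C = C, G = G, T = T,
                                     other = other), mode = mode)
}
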