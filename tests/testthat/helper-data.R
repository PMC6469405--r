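# Five lines, two diploid markers, and a phenotype -- the worked toy data
# used throughout: small enough that every solver can be checked by hand.
toy_markers <- function() {
  marker_matrix(matrix(c(2, 2, 1, 2, 2, 0, 2, 1, 1, 0),
                       ncol = 2, byrow = TRUE))
}

toy_pheno <- function() c(-0.72, 2.34, 0.08, -0.89, 0.86)

# Random dense marker matrix (continuous entries; exercises the algebra
# rather than the genetics).
rand_markers <- function(n, p, seed) {
  set.seed(seed)
  marker_matrix(matrix(round(runif(n * p, 0, 2), 3), n, p))
}

# Random complete degree-2 polynomial model over p loci.
rand_poly <- function(p, seed) {
  set.seed(seed)
  mono <- enumerate_monomials(p, 2L)
  poly_model(mono, rnorm(length(mono)), p = p)
}

# A small biallelic VCF written as plain text (3 sites x 2 samples).
write_toy_vcf <- function(path, gts = c("0/0", "0/1", "1/1",
                                        "0|0", "0/1", "1|1")) {
  g <- matrix(gts, nrow = 3)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "100", "site1", "A", "G", ".", "PASS", ".", "GT",
          g[1, 1], g[1, 2], sep = "\t"),
    paste("1", "200", "site2", "C", "T", ".", "PASS", ".", "GT",
          g[2, 1], g[2, 2], sep = "\t"),
    paste("1", "300", "site3", "G", "A", ".", "PASS", ".", "GT",
          g[3, 1], g[3, 2], sep = "\t"))
  writeLines(lines, path)
  path
}
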