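# Panel, frequency, genotype and VCF I/O contracts.

test_that("panel TSV parses, validates and round-trips exactly", {
  panel <- tiny_panel(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_s3_class(back, "snp_panel")
  expect_equal(as.data.frame(back), as.data.frame(panel))

  # comment lines and header are part of the dialect
  lines <- c("# a comment", readLines(path))
  writeLines(lines, path)
  expect_equal(nrow(read_panel(path)), 3L)
})

test_that("invalid panels are rejected with informative errors", {
  df <- as.data.frame(tiny_panel(3))
  dup <- df; dup$locus_id[2] <- "rs1"
  expect_error(as_panel(dup), "duplicated locus_id")
  same <- df; same$alt[1] <- same$ref[1]
  expect_error(as_panel(same), "ref equals alt")
  badc <- df; badc$category[1] <- "mystery"
  expect_error(as_panel(badc), "unknown marker category")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tchrom\tpos\tref\talt\tcategory",
               "rs1\t1\t100\tA\tG\tidentity",
               "rs2\t1\t200\tA"), path)
  expect_error(read_panel(path), "line 3")
})

test_that("frequency tables validate range and locus coverage", {
  panel <- tiny_panel(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tSWE", "rs1\t0.30", "rs2\t0.5", "rs3\t0.7"), path)
  ft <- read_frequencies(path, panel)
  q <- freq_vector(ft, "SWE", c("rs1"))
  expect_equal(unname(q), 0.30)        # and p = 1 - q = 0.70 implicitly
  expect_error(freq_vector(ft, "SWE", "rs9"), "no frequency for locus rs9")

  writeLines(c("locus_id\tSWE", "rs1\t1.2"), path)
  expect_error(read_frequencies(path, panel), "outside")
  writeLines(c("locus_id\tSWE", "rs1\t0.2", "rs9\t0.3"), path)
  expect_warning(read_frequencies(path, panel), "not in panel")
})

test_that("genotype tables round-trip through TSV with '.' as NA", {
  gt <- genotype_table(c("rs1", "rs2", "rs3"),
                       a1 = c("A", "G", NA), a2 = c("G", NA, NA),
                       status = c("called", "called", "no_call_low_coverage"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gt, path)
  back <- read_genotypes(path)
  expect_equal(as.data.frame(back)[1:4], as.data.frame(gt)[1:4])
  expect_error(genotype_table("rs1", NA, NA, "called"),
               "called genotype without alleles")
})

test_that("minimal VCF output honours the GT:AD:DP contract", {
  panel <- as_panel(data.frame(
    locus_id = c("rs1", "rs2", "rs3"), chrom = c("2", "1", "Y"),
    pos = c(50L, 100L, 10L), ref = c("A", "C", "T"), alt = c("G", "T", "C"),
    category = c("identity", "identity", "Y")))
  gt <- genotype_table(c("rs1", "rs2", "rs3"),
                       a1 = c("A", NA, "C"), a2 = c("G", NA, NA),
                       status = c("called", "no_call_imbalance", "called"))
  dep <- depth_table(c("rs1", "rs2", "rs3"), A = c(60, 0, 0),
                     G = c(40, 0, 0), C = c(0, 3, 12), T = c(0, 5, 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, dep, panel, path)
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  fields <- do.call(rbind, strsplit(lines, "\t"))
  # sorted by (chrom, pos): rs2 (chr1) before rs1 (chr2) before rs3 (Y)
  expect_equal(fields[, 3], c("rs2", "rs1", "rs3"))
  expect_equal(fields[fields[, 3] == "rs1", 10], "0/1:60,40:100")
  expect_equal(fields[fields[, 3] == "rs2", 10], "./.:3,5:8")
  expect_equal(fields[fields[, 3] == "rs3", 10], "1:1,12:13")
})

test_that("VCF output parses with a standard parser and DP = sum(AD)", {
  skip_if_not_installed("vcfR")
  panel <- synthetic_panel(40, seed = 4)
  freqs <- synthetic_frequencies(panel, seed = 4)
  truth <- sample_individual(freqs, panel, "male", seed = 5)
  cfg <- sim_config(input_mass_pg = 2000, reads_target = 20000, seed = 6)
  reads <- simulate_reads(truth, panel, cfg)
  dep <- tabulate_depths(reads, "umi", panel = panel)
  calls <- call_genotypes(dep, panel, call_thresholds(), "male")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(calls, dep, panel, path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(nrow(v@fix), 40L)
  ad <- vcfR::extract.gt(v, "AD")
  dp <- as.integer(vcfR::extract.gt(v, "DP"))
  adsum <- vapply(strsplit(ad, ",", fixed = TRUE),
                  function(x) sum(as.integer(x)), integer(1))
  expect_equal(unname(adsum), dp)
})

test_that("read tables validate alleles, qualities and UMI length", {
  r <- make_reads("rs1", c("A", "G"), c("ACGTACGTACGT", "ACGTACGTACGT"))
  expect_equal(nrow(validate_reads(r, umi_length = 12)), 2L)
  expect_error(validate_reads(r, umi_length = 10), "UMI length")
  bad <- make_reads("rs1", "N", "ACGT")
  expect_error(validate_reads(bad), "allele must be")
  negq <- make_reads("rs1", "A", "ACGT", qual = -1L)
  expect_error(validate_reads(negq), "quality")
})
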