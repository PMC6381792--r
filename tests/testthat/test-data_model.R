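test_that("VCF import codes dosages, filters sites, and round-trips", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3",
    "Chr01\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "Chr01\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/0",
    "Chr01\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0"), tmp)
  g <- read_vcf(tmp, filter = NULL)
  expect_equal(dim(g$dosage), c(3L, 2L))            # multi-allelic skipped
  expect_equal(attr(g, "n_skipped_multiallelic"), 1L)
  expect_equal(unname(g$dosage[, 1]), c(0L, 1L, 2L))
  expect_equal(unname(g$dosage[, 2]), c(1L, 1L, 0L))
  expect_equal(g$sites$pos, c(100L, 200L))

  # site with missing fraction above the cap is dropped
  tmp2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste0("i", 1:10, collapse = "\t")),
    paste("Chr01\t100\t.\tA\tG\t.\tPASS\t.\tGT",
          paste(c("./.", "./.", rep("0/1", 8)), collapse = "\t"), sep = "\t"),
    paste("Chr01\t200\t.\tC\tT\t.\tPASS\t.\tGT",
          paste(rep(c("0/1", "0/0"), 5), collapse = "\t"), sep = "\t")), tmp2)
  gf <- read_vcf(tmp2, filter = filter_config(max_missing = 0.10))
  expect_equal(gf$sites$pos, 200L)

  # simulated matrix round-trips through the writer and reader
  sim <- simulate_panel(panel_config(sizes = c(S = 20L, NW = 10L, NE = 10L),
                                     n_regions = 2L, snps_per_region = 40L,
                                     seed = 3))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, f)
  back <- read_vcf(f, filter = NULL)
  expect_identical(unname(back$dosage), unname(sim$genotypes$dosage))
  expect_equal(back$sites$pos, sim$genotypes$sites$pos)
  expect_equal(back$sites$ref, sim$genotypes$sites$ref)
})

test_that("empty filter result and malformed VCF raise clear errors", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2",
    "Chr01\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/0"), tmp)
  expect_error(read_vcf(tmp, filter = filter_config(min_maf = 0.05)),
               "no sites survive")
  expect_error(read_vcf(tempfile(fileext = ".vcf")), "no such file")
})

test_that("filtering is idempotent and counts are conserved", {
  for (s in 1:5) {
    set.seed(s)
    n <- 30; m <- 60
    dos <- matrix(rbinom(n * m, 2, runif(m, 0.01, 0.5)[rep(1:m, each = n)]),
                  n, m)
    dos[runif(n * m) < 0.15] <- NA
    g <- genotype_matrix(dos, data.frame(chrom = "c1", pos = 1:m * 10,
                                         ref = "A", alt = "G"))
    expect_equal(colSums(!is.na(g$dosage)) + colSums(is.na(g$dosage)),
                 rep(n, m), ignore_attr = TRUE)
    f1 <- apply_filter(g)
    f2 <- apply_filter(f1)
    expect_identical(f1$dosage, f2$dosage)
    expect_identical(f1$sites, f2$sites)
  }
})

test_that("linkage inputs validate maps and round-trip through TSV", {
  calls <- matrix(c(0, 1, 0, 1, 1, 0, 0, 1), 2, 4,
                  dimnames = list(c("p1", "p2"), c("m1", "m2", "m3", "m4")))
  map <- data.frame(lg = c("LG01", "LG01", "LG02", "LG02"),
                    marker = c("m1", "m2", "m3", "m4"),
                    cm = c(0, 5, 0, 7))
  ph <- data.frame(individual = c("p1", "p2"), trait = "V",
                   timepoint = "T01", value = c(1.5, 2.5))
  ld <- linkage_dataset(map, calls, ph)
  expect_equal(length(unique(ld$map$lg)), 2L)

  bad_calls <- calls
  colnames(bad_calls)[4] <- "mX"
  expect_error(linkage_dataset(map, bad_calls, ph), "mX")

  bad_map <- map
  bad_map$cm[2] <- -1
  expect_error(linkage_dataset(bad_map, calls, ph), "LG01")

  d <- tempfile(); dir.create(d)
  fam <- simulate_fullsib(family_config(n_progeny = 40L, n_lg = 2L,
                                        markers_per_lg = 6L,
                                        n_timepoints = 2L, seed = 9))
  paths <- file.path(d, c("map.tsv", "calls.tsv", "pheno.tsv"))
  write_linkage_dataset(fam, paths[1], paths[2], paths[3])
  back <- read_linkage_inputs(paths[1], paths[2], paths[3])
  expect_equal(back$map, fam$map, ignore_attr = TRUE)
  expect_identical(unname(back$calls), unname(fam$calls))
  expect_equal(back$phenotypes$value, fam$phenotypes$value)
})

test_that("BED writer uses 0-based half-open coordinates and sorts", {
  f <- tempfile(fileext = ".bed")
  # 1-based inclusive 9,970,001-10,030,000 corresponds to half-open
  # [9,970,000, 10,030,000)
  write_intervals(data.frame(chrom = "Chr14", start = 9970000L,
                             end = 10030000L, name = "SHR18"), f)
  line <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_equal(line[1:3], c("Chr14", "9970000", "10030000"))

  f2 <- tempfile(fileext = ".bed")
  write_intervals(data.frame(chrom = c("c2", "c1", "c1"),
                             start = c(50L, 500L, 10L),
                             end = c(80L, 900L, 20L)), f2)
  back <- read_intervals(f2)
  expect_equal(back$chrom, c("c1", "c1", "c2"))
  expect_equal(back$start, c(10L, 500L, 50L))

  f3 <- tempfile(fileext = ".bed")
  write_intervals(data.frame(chrom = character(0), start = integer(0),
                             end = integer(0)), f3)
  expect_equal(nrow(read_intervals(f3)), 0L)

  expect_error(write_intervals(data.frame(chrom = "c1", start = 10L,
                                          end = 10L), tempfile()),
               "start must be < end")

  # round-trip identity
  iv <- data.frame(chrom = c("c1", "c2"), start = c(0L, 100L),
                   end = c(250L, 400L), name = c("a", "b"))
  f4 <- tempfile(fileext = ".bed")
  write_intervals(iv, f4)
  expect_equal(read_intervals(f4), iv, ignore_attr = TRUE)
})

test_that("phenotype tables expose sets and aligned vectors", {
  ph <- data.frame(individual = c("a", "b", "a", "b"),
                   trait = c("H", "H", "BD", "BD"),
                   timepoint = "T01", value = 1:4)
  expect_equal(nrow(phenotype_sets(ph)), 2L)
  y <- phenotype_vector(ph, "BD", "T01", individuals = c("b", "a", "zzz"))
  expect_equal(unname(y), c(4, 3, NA))
})
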