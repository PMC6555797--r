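# SNP-panel typing, breadth-of-coverage presence calls, structure labels,
# and the end-to-end classification of synthetic accession panels.

test_that("breadth-of-coverage presence calls are exact and monotone", {
  expect_equal(call_presence(rep(0L, 100), gene = "A4")$breadth, 0)
  expect_identical(call_presence(rep(0L, 100), gene = "A4")$call, "absent")

  deep <- call_presence(rep(30L, 200), gene = "A4")
  expect_equal(deep$breadth, 1)
  expect_identical(deep$call, "present")

  half <- call_presence(c(rep(5L, 100), rep(0L, 100)), gene = "A6",
                        breadth_threshold = 0.8)
  expect_equal(half$breadth, 0.5)
  expect_identical(half$call, "absent")

  expect_error(call_presence(integer(0)), "Empty")

  # monotone: raising any depth never flips present -> absent
  set.seed(7)
  for (i in 1:20) {
    depths <- rpois(50, 3)
    before <- call_presence(depths, gene = "g")
    j <- sample(50, 1)
    depths[j] <- depths[j] + sample(1:10, 1)
    after <- call_presence(depths, gene = "g")
    expect_gte(after$breadth, before$breadth)
    if (before$call == "present") expect_identical(after$call, "present")
  }
})

test_that("interval form counts missing positions as uncovered", {
  depth_tbl <- tibble::tibble(
    chrom = "S1g",
    pos = c(1001:1500, 5001:5050),       # A6 only 50/600 positions covered
    depth = c(rep(30L, 500), rep(30L, 50))
  )
  calls <- call_presence(depth_tbl, intervals = s1_gene_intervals())
  a4 <- calls[calls$gene == "A4", ]
  expect_equal(a4$breadth, 500 / 600)
  expect_identical(a4$call, "present")
  a6 <- calls[calls$gene == "A6", ]
  expect_equal(a6$breadth, 50 / 600)
  expect_identical(a6$call, "absent")
})

test_that("BED coordinates convert to 1-based inclusive and back", {
  path <- tempfile(fileext = ".bed")
  on.exit(unlink(path))
  intervals <- tibble::tibble(
    chrom = "S1g", start = c(101L, 3001L), end = c(200L, 3900L),
    gene = c("geneA", "geneB")
  )
  write_gene_bed(intervals, path)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = "ciic")
  expect_equal(raw$X2, c(100L, 3000L))   # 0-based starts on disk
  expect_equal(raw$X3, c(200L, 3900L))   # half-open ends coincide
  back <- read_gene_bed(path)
  expect_equal(as.data.frame(back), as.data.frame(intervals))
  expect_equal(back$end - back$start + 1L, c(100L, 900L))  # true lengths
})

test_that("protector typing reads the site-7 stop-gain state", {
  expect_identical(type_tpr(c("A", "G", "C", "T", "G", "A", "C")), "TPR")
  expect_identical(type_tpr(c("A", "G", "C", "T", "G", "A", "A")), "TP")
  expect_message(
    out <- type_tpr(c("A", "G", "C", "T", "G", "A", "N")),
    "untypable"
  )
  expect_true(is.na(out))
  expect_error(type_tpr(c("A", "C")), "7 sites")
})

test_that("structure labels compose from presence calls and protector type", {
  expect_identical(classify_structure(TRUE, TRUE, "TPR"), "A4-TPR-A6")
  expect_identical(classify_structure(TRUE, FALSE, "TP"), "A4-TP")
  expect_identical(classify_structure(FALSE, FALSE, "TP"), "TP")
  expect_identical(classify_structure(FALSE, TRUE, "TPR"), "TPR-A6")
  expect_identical(classify_structure("present", "absent", "TPR"), "A4-TPR")
  expect_true(is.na(classify_structure(TRUE, TRUE, NA)))
  # all eight structure labels are reachable
  combos <- expand.grid(a4 = c(TRUE, FALSE), a6 = c(TRUE, FALSE),
                        tpr = c("TPR", "TP"), stringsAsFactors = FALSE)
  labels <- classify_structure(combos$a4, combos$a6, combos$tpr)
  expect_setequal(labels, c("A4-TPR-A6", "TPR-A6", "A4-TPR", "TPR",
                            "A4-TP-A6", "TP-A6", "A4-TP", "TP"))
})

test_that("allele lookup is exact-match with novel fallback", {
  catalog <- read_allele_catalog(
    system.file("extdata", "allele_catalog_synthetic.yaml",
                package = "segdrive")
  )
  expect_identical(classify_allele("AGCTGAC", "A4-TPR-A6", catalog), "2-1")
  expect_identical(classify_allele("AGCTGAA", "TP", catalog), "1-1")
  expect_identical(classify_allele("CCCCCCC", "TP", catalog), "novel")
  # same pattern but conflicting structure does not match
  expect_identical(classify_allele("AGCTGAC", "TPR", catalog), "novel")
  expect_true(is.na(classify_allele(NA_character_, "TP", catalog)))
  # duplicate patterns are a configuration error
  dup <- tibble::tibble(allele = c("x", "y"), structure = c("TP", "TP"),
                        pattern = c("AAAAAAA", "AAAAAAA"))
  expect_error(segdrive:::allele_catalog_tbl(dup), "duplicate")
})

test_that("simulated VCFs read back with the intended SNP states", {
  dir <- file.path(tempdir(), "panel-vcf")
  design <- tibble::tibble(
    lineage = c("glaberrima-like", "sativa-like"),
    structure = c("A4-TPR-A6", "TP"),
    n = c(1, 1)
  )
  manifest <- simulate_accession_panel(design, dir, mean_depth = 30,
                                       seed = 21)
  states <- read_snp_states(manifest$vcf[1])
  expect_identical(as.character(states), c("A", "G", "C", "T", "G", "A", "C"))
  expect_identical(attr(states, "accession"), manifest$accession[1])
  states2 <- read_snp_states(manifest$vcf[2])
  expect_identical(unname(states2[7]), "A")
})

test_that("a high-depth synthetic panel is classified without confusion", {
  dir <- file.path(tempdir(), "panel-hi")
  design <- tibble::tibble(
    lineage = c("glaberrima-like", "sativa-like", "barthii-like",
                "intermediate"),
    structure = c("A4-TPR-A6", "TP", "A4-TPR-A6", "A4-TP"),
    n = c(6, 6, 4, 4)
  )
  manifest <- simulate_accession_panel(design, dir, mean_depth = 30,
                                       seed = 5)
  catalog <- read_allele_catalog(
    system.file("extdata", "allele_catalog_synthetic.yaml",
                package = "segdrive")
  )
  calls <- classify_haplotypes(manifest, catalog = catalog)
  expect_equal(nrow(calls), 20L)
  expect_identical(calls$structure, manifest$structure)  # 100% recovery
  expect_identical(calls$snp_pattern, manifest$pattern)
  # catalogued patterns resolve to allele names, others to novel
  expect_true(all(calls$allele[calls$structure == "A4-TPR-A6"] == "2-1"))

  # truth and samples manifests round-trip from disk
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             col_types = "ccc")
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"), col_types = "cccc")
  calls2 <- classify_haplotypes(samples,
                                intervals = read_gene_bed(
                                  file.path(dir, "genes.bed")))
  expect_identical(calls2$structure, truth$structure)
})

test_that("classification degrades to absent/untypable as depth vanishes", {
  design <- tibble::tibble(lineage = "glaberrima-like",
                           structure = "A4-TPR-A6", n = 4)
  dir0 <- file.path(tempdir(), "panel-zero")
  m0 <- simulate_accession_panel(design, dir0, mean_depth = 0, seed = 9)
  calls0 <- classify_haplotypes(m0)
  expect_true(all(calls0$a4 == "absent"))
  expect_true(all(calls0$a6 == "absent"))
  expect_true(all(is.na(calls0$tpr_state)))
  expect_true(all(is.na(calls0$structure)))

  # at depth 1 with min_depth 2, breadth falls below threshold
  dir1 <- file.path(tempdir(), "panel-low")
  m1 <- simulate_accession_panel(design, dir1, mean_depth = 1, seed = 9)
  calls1 <- classify_haplotypes(m1)
  expect_true(all(calls1$a4 == "absent"))

  # at depth >= 10 recovery is essentially perfect
  dir10 <- file.path(tempdir(), "panel-mid")
  design10 <- tibble::tibble(
    lineage = c("glab", "sat"), structure = c("A4-TPR-A6", "TP"),
    n = c(10, 10)
  )
  m10 <- simulate_accession_panel(design10, dir10, mean_depth = 10, seed = 13)
  calls10 <- classify_haplotypes(m10)
  acc <- mean(calls10$structure == m10$structure, na.rm = TRUE)
  expect_gte(acc, 0.99)
})

test_that("empty designs produce empty but well-formed panels", {
  dir <- file.path(tempdir(), "panel-empty")
  design <- tibble::tibble(lineage = character(), structure = character(),
                           n = integer())
  m <- simulate_accession_panel(design, dir, mean_depth = 30, seed = 1)
  expect_equal(nrow(m), 0L)
  expect_true(file.exists(file.path(dir, "samples.tsv")))
})
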