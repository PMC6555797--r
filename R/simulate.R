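#' Sample a synthetic progeny count table from a cross
#'
#' Multinomial draw of `n` individuals from the model-predicted class
#' probabilities at one locus of a cross (marginalised from
#' [cross_progeny()]). Identical seeds give identical tables.
#'
#' @param mother,father Parental [kp_genotype()]s (selfing by default).
#' @param locus Locus to score.
#' @param n Number of progeny individuals (>= 1).
#' @param seed Integer seed.
#' @param model Model to simulate under; defaults to the mother's.
#' @return A [observed_counts()]-style `kp_counts` tibble (classes with a
#'   zero draw are kept with count 0 when the model gives them positive
#'   probability).
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' sample_progeny_counts(f1, locus = "S1", n = 500, seed = 1)
#' @export
sample_progeny_counts <- function(mother, father = mother, locus, n, seed,
                                  model = mother$model) {
  stopifnot(n >= 1)
  m <- expected_class_probs(mother, father, locus, model)
  set.seed(as.integer(seed))
  draw <- as.integer(rmultinom(1, n, m$prob))
  structure(
    tibble(locus = locus, class = m$class, count = draw),
    class = c("kp_counts", class(tibble()))
  )
}

#' Simulate a per-base depth profile for a present or absent gene
#'
#' Present genes get independent Poisson(`mean_depth`) depths at every
#' position; absent genes get Poisson(`mean_depth * contamination_rate`),
#' modelling sparse cross-mapping reads.
#'
#' @param length Gene length in bp (>= 1).
#' @param present Logical: is the gene present in the accession?
#' @param mean_depth Mean sequencing depth (>= 0).
#' @param seed Integer seed.
#' @param contamination_rate Fraction of `mean_depth` leaking onto absent
#'   genes (default 0.01).
#' @return Integer vector of per-position depths.
#' @examples
#' summary(simulate_depth_profile(1000, TRUE, mean_depth = 30, seed = 1))
#' @export
simulate_depth_profile <- function(length, present, mean_depth, seed,
                                   contamination_rate = 0.01) {
  stopifnot(length >= 1, mean_depth >= 0)
  set.seed(as.integer(seed))
  lambda <- if (present) mean_depth else mean_depth * contamination_rate
  rpois(length, lambda)
}

structure_genes <- function(structure) {
  list(
    a4 = grepl("^A4-", structure),
    a6 = grepl("-A6$", structure),
    tpr = if (grepl("TPR", structure)) "TPR" else "TP"
  )
}

# Derive the 7-site state vector of a structure's default pattern: all-ref
# for TPR haplotypes, alt at site 7 for TP haplotypes.
default_pattern <- function(structure, panel) {
  g <- structure_genes(structure)
  states <- panel$ref
  if (g$tpr == "TP") states[7] <- panel$alt[7]
  paste(states, collapse = "")
}

write_minimal_vcf <- function(path, accession, panel, pattern, site_depth) {
  states <- strsplit(pattern, "")[[1]]
  gt <- vapply(seq_len(7), function(i) {
    if (site_depth[i] < 1L) return("./.")
    if (states[i] == panel$ref[i]) "0/0"
    else if (states[i] == panel$alt[i]) "1/1"
    else "./."
  }, character(1))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=segdrive-simulate_accession_panel",
    paste0("##contig=<ID=", unique(panel$chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accession), collapse = "\t"),
    vapply(seq_len(7), function(i) {
      paste(c(panel$chrom[i], panel$pos[i], paste0("site", i), panel$ref[i],
              panel$alt[i], ".", "PASS", ".", "GT", gt[i]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an accession panel with lineage-structured haplotypes
#'
#' Writes, for each simulated accession, a single-sample VCF restricted to the
#' 7 panel sites and a samtools-depth style per-base depth file over the gene
#' intervals, in exactly the dialects [classify_haplotypes()] reads, plus a
#' BED file of the intervals, a `samples.tsv` manifest, and a `truth.tsv` of
#' generating labels for accuracy scoring.
#'
#' The design emulates lineage-specific locus structures: e.g. all
#' African-rice-like accessions carrying the three-gene `A4-TPR-A6` haplotype
#' and all Asian-rice-like accessions the one-gene `TP` haplotype. SNP states
#' at panel sites are deterministic given the lineage pattern; depths are
#' Poisson (see [simulate_depth_profile()]). Sites with simulated depth 0 are
#' emitted as missing genotypes, so a zero-depth panel is wholly untypable.
#'
#' @param design A tibble with columns `lineage`, `structure` (e.g.
#'   `"A4-TPR-A6"`, `"TP"`), `n` (accessions), and optionally `pattern`
#'   (7-character SNP states; defaults to the structure's all-reference /
#'   site-7-alternate pattern).
#' @param dir Output directory (created if needed).
#' @param mean_depth Mean sequencing depth for present genes.
#' @param seed Integer seed; every file is a pure function of
#'   `(design, seed)`.
#' @param contamination_rate Cross-mapping depth fraction on absent genes.
#' @param intervals Gene intervals (must contain genes `A4`, `TPR`, `A6`).
#' @param panel A [snp_panel()].
#' @return The samples manifest tibble (`accession`, `lineage`, `structure`,
#'   `pattern`, `vcf`, `depth`), invisibly also written as `samples.tsv` and
#'   `truth.tsv` under `dir`.
#' @examples
#' design <- tibble::tibble(
#'   lineage = c("glaberrima-like", "sativa-like"),
#'   structure = c("A4-TPR-A6", "TP"),
#'   n = c(2, 2)
#' )
#' panel_dir <- file.path(tempdir(), "panel-demo")
#' manifest <- simulate_accession_panel(design, panel_dir,
#'                                      mean_depth = 30, seed = 1)
#' classify_haplotypes(manifest)
#' @export
simulate_accession_panel <- function(design, dir, mean_depth = 30, seed,
                                     contamination_rate = 0.01,
                                     intervals = s1_gene_intervals(),
                                     panel = s1_snp_panel()) {
  design <- as_tibble(design)
  need <- c("lineage", "structure", "n")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    abort(sprintf("`design` is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"pattern" %in% names(design)) {
    design$pattern <- unname(vapply(design$structure, default_pattern,
                                    character(1), panel = panel))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_bed(intervals, file.path(dir, "genes.bed"))
  rows <- list()
  acc_i <- 0L
  for (d in seq_len(nrow(design))) {
    for (r in seq_len(design$n[d])) {
      acc_i <- acc_i + 1L
      accession <- sprintf("acc%03d", acc_i)
      g <- structure_genes(design$structure[d])
      present <- c(A4 = g$a4, TPR = TRUE, A6 = g$a6)
      depth_rows <- list()
      for (gi in seq_len(nrow(intervals))) {
        gene <- intervals$gene[gi]
        len <- intervals$end[gi] - intervals$start[gi] + 1L
        prof <- simulate_depth_profile(
          len, present[[gene]], mean_depth,
          seed = as.integer(seed) + 131L * acc_i + gi,
          contamination_rate = contamination_rate
        )
        depth_rows[[gi]] <- tibble(
          chrom = intervals$chrom[gi],
          pos = seq.int(intervals$start[gi], intervals$end[gi]),
          depth = prof
        )
      }
      depth_tbl <- dplyr::bind_rows(depth_rows)
      depth_path <- file.path(dir, paste0(accession, ".depth.tsv"))
      readr::write_tsv(depth_tbl, depth_path, col_names = FALSE)
      site_depth <- depth_tbl$depth[match(panel$pos, depth_tbl$pos)]
      site_depth[is.na(site_depth)] <- 0L
      vcf_path <- file.path(dir, paste0(accession, ".vcf"))
      write_minimal_vcf(vcf_path, accession, panel, design$pattern[d],
                        site_depth)
      rows[[acc_i]] <- tibble(
        accession = accession,
        lineage = design$lineage[d],
        structure = design$structure[d],
        pattern = design$pattern[d],
        vcf = vcf_path,
        depth = depth_path
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0L) {
    manifest <- tibble(accession = character(), lineage = character(),
                       structure = character(), pattern = character(),
                       vcf = character(), depth = character())
  }
  readr::write_tsv(manifest[, c("accession", "vcf", "depth")],
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(manifest[, c("accession", "lineage", "structure",
                                "pattern")],
                   file.path(dir, "truth.tsv"))
  manifest
}
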