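#' Define a SNP panel for protector-gene typing
#'
#' Seven coding-sequence SNP sites distinguish the full-length protector gene
#' (TPR) from its truncated form (TP); site 7 is the C-to-A stop-gain that
#' truncates TP. A panel records, per site, the reference chromosome/position
#' and the two admissible states.
#'
#' @param sites A tibble/data frame with columns `site` (1..7), `chrom`,
#'   `pos`, `ref`, `alt` (single nucleotides).
#' @return A tibble of class `kp_snp_panel`.
#' @seealso [s1_snp_panel()] for the default panel layout.
#' @export
snp_panel <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("site", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    abort(sprintf("`sites` is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (nrow(sites) != 7L || !identical(sort(as.integer(sites$site)), 1:7)) {
    abort("A SNP panel must define exactly sites 1 to 7.")
  }
  if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L)) {
    abort("`ref` and `alt` must be single nucleotides.")
  }
  sites <- dplyr::arrange(sites, .data$site)
  structure(sites, class = c("kp_snp_panel", class(tibble())))
}

#' Default S1 protector-gene SNP panel and gene intervals
#'
#' A synthetic reference layout for the S1 locus used by the simulator and the
#' examples: three gene intervals (`A4`, `TPR`, `A6`) on contig `S1g`, with
#' the seven panel SNPs inside the `TPR` interval. Site 7 has reference state
#' `C` (full-length TPR) and alternate `A` (truncated TP). Real analyses
#' supply their own panel coordinates from the reference annotation.
#'
#' @return `s1_snp_panel()`: a [snp_panel()]. `s1_gene_intervals()`: a tibble
#'   with `chrom`, `start`, `end`, `gene` (1-based inclusive coordinates).
#' @export
s1_snp_panel <- function() {
  snp_panel(tibble(
    site = 1:7,
    chrom = "S1g",
    pos = c(3101L, 3201L, 3301L, 3401L, 3501L, 3601L, 3701L),
    ref = c("A", "G", "C", "T", "G", "A", "C"),
    alt = c("G", "A", "T", "C", "A", "G", "A")
  ))
}

#' @rdname s1_snp_panel
#' @export
s1_gene_intervals <- function() {
  tibble(
    chrom = "S1g",
    start = c(1001L, 3001L, 5001L),
    end   = c(1600L, 3900L, 5600L),
    gene  = c("A4", "TPR", "A6")
  )
}

#' Read a samtools-depth style per-base depth file
#'
#' Three tab-separated columns: chromosome, 1-based position, read depth.
#' Positions absent from the file are treated as depth 0 by downstream
#' breadth computations (so both the default and `-a` samtools dialects
#' work).
#'
#' @param path File path.
#' @return A tibble with `chrom`, `pos`, `depth`.
#' @export
read_depth_tsv <- function(path) {
  tbl <- readr::read_tsv(path,
    col_names = c("chrom", "pos", "depth"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      depth = readr::col_integer()
    ),
    comment = "#"
  )
  if (any(tbl$depth < 0, na.rm = TRUE)) abort("Depths must be >= 0.")
  tbl
}

#' Read gene intervals from a BED file
#'
#' BED uses 0-based half-open coordinates; they are converted to the 1-based
#' inclusive convention used throughout (a BED line `chr 100 200 gene` becomes
#' `start = 101, end = 200`).
#'
#' @param path BED file path (columns chrom, start, end, name).
#' @return A tibble with `chrom`, `start`, `end`, `gene` (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  tbl <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "gene"),
    col_types = "ciic", comment = "#"
  )
  tibble(
    chrom = tbl$chrom,
    start = tbl$start + 1L,
    end = tbl$end,
    gene = tbl$gene
  )
}

#' Write gene intervals to BED (0-based half-open)
#'
#' @param intervals Tibble with 1-based inclusive `chrom`, `start`, `end`,
#'   `gene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(intervals, path) {
  readr::write_tsv(
    tibble(
      chrom = intervals$chrom,
      start = intervals$start - 1L,
      end = intervals$end,
      name = intervals$gene
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Call gene presence/absence from breadth of coverage
#'
#' Breadth is the fraction of positions in the gene interval covered at depth
#' `>= min_depth`; the gene is called present when breadth
#' `>= breadth_threshold`. The call is monotone in depth: raising any
#' position's depth can only raise breadth.
#'
#' Two input forms are supported: a bare integer vector of per-position depths
#' (one gene), or a depth tibble from [read_depth_tsv()] together with
#' `intervals`, in which case one call per gene interval is returned and
#' positions missing from the depth table count as depth 0.
#'
#' @param depth Integer vector of per-base depths, or a tibble with `chrom`,
#'   `pos`, `depth`.
#' @param intervals Gene intervals (`chrom`, `start`, `end`, `gene`, 1-based
#'   inclusive); required when `depth` is a tibble.
#' @param gene Gene id for the vector form.
#' @param min_depth Minimum per-base depth for a position to count as covered.
#' @param breadth_threshold Minimum breadth to call a gene present.
#' @return A tibble with `gene`, `breadth`, `call` (`"present"`/`"absent"`).
#' @examples
#' call_presence(rep(30L, 100), gene = "A4")
#' call_presence(c(rep(5L, 50), rep(0L, 50)), gene = "A6")  # breadth 0.5
#' @export
call_presence <- function(depth, intervals = NULL, gene = "gene",
                          min_depth = 2L, breadth_threshold = 0.8) {
  if (is.data.frame(depth)) {
    if (is.null(intervals)) {
      abort("Supply `intervals` when `depth` is a per-position table.")
    }
    ivs <- as_tibble(intervals)[, c("chrom", "start", "end", "gene")]
    calls <- purrr::pmap_dfr(ivs, function(chrom, start, end, gene) {
      sel <- depth$chrom == chrom & depth$pos >= start & depth$pos <= end
      covered <- sum(depth$depth[sel] >= min_depth)
      breadth <- covered / (end - start + 1L)
      tibble(gene = gene, breadth = breadth)
    })
  } else {
    if (length(depth) == 0L) abort("Empty depth profile.")
    calls <- tibble(gene = gene,
                    breadth = mean(depth >= min_depth))
  }
  calls$call <- ifelse(calls$breadth >= breadth_threshold, "present",
                       "absent")
  calls
}

#' Type the protector gene from the 7-site SNP states
#'
#' Site 7 carries the stop-gain polymorphism: state `C` means the full-length
#' protector (`TPR`), state `A` the truncated form (`TP`). Any other state
#' (missing data `N`, unexpected nucleotide) yields `NA` ("untypable").
#'
#' @param snp_states Character vector of 7 single-nucleotide states (sites 1-7
#'   in order), or a matrix/data frame with 7 columns (one row per accession).
#' @param panel A [snp_panel()]; site 7's `ref`/`alt` define the C/A states.
#' @return Character vector: `"TPR"`, `"TP"`, or `NA` per accession.
#' @examples
#' type_tpr(c("A", "G", "C", "T", "G", "A", "C"))  # TPR
#' type_tpr(c("A", "G", "C", "T", "G", "A", "A"))  # TP
#' type_tpr(c("A", "G", "C", "T", "G", "A", "N"))  # NA (untypable)
#' @export
type_tpr <- function(snp_states, panel = s1_snp_panel()) {
  if (is.null(dim(snp_states))) {
    if (length(snp_states) != 7L) {
      abort("`snp_states` must have 7 sites.")
    }
    s7 <- snp_states[[7]]
  } else {
    if (ncol(snp_states) != 7L) abort("`snp_states` must have 7 columns.")
    s7 <- as.character(as.matrix(snp_states)[, 7])
  }
  ref7 <- panel$ref[panel$site == 7]
  alt7 <- panel$alt[panel$site == 7]
  out <- rep(NA_character_, length(s7))
  out[s7 == ref7] <- "TPR"
  out[s7 == alt7] <- "TP"
  bad <- is.na(out)
  if (any(bad)) {
    rlang::inform(sprintf(
      "%d accession(s) untypable at site 7 (state not %s/%s).",
      sum(bad), ref7, alt7
    ))
  }
  out
}

#' Compose the locus structure label from presence calls and protector type
#'
#' The label concatenates the flanking killer genes around the protector type:
#' `{A4-}? {TPR|TP} {-A6}?`, giving one of `TP`, `TPR`, `A4-TP`, `TP-A6`,
#' `A4-TP-A6`, `A4-TPR`, `TPR-A6`, `A4-TPR-A6`. An untypable protector state
#' (`NA`) propagates to an `NA` structure.
#'
#' @param a4_present,a6_present Logical (or `"present"`/`"absent"`).
#' @param tpr_state `"TPR"`, `"TP"` or `NA`, e.g. from [type_tpr()].
#' @return Character vector of structure labels.
#' @examples
#' classify_structure(TRUE, TRUE, "TPR")    # "A4-TPR-A6"
#' classify_structure(TRUE, FALSE, "TP")    # "A4-TP"
#' classify_structure(FALSE, FALSE, "TP")   # "TP"
#' @export
classify_structure <- function(a4_present, a6_present, tpr_state) {
  to_lgl <- function(x) {
    if (is.character(x)) x == "present" else as.logical(x)
  }
  a4 <- to_lgl(a4_present)
  a6 <- to_lgl(a6_present)
  n <- max(length(a4), length(a6), length(tpr_state))
  a4 <- rep_len(a4, n); a6 <- rep_len(a6, n)
  tpr_state <- rep_len(tpr_state, n)
  ifelse(is.na(tpr_state), NA_character_,
         paste0(ifelse(a4, "A4-", ""), tpr_state, ifelse(a6, "-A6", "")))
}

#' Read an allele-name catalogue
#'
#' The catalogue maps 7-character SNP-pattern strings (plus a structure label)
#' to published allele names. It is configuration, not code: the file shipped
#' at `system.file("extdata", "allele_catalog_synthetic.yaml",
#' package = "segdrive")` contains synthetic placeholder entries illustrating
#' the format; substitute the authoritative patterns for real analyses.
#'
#' @param path YAML or JSON file with a list of entries, each with `allele`,
#'   `structure`, `pattern` (7 characters).
#' @return A tibble of class `kp_catalog` with those columns.
#' @export
read_allele_catalog <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  entries <- doc$alleles %||% doc
  tbl <- purrr::map_dfr(entries, function(e) {
    tibble(allele = e$allele, structure = e$structure, pattern = e$pattern)
  })
  allele_catalog_tbl(tbl)
}

allele_catalog_tbl <- function(tbl) {
  if (any(nchar(tbl$pattern) != 7L)) {
    abort("Catalogue patterns must be 7 characters (sites 1-7).")
  }
  if (anyDuplicated(tbl$pattern)) {
    abort("Catalogue contains duplicate SNP patterns.")
  }
  structure(as_tibble(tbl), class = c("kp_catalog", class(tibble())))
}

#' Look up an allele name from its SNP pattern
#'
#' Exact match of the 7-character pattern against the catalogue (the structure
#' label must also agree when the catalogue records one); no match returns
#' `"novel"`, an untypable pattern returns `NA`.
#'
#' @param pattern 7-character SNP-state string(s), e.g. `"AGCTGAC"`.
#' @param structure Structure label(s) from [classify_structure()].
#' @param catalog A [read_allele_catalog()] tibble.
#' @return Character vector of allele names, `"novel"`, or `NA`.
#' @export
classify_allele <- function(pattern, structure, catalog) {
  stopifnot(inherits(catalog, "kp_catalog") || is.data.frame(catalog))
  n <- max(length(pattern), length(structure))
  pattern <- rep_len(pattern, n)
  structure <- rep_len(structure, n)
  vapply(seq_len(n), function(i) {
    if (is.na(pattern[[i]]) || is.na(structure[[i]])) return(NA_character_)
    hit <- catalog$pattern == pattern[[i]] &
      (is.na(catalog$structure) | catalog$structure == structure[[i]])
    if (any(hit)) catalog$allele[which(hit)[1]] else "novel"
  }, character(1))
}

#' Read SNP-panel states for one accession from a VCF
#'
#' Only records matching the panel's chrom/pos are used; other records are
#' ignored. Homozygous reference genotypes give the `ref` state, homozygous
#' alternate the `alt` state; missing or heterozygous genotypes, and sites
#' absent from the VCF, give `"N"`.
#'
#' @param path VCF file path (single-sample; the first sample is read).
#' @param panel A [snp_panel()].
#' @return Named character vector of 7 states (names `site1`..`site7`), with
#'   attribute `accession` (the VCF sample name).
#' @export
read_snp_states <- function(path, panel = s1_snp_panel()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  states <- setNames(rep("N", 7L), paste0("site", 1:7))
  accession <- NA_character_
  if (nrow(vcf@gt) > 0 && ncol(vcf@gt) >= 2) {
    accession <- colnames(vcf@gt)[2]
  }
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) > 0) {
    gt <- vcfR::extract.gt(vcf)
    for (i in seq_len(nrow(panel))) {
      j <- which(fix$CHROM == panel$chrom[i] &
                   as.integer(fix$POS) == panel$pos[i])
      if (length(j) != 1L) next
      g <- gt[j, 1]
      if (is.na(g)) next
      alleles <- strsplit(g, "[/|]")[[1]]
      if (length(alleles) != 2L || anyNA(suppressWarnings(
        as.integer(alleles)))) next
      if (all(alleles == "0")) {
        states[i] <- fix$REF[j]
      } else if (all(alleles == "1")) {
        states[i] <- fix$ALT[j]
      } # heterozygous or other -> N
    }
  }
  attr(states, "accession") <- accession
  states
}

#' Classify accessions' locus haplotype structures end to end
#'
#' For each accession: read the 7-site SNP states from its VCF, type the
#' protector gene from site 7, call A4/A6 presence from breadth of coverage in
#' its depth file, compose the structure label, and look the pattern up in the
#' allele catalogue.
#'
#' @param samples A tibble with columns `accession`, `vcf`, `depth` (file
#'   paths), e.g. the `samples.tsv` written by [simulate_accession_panel()].
#' @param intervals Gene intervals tibble (1-based inclusive) containing genes
#'   `A4` and `A6`; e.g. from [read_gene_bed()] or [s1_gene_intervals()].
#' @param panel A [snp_panel()].
#' @param catalog Optional [read_allele_catalog()] tibble; when `NULL` the
#'   `allele` column is `NA`.
#' @param min_depth,breadth_threshold Presence-call parameters, see
#'   [call_presence()].
#' @return A tibble with one row per accession: `accession`, `tpr_state`,
#'   `a4`, `a6` (calls), `structure`, `snp_pattern`, `allele`.
#' @export
classify_haplotypes <- function(samples, intervals = s1_gene_intervals(),
                                panel = s1_snp_panel(), catalog = NULL,
                                min_depth = 2L, breadth_threshold = 0.8) {
  samples <- as_tibble(samples)
  need <- c("accession", "vcf", "depth")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    abort(sprintf("`samples` is missing columns: %s",
                  paste(miss, collapse = ", ")))
  }
  purrr::pmap_dfr(
    samples[need],
    function(accession, vcf, depth) {
      states <- read_snp_states(vcf, panel)
      tpr <- suppressMessages(type_tpr(unname(states), panel))
      dp <- read_depth_tsv(depth)
      calls <- call_presence(dp,
        intervals = dplyr::filter(intervals, .data$gene %in% c("A4", "A6")),
        min_depth = min_depth, breadth_threshold = breadth_threshold
      )
      a4 <- calls$call[calls$gene == "A4"]
      a6 <- calls$call[calls$gene == "A6"]
      structure_label <- classify_structure(a4, a6, tpr)
      pattern <- if (any(states == "N")) NA_character_ else {
        paste(states, collapse = "")
      }
      tibble(
        accession = accession,
        tpr_state = tpr,
        a4 = a4, a6 = a6,
        structure = structure_label,
        snp_pattern = pattern,
        allele = if (is.null(catalog)) NA_character_ else {
          classify_allele(pattern, structure_label, catalog)
        }
      )
    }
  )
}

#' Summarise haplotype calls per structure class
#'
#' @param calls Output of [classify_haplotypes()].
#' @return A tibble of `structure` and `n`, untypable accessions under `NA`.
#' @export
summarise_haplotypes <- function(calls) {
  dplyr::count(calls, .data$structure, name = "n")
}
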