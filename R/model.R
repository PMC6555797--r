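#' Define a killer-protector genetic model
#'
#' A `kp_model` bundles the locus/allele catalogue with the killer-protector
#' specification. Each allele is a set of functional components (gene
#' identifiers). The killer *arms* in the diploid sporophyte when the union of
#' components over both alleles at all loci contains every killer component;
#' once armed, a gamete survives only if its own components contain every
#' protector component (gametophytic rescue), otherwise it aborts with the
#' sex-specific abortion probability.
#'
#' Loci assort independently: a tightly linked gene cluster is modelled as a
#' single locus whose alleles carry several components, while unlinked
#' transgene insertions are separate loci with a null allele `"-"` (empty
#' component set).
#'
#' @param loci Named list of loci. Each locus is a named list mapping allele
#'   names to character vectors of component ids (use `character()` for a null
#'   allele).
#' @param killer Character vector of component ids that must all be present in
#'   the sporophyte for the killer to arm.
#' @param protector Character vector of component ids a gamete must carry to be
#'   protected once the killer is armed.
#' @param abort Default abortion probability for unprotected gametes, applied
#'   to both sexes unless overridden.
#' @param abort_male,abort_female Sex-specific abortion probabilities in
#'   \[0, 1\].
#'
#' @return An object of class `kp_model`.
#' @examples
#' mod <- kp_model(
#'   loci = list(
#'     S1   = list(g = c("A4", "TPR", "A6"), s = "TP"),
#'     TPRt = list(T = "TPR", "-" = character())
#'   ),
#'   killer = c("A4", "TPR", "A6"), protector = "TPR", abort = 1
#' )
#' mod
#' @seealso [s1_model()] for the canonical rice S1 configuration.
#' @export
kp_model <- function(loci, killer = c("A4", "TPR", "A6"), protector = "TPR",
                     abort = 1, abort_male = abort, abort_female = abort) {
  if (!is.list(loci) || length(loci) < 1L || is.null(names(loci)) ||
      any(!nzchar(names(loci)))) {
    abort("`loci` must be a non-empty named list of loci.")
  }
  if (anyDuplicated(names(loci))) abort("Locus names must be unique.")
  loci <- lapply(loci, function(alleles) {
    if (!is.list(alleles) || length(alleles) < 1L || is.null(names(alleles))) {
      abort("Each locus must be a named list with at least one allele.")
    }
    if (anyDuplicated(names(alleles))) {
      abort("Allele names must be unique within a locus.")
    }
    bad <- grepl("[/|]", names(alleles))
    if (any(bad)) abort("Allele names may not contain '/' or '|'.")
    lapply(alleles, function(comp) {
      comp <- as.character(comp)
      if (anyDuplicated(comp)) comp <- unique(comp)
      comp
    })
  })
  check_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      abort(sprintf("`%s` must be a single probability in [0, 1].", what))
    }
    as.numeric(p)
  }
  killer <- as.character(killer)
  protector <- as.character(protector)
  if (length(killer) == 0L) abort("`killer` must name at least one component.")
  if (length(protector) == 0L) {
    abort("`protector` must name at least one component.")
  }
  structure(
    list(
      loci = loci,
      killer = unique(killer),
      protector = unique(protector),
      abort_male = check_prob(abort_male, "abort_male"),
      abort_female = check_prob(abort_female, "abort_female")
    ),
    class = "kp_model"
  )
}

#' The canonical rice S1 killer-protector model
#'
#' Preconfigured model of the S1 locus of Asian x African rice hybrids. The
#' African allele `g` carries the three-gene cluster `{A4, TPR, A6}`; the Asian
#' allele `s` carries only the truncated `TP`. Knockout alleles `gm`
#' (`{A4, A6}`, TPR knocked out), `gm4` (`{TPR, A6}`) and `gm6` (`{A4, TPR}`)
#' are included for modelling CRISPR mutants. Optional unlinked transgene loci:
#' `TPRt` with alleles `T = {TPR}` / `-`, and `A4A6t` with alleles
#' `46 = {A4, A6}` / `-`.
#'
#' @param abort Abortion probability for unprotected gametes (both sexes).
#' @param transgenes Character vector of transgene loci to include, a subset of
#'   `c("TPRt", "A4A6t")`.
#' @inheritParams kp_model
#' @return A `kp_model`.
#' @examples
#' s1_model()                      # native locus only
#' s1_model(transgenes = "TPRt")   # plus the protector transgene
#' @export
s1_model <- function(abort = 1, abort_male = abort, abort_female = abort,
                     transgenes = c("TPRt", "A4A6t")) {
  if (length(transgenes)) {
    transgenes <- match.arg(transgenes, several.ok = TRUE)
  }
  loci <- list(
    S1 = list(
      g   = c("A4", "TPR", "A6"),
      s   = "TP",
      gm  = c("A4", "A6"),
      gm4 = c("TPR", "A6"),
      gm6 = c("A4", "TPR")
    )
  )
  if ("TPRt" %in% transgenes) {
    loci$TPRt <- list(T = "TPR", "-" = character())
  }
  if ("A4A6t" %in% transgenes) {
    loci$A4A6t <- list("46" = c("A4", "A6"), "-" = character())
  }
  kp_model(loci,
    killer = c("A4", "TPR", "A6"), protector = "TPR",
    abort_male = abort_male, abort_female = abort_female
  )
}

#' @export
print.kp_model <- function(x, ...) {
  cat("<kp_model>\n")
  cat("  killer components:   ", paste(x$killer, collapse = " + "), "\n")
  cat("  protector components:", paste(x$protector, collapse = " + "), "\n")
  cat(sprintf(
    "  abortion probability: male %.3g, female %.3g\n",
    x$abort_male, x$abort_female
  ))
  for (loc in names(x$loci)) {
    alle <- vapply(names(x$loci[[loc]]), function(a) {
      comp <- x$loci[[loc]][[a]]
      if (length(comp) == 0L) sprintf("%s = {}", a)
      else sprintf("%s = {%s}", a, paste(comp, collapse = ","))
    }, character(1))
    cat(sprintf("  locus %s: %s\n", loc, paste(alle, collapse = "; ")))
  }
  invisible(x)
}

#' List the allele catalogue of a model as a tibble
#'
#' @param model A [kp_model()].
#' @return A tibble with columns `locus`, `allele` and a list-column
#'   `components`.
#' @export
allele_catalog <- function(model) {
  stopifnot(inherits(model, "kp_model"))
  purrr::imap_dfr(model$loci, function(alleles, locus) {
    tibble(
      locus = locus,
      allele = names(alleles),
      components = unname(alleles)
    )
  })
}

#' Read and write model configuration files
#'
#' Models serialise to YAML or JSON (chosen by file extension) with the layout
#' `loci:` (locus -> allele -> component list), `killer:`, `protector:`,
#' `abort_male:`, `abort_female:`. A written file reads back to an identical
#' model object.
#'
#' @param model A [kp_model()].
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_kp_model()` returns a `kp_model`; `write_kp_model()` returns
#'   `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' write_kp_model(s1_model(), path)
#' identical(read_kp_model(path), s1_model())
#' @export
write_kp_model <- function(model, path) {
  stopifnot(inherits(model, "kp_model"))
  doc <- list(
    loci = lapply(model$loci, function(a) lapply(a, as.list)),
    killer = as.list(model$killer),
    protector = as.list(model$protector),
    abort_male = model$abort_male,
    abort_female = model$abort_female
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname write_kp_model
#' @export
read_kp_model <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  req <- c("loci", "killer", "protector")
  miss <- setdiff(req, names(doc))
  if (length(miss)) {
    abort(sprintf("Model file is missing fields: %s",
                  paste(miss, collapse = ", ")))
  }
  loci <- lapply(doc$loci, function(a) lapply(a, function(x) {
    unlist(lapply(x, as.character), use.names = FALSE) %||% character()
  }))
  kp_model(
    loci = loci,
    killer = unlist(doc$killer),
    protector = unlist(doc$protector),
    abort_male = doc$abort_male %||% 1,
    abort_female = doc$abort_female %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
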