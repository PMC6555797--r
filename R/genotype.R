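#' Construct a diploid sporophyte genotype
#'
#' Assigns an unordered pair of allele names to each locus of a model. Loci of
#' the model not mentioned default to homozygous null (`-/-`) when the locus
#' has a null allele, and must be given explicitly otherwise. Pair order is
#' non-semantic: `c("s", "g")` and `c("g", "s")` give the same genotype.
#'
#' @param model A [kp_model()].
#' @param ... One length-2 character vector of allele names per locus, named by
#'   locus (e.g. `S1 = c("g", "s"), TPRt = c("T", "-")`).
#' @return An object of class `kp_genotype`.
#' @examples
#' mod <- s1_model(transgenes = "TPRt")
#' kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-"))
#' @export
kp_genotype <- function(model, ...) {
  stopifnot(inherits(model, "kp_model"))
  given <- list(...)
  if (length(given) && (is.null(names(given)) || any(!nzchar(names(given))))) {
    abort("Genotype loci must be given as named arguments.")
  }
  unknown <- setdiff(names(given), names(model$loci))
  if (length(unknown)) {
    abort(sprintf("Unknown locus: %s (model defines %s).",
                  paste(unknown, collapse = ", "),
                  paste(names(model$loci), collapse = ", ")))
  }
  alleles <- lapply(names(model$loci), function(loc) {
    cat_names <- names(model$loci[[loc]])
    pair <- given[[loc]]
    if (is.null(pair)) {
      if (!NULL_ALLELE %in% cat_names) {
        abort(sprintf(
          "Locus %s has no null allele; specify its genotype explicitly.", loc
        ))
      }
      pair <- c(NULL_ALLELE, NULL_ALLELE)
    }
    pair <- as.character(pair)
    if (length(pair) != 2L) {
      abort(sprintf("Locus %s: a diploid genotype needs exactly 2 alleles.",
                    loc))
    }
    bad <- setdiff(pair, cat_names)
    if (length(bad)) {
      abort(sprintf("Locus %s: unknown allele '%s' (catalogue: %s).",
                    loc, bad[[1]], paste(cat_names, collapse = ", ")))
    }
    sort_alleles(pair)
  })
  names(alleles) <- names(model$loci)
  structure(list(model = model, alleles = alleles), class = "kp_genotype")
}

# Canonical allele order within a class label: named alleles lexicographic,
# the null allele "-" last (so labels read T/- not -/T).
sort_alleles <- function(a) {
  a[order(a == NULL_ALLELE, a, method = "radix")]
}

genotype_label <- function(genotype) {
  paste(vapply(genotype$alleles, paste, character(1), collapse = "/"),
        collapse = "|")
}

#' @export
print.kp_genotype <- function(x, ...) {
  cat("<kp_genotype> ", genotype_label(x), "\n", sep = "")
  invisible(x)
}

#' Parse a compact genotype string
#'
#' Accepts strings like `"S1=g/s, TPRt=T/-"` (comma- or semicolon-separated
#' `locus=a1/a2` terms) and returns the corresponding [kp_genotype()].
#'
#' @param model A [kp_model()].
#' @param string Genotype specification string.
#' @return A `kp_genotype`.
#' @examples
#' parse_genotype(s1_model(), "S1=g/s, TPRt=T/-")
#' @export
parse_genotype <- function(model, string) {
  terms <- strsplit(string, "[,;]")[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (!length(terms)) abort("Empty genotype string.")
  parts <- strsplit(terms, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    abort(sprintf("Cannot parse genotype term '%s' (expected locus=a1/a2).",
                  terms[bad][[1]]))
  }
  spec <- lapply(parts, function(p) {
    al <- strsplit(trimws(p[[2]]), "/", fixed = TRUE)[[1]]
    if (length(al) != 2L) {
      abort(sprintf("Locus %s: expected two '/'-separated alleles.",
                    trimws(p[[1]])))
    }
    trimws(al)
  })
  names(spec) <- trimws(vapply(parts, `[[`, character(1), 1L))
  do.call(kp_genotype, c(list(model), spec))
}
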