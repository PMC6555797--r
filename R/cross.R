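# ---- internal cross machinery ----------------------------------------------

# Precompute everything about a cross that does not depend on the abortion
# probabilities: parental gamete tables, arming flags, and the mapping from
# (female gamete, male gamete) pairs to canonical diploid class labels.
# design_probs() then evaluates progeny class probabilities for any (k_f, k_m)
# in microseconds, which the ML killing-efficiency estimator relies on.
cross_design <- function(model, mother_alleles, father_alleles) {
  if (!identical(names(mother_alleles), names(father_alleles))) {
    abort("Mother and father must be genotyped at the same loci.")
  }
  fg <- gametes_core(model, mother_alleles)
  mg <- gametes_core(model, father_alleles)
  loci <- names(mother_alleles)
  nf <- length(fg$weight)
  nm <- length(mg$weight)
  # per-locus diploid label for every ordered (f, m) gamete pair
  pair_label <- matrix("", nf, nm)
  per_locus <- lapply(loci, function(loc) {
    lab <- matrix("", nf, nm)
    for (i in seq_len(nf)) {
      for (j in seq_len(nm)) {
        lab[i, j] <- paste(sort_alleles(c(fg$alleles[i, loc],
                                          mg$alleles[j, loc])),
                           collapse = "/")
      }
    }
    lab
  })
  names(per_locus) <- loci
  joint <- per_locus[[1]]
  if (length(loci) > 1L) {
    for (loc in loci[-1]) joint <- matrix(paste(joint, per_locus[[loc]],
                                                sep = "|"),
                                          nrow = nf)
  }
  classes <- sort(unique(as.vector(joint)))
  list(
    model = model, loci = loci,
    female = fg, male = mg,
    armed_female = armed_core(model, mother_alleles),
    armed_male = armed_core(model, father_alleles),
    joint_idx = matrix(match(joint, classes), nrow = nf),
    classes = classes,
    per_locus = per_locus
  )
}

design_probs <- function(design, abort_female = design$model$abort_female,
                         abort_male = design$model$abort_male) {
  f <- select_core(design$female, design$armed_female, abort_female)
  m <- select_core(design$male, design$armed_male, abort_male)
  pair_p <- outer(f$weight, m$weight)
  p <- rowsum(as.vector(pair_p), as.vector(design$joint_idx))
  probs <- numeric(length(design$classes))
  probs[as.integer(rownames(p))] <- p
  names(probs) <- design$classes
  probs
}

# Marginalise a named joint-class probability vector onto one locus.
marginal_core <- function(probs, loci, locus) {
  i <- match(locus, loci)
  if (is.na(i)) {
    abort(sprintf("Unknown locus '%s' (cross defines %s).", locus,
                  paste(loci, collapse = ", ")))
  }
  part <- vapply(strsplit(names(probs), "|", fixed = TRUE), `[[`,
                 character(1), i)
  m <- rowsum(unname(probs), part)
  setNames(as.numeric(m), rownames(m))
}

# ---- exported surface -------------------------------------------------------

#' Predict the progeny genotype distribution of a cross
#'
#' Random union of the mother's post-selection female gametes with the
#' father's post-selection male gametes. Each parent's killer arms on its own
#' sporophytic genotype; viability selection uses the model's sex-specific
#' abortion probabilities. Selfing is `cross_progeny(x, x)` (the default).
#'
#' @param mother,father [kp_genotype()] objects sharing the same loci.
#' @param model Model to cross under; defaults to the mother's.
#' @return A tibble of class `kp_progeny` with one column per locus (diploid
#'   class label such as `"g/s"`), a combined `class` label, and `prob`.
#'   Probabilities sum to 1.
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' cross_progeny(f1)  # selfed F1: 4:4:1 at both loci
#' @export
cross_progeny <- function(mother, father = mother, model = mother$model) {
  stopifnot(inherits(mother, "kp_genotype"), inherits(father, "kp_genotype"))
  design <- cross_design(model, mother$alleles, father$alleles)
  probs <- design_probs(design)
  parts <- strsplit(names(probs), "|", fixed = TRUE)
  out <- as_tibble(setNames(
    lapply(seq_along(design$loci),
           function(i) vapply(parts, `[[`, character(1), i)),
    design$loci
  ))
  out$class <- names(probs)
  out$prob <- unname(probs)
  structure(out,
    class = c("kp_progeny", class(tibble())),
    model = model, loci = design$loci
  )
}

#' Marginalise a progeny distribution onto one locus
#'
#' @param progeny A [cross_progeny()] result.
#' @param locus Locus name.
#' @return A tibble with `class` (e.g. `"g/g"`, `"g/s"`, `"s/s"`) and `prob`.
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' marginal_locus(cross_progeny(f1), "S1")
#' @export
marginal_locus <- function(progeny, locus) {
  stopifnot(inherits(progeny, "kp_progeny"))
  loci <- attr(progeny, "loci")
  probs <- setNames(progeny$prob, progeny$class)
  m <- marginal_core(probs, loci, locus)
  tibble(locus = locus, class = names(m), prob = unname(m))
}

#' Expected per-class probabilities at one locus of a cross
#'
#' Convenience wrapper: runs [cross_progeny()] and marginalises onto `locus`.
#' These are the expectations fed to [chi_square_gof()].
#'
#' @inheritParams cross_progeny
#' @param locus Locus to marginalise onto.
#' @return A tibble with `locus`, `class`, `prob`.
#' @export
expected_class_probs <- function(mother, father = mother, locus,
                                 model = mother$model) {
  marginal_locus(cross_progeny(mother, father, model), locus)
}

#' Allele frequency implied by a progeny distribution
#'
#' Sum over diploid classes of (copies of the allele / 2) times the class
#' probability.
#'
#' @param progeny A [cross_progeny()] result (or a marginal tibble with
#'   `class` and `prob`).
#' @param locus Locus name.
#' @param allele Allele name.
#' @return A single probability.
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' allele_frequency(cross_progeny(f1), "S1", "g")  # 2/3
#' @export
allele_frequency <- function(progeny, locus, allele) {
  m <- if (inherits(progeny, "kp_progeny")) {
    marginal_locus(progeny, locus)
  } else {
    progeny
  }
  alleles <- strsplit(m$class, "/", fixed = TRUE)
  known <- unique(unlist(alleles))
  if (!allele %in% known) {
    abort(sprintf("Allele '%s' does not occur at locus %s (classes: %s).",
                  allele, locus, paste(m$class, collapse = ", ")))
  }
  dosage <- vapply(alleles, function(a) sum(a == allele), numeric(1))
  sum(dosage / 2 * m$prob)
}

#' Write a progeny distribution (or any class/prob tibble) to TSV
#'
#' @param x A tibble with at least `class` and `prob` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_progeny_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
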