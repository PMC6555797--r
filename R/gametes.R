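# ---- internal fast core (base R; also used by the likelihood machinery) ----

# Union of components carried by a set of alleles, given as a named list
# locus -> character vector of allele names.
components_union <- function(model, alleles) {
  unique(unlist(lapply(names(alleles), function(loc) {
    unlist(model$loci[[loc]][alleles[[loc]]], use.names = FALSE)
  }), use.names = FALSE))
}

armed_core <- function(model, alleles) {
  all(model$killer %in% components_union(model, alleles))
}

# Pre-selection gamete classes of a diploid genotype: independent assortment,
# 1/2 per allele per locus, identical classes merged. Returns a base list with
# a character matrix of per-locus alleles (rows = classes), merged weights,
# labels, and the gametophytic protection flag per class.
gametes_core <- function(model, alleles) {
  grid <- expand.grid(alleles, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  key <- do.call(paste, c(grid, list(sep = "|")))
  w <- rowsum(rep(1 / nrow(grid), nrow(grid)), key)
  labels <- rownames(w)
  mat <- do.call(rbind, strsplit(labels, "|", fixed = TRUE))
  colnames(mat) <- names(alleles)
  protected <- vapply(seq_len(nrow(mat)), function(i) {
    comps <- unlist(lapply(names(alleles), function(loc) {
      model$loci[[loc]][[mat[i, loc]]]
    }), use.names = FALSE)
    all(model$protector %in% comps)
  }, logical(1))
  list(alleles = mat, label = labels, weight = as.numeric(w),
       protected = protected)
}

# Down-weight unprotected gametes by the abortion probability and renormalise.
select_core <- function(g, armed, abort_prob) {
  w <- g$weight
  if (armed) w <- w * ifelse(g$protected, 1, 1 - abort_prob)
  vf <- sum(w) / sum(g$weight)
  if (vf <= 0) {
    w_norm <- rep(0, length(w))
  } else {
    w_norm <- w / sum(w)
  }
  list(alleles = g$alleles, label = g$label, weight = w_norm,
       protected = g$protected, viable_fraction = vf)
}

# ---- exported surface -------------------------------------------------------

#' Does the sporophyte arm the killer?
#'
#' The killer arms when the union of components carried by both alleles at all
#' loci of the diploid sporophyte contains every killer component. Components
#' from unlinked loci complement in trans: three killer genes split across two
#' transgene insertions still arm.
#'
#' @param genotype A [kp_genotype()].
#' @param model The model to evaluate under; defaults to the genotype's own.
#' @return A single logical.
#' @examples
#' mod <- s1_model()
#' arm_killer(kp_genotype(mod, S1 = c("g", "s")))            # TRUE
#' arm_killer(kp_genotype(mod, S1 = c("s", "s"),
#'                        TPRt = c("T", "-")))               # FALSE
#' @export
arm_killer <- function(genotype, model = genotype$model) {
  stopifnot(inherits(genotype, "kp_genotype"))
  armed_core(model, genotype$alleles)
}

#' Enumerate the gamete classes of a genotype
#'
#' Meiosis with independent assortment: each locus transmits either allele
#' with probability 1/2, giving up to `2^L` gamete classes; identical classes
#' (from homozygous loci) are merged. Weights sum to 1.
#'
#' @param genotype A [kp_genotype()].
#' @return A tibble of class `kp_gametes` with one column per locus, plus
#'   `gamete` (class label), `protected` (does the gamete itself carry all
#'   protector components?) and `weight`. Attribute `stage` is
#'   `"pre_selection"`.
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' enumerate_gametes(f1)
#' @export
enumerate_gametes <- function(genotype) {
  stopifnot(inherits(genotype, "kp_genotype"))
  g <- gametes_core(genotype$model, genotype$alleles)
  out <- as_tibble(as.data.frame(g$alleles, stringsAsFactors = FALSE))
  out$gamete <- g$label
  out$protected <- g$protected
  out$weight <- g$weight
  new_kp_gametes(out, stage = "pre_selection", model = genotype$model,
                 viable_fraction = NA_real_)
}

new_kp_gametes <- function(tbl, stage, model, viable_fraction) {
  structure(tbl,
    class = c("kp_gametes", class(tibble())),
    stage = stage, model = model, viable_fraction = viable_fraction
  )
}

#' Apply gamete viability selection
#'
#' If the killer is not armed the distribution is returned unchanged with a
#' viable fraction of 1. If armed, gametes carrying all protector components
#' keep their weight; every other gamete is down-weighted by the sex-specific
#' abortion probability, and weights are renormalised. The surviving mass as a
#' fraction of the pre-selection mass is stored in the `viable_fraction`
#' attribute (readable with [viable_fraction()]) — it is the predicted
#' fertility contribution of that sex.
#'
#' @param gametes A pre-selection [enumerate_gametes()] tibble.
#' @param killer_armed Logical, usually from [arm_killer()] on the parent.
#' @param model A [kp_model()] supplying protector set and abortion
#'   probabilities; defaults to the model the gametes were generated under.
#' @param sex `"male"` (pollen) or `"female"` (embryo sac).
#' @return A `kp_gametes` tibble with renormalised weights, `stage`
#'   `"post_selection"`.
#' @examples
#' f1 <- kp_genotype(s1_model(), S1 = c("g", "s"), TPRt = c("T", "-"))
#' g <- apply_viability(enumerate_gametes(f1), arm_killer(f1), sex = "male")
#' viable_fraction(g)  # 0.75
#' @export
apply_viability <- function(gametes, killer_armed,
                            model = attr(gametes, "model"),
                            sex = c("male", "female")) {
  stopifnot(inherits(gametes, "kp_gametes"))
  if (!identical(attr(gametes, "stage"), "pre_selection")) {
    abort("`gametes` must be a pre-selection distribution.")
  }
  sex <- match.arg(sex)
  k <- if (sex == "male") model$abort_male else model$abort_female
  # recompute protection under the supplied model (protector set may differ
  # from the one the gametes were enumerated under)
  loci <- intersect(names(model$loci), names(gametes))
  protected <- vapply(seq_len(nrow(gametes)), function(i) {
    comps <- unlist(lapply(loci, function(loc) {
      model$loci[[loc]][[gametes[[loc]][[i]]]]
    }), use.names = FALSE)
    all(model$protector %in% comps)
  }, logical(1))
  g <- list(alleles = NULL, label = gametes$gamete, weight = gametes$weight,
            protected = protected)
  sel <- select_core(g, isTRUE(killer_armed), k)
  out <- gametes
  out$protected <- protected
  out$weight <- sel$weight
  new_kp_gametes(out, stage = "post_selection", model = model,
                 viable_fraction = sel$viable_fraction)
}

#' @rdname apply_viability
#' @export
viable_fraction <- function(gametes) {
  attr(gametes, "viable_fraction")
}

#' Predict pollen and spikelet fertility
#'
#' Fertility of each sex is the viable gamete fraction after killer-protector
#' selection. Spikelet (seed-set) fertility is taken as the female viable
#' fraction, assuming pollen is in excess.
#'
#' @param genotype A [kp_genotype()].
#' @param model Model to predict under; defaults to the genotype's own.
#' @return A one-row tibble with `genotype`, `killer_armed`,
#'   `pollen_fertility`, `female_fertility`, `spikelet_fertility`.
#' @examples
#' mod <- s1_model()
#' # S1 heterozygote, no transgene: semi-sterile (~50%)
#' predict_fertility(kp_genotype(mod, S1 = c("g", "s")))
#' # plus one hemizygous protector transgene copy: ~75%
#' predict_fertility(kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-")))
#' @export
predict_fertility <- function(genotype, model = genotype$model) {
  stopifnot(inherits(genotype, "kp_genotype"))
  armed <- armed_core(model, genotype$alleles)
  g <- gametes_core(model, genotype$alleles)
  vf_m <- select_core(g, armed, model$abort_male)$viable_fraction
  vf_f <- select_core(g, armed, model$abort_female)$viable_fraction
  tibble(
    genotype = genotype_label(genotype),
    killer_armed = armed,
    pollen_fertility = vf_m,
    female_fertility = vf_f,
    spikelet_fertility = vf_f
  )
}
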