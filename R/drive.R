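#' Construct a population state for drive simulations
#'
#' A population is a distribution over diploid genotype classes of the model's
#' loci. Class labels follow the cross engine's convention: per-locus `a1/a2`
#' labels joined with `|` across loci (for a single-locus model just
#' `"g/s"` etc.).
#'
#' @param model A [kp_model()].
#' @param freqs Named numeric vector of genotype-class frequencies; normalised
#'   to sum to 1.
#' @param generation Generation index of this state (0 = founding).
#' @return A tibble of class `kp_population` with `generation`, `class`,
#'   `freq`.
#' @examples
#' kp_population(s1_model(transgenes = character(0)), c("g/s" = 1))
#' @export
kp_population <- function(model, freqs, generation = 0L) {
  stopifnot(inherits(model, "kp_model"))
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) {
    abort("`freqs` must be named by genotype class.")
  }
  if (any(freqs < 0) || sum(freqs) <= 0) {
    abort("Frequencies must be non-negative with positive total.")
  }
  # validate classes by parsing them into genotypes
  lapply(names(freqs), function(cl) class_to_genotype(model, cl))
  structure(
    tibble(generation = as.integer(generation), class = names(freqs),
           freq = as.numeric(freqs) / sum(freqs)),
    class = c("kp_population", class(tibble())),
    model = model
  )
}

# Parse a combined class label back into a kp_genotype.
class_to_genotype <- function(model, label) {
  per_locus <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(per_locus) != length(model$loci)) {
    abort(sprintf("Class '%s' does not match the model's %d locus/loci.",
                  label, length(model$loci)))
  }
  spec <- lapply(per_locus, function(x) strsplit(x, "/", fixed = TRUE)[[1]])
  names(spec) <- names(model$loci)
  do.call(kp_genotype, c(list(model), spec))
}

# Expected next-generation class frequencies (deterministic, infinite
# population). Selfing unites gametes within individuals, each parent
# contributing seed in proportion to its female viable-gamete fraction.
# Random mating pools male and female gamete clouds across the population,
# each individual's cloud weighted by frequency x surviving gamete mass.
next_gen_probs <- function(model, freqs, mating = c("selfing",
                                                    "random_mating")) {
  mating <- match.arg(mating)
  classes <- names(freqs)
  genos <- lapply(classes, class_to_genotype, model = model)
  if (mating == "selfing") {
    acc <- list()
    total <- 0
    for (i in seq_along(genos)) {
      if (freqs[[i]] == 0) next
      design <- cross_design(model, genos[[i]]$alleles, genos[[i]]$alleles)
      fec <- select_core(design$female, design$armed_female,
                         model$abort_female)$viable_fraction
      w <- freqs[[i]] * fec
      if (w == 0) next
      p <- design_probs(design)
      acc[[length(acc) + 1L]] <- w * p
      total <- total + w
    }
    if (total == 0) abort("Population produced no viable seed.")
    all_classes <- sort(unique(unlist(lapply(acc, names))))
    out <- setNames(numeric(length(all_classes)), all_classes)
    for (p in acc) out[names(p)] <- out[names(p)] + p
    out / total
  } else {
    pool <- function(sex) {
      cloud <- list()
      for (i in seq_along(genos)) {
        if (freqs[[i]] == 0) next
        g <- gametes_core(model, genos[[i]]$alleles)
        armed <- armed_core(model, genos[[i]]$alleles)
        k <- if (sex == "male") model$abort_male else model$abort_female
        sel <- select_core(g, armed, k)
        # un-normalised surviving mass: fertile individuals contribute more
        w <- freqs[[i]] * sel$viable_fraction * sel$weight
        cloud[[length(cloud) + 1L]] <-
          list(alleles = g$alleles, label = g$label, weight = w)
      }
      labels <- unlist(lapply(cloud, `[[`, "label"))
      weights <- unlist(lapply(cloud, `[[`, "weight"))
      alleles <- do.call(rbind, lapply(cloud, `[[`, "alleles"))
      agg <- rowsum(weights, labels)
      keep <- match(rownames(agg), labels)
      list(alleles = alleles[keep, , drop = FALSE],
           weight = as.numeric(agg) / sum(agg))
    }
    fp <- pool("female")
    mp <- pool("male")
    loci <- names(model$loci)
    out <- list()
    for (i in seq_len(nrow(fp$alleles))) {
      for (j in seq_len(nrow(mp$alleles))) {
        lab <- paste(vapply(loci, function(loc) {
          paste(sort_alleles(c(fp$alleles[i, loc], mp$alleles[j, loc])),
                collapse = "/")
        }, character(1)), collapse = "|")
        out[[lab]] <- (out[[lab]] %||% 0) + fp$weight[i] * mp$weight[j]
      }
    }
    out <- unlist(out)
    out[sort(names(out))]
  }
}

#' Advance a population one generation (deterministic)
#'
#' Infinite-population update: every individual produces gametes, viability
#' selection removes unprotected gametes of armed parents, and offspring are
#' formed by selfing (default; gametes unite within individuals, seed output
#' proportional to the female viable fraction) or random mating (pooled gamete
#' clouds).
#'
#' @param state A [kp_population()].
#' @param model Model to step under; defaults to the state's.
#' @param mating `"selfing"` or `"random_mating"`.
#' @return A `kp_population` at `generation + 1`.
#' @examples
#' pop <- kp_population(s1_model(abort = 0.95, transgenes = character(0)),
#'                      c("g/s" = 1))
#' deterministic_step(pop)
#' @export
deterministic_step <- function(state, model = attr(state, "model"),
                               mating = c("selfing", "random_mating")) {
  stopifnot(inherits(state, "kp_population"))
  mating <- match.arg(mating)
  freqs <- setNames(state$freq, state$class)
  p <- next_gen_probs(model, freqs, mating)
  kp_population(model, p, generation = max(state$generation) + 1L)
}

#' Run a multi-generation deterministic drive trajectory
#'
#' Iterates [deterministic_step()] from a founding state. When the abortion
#' probability is positive and the driver allele carries the protector, the
#' driver frequency is non-decreasing along the trajectory.
#'
#' @inheritParams deterministic_step
#' @param generations Number of generations to advance (>= 0).
#' @return A tibble of class `kp_trajectory` with `generation`, `class`,
#'   `freq` for generations `0..generations`. Attribute `mating` records the
#'   mating system.
#' @examples
#' pop <- kp_population(s1_model(abort = 0.95, transgenes = character(0)),
#'                      c("g/s" = 1))
#' traj <- run_trajectory(pop, generations = 5)
#' driver_frequency(traj, "S1", "g")
#' @export
run_trajectory <- function(state, generations,
                           model = attr(state, "model"),
                           mating = c("selfing", "random_mating")) {
  stopifnot(inherits(state, "kp_population"), generations >= 0)
  mating <- match.arg(mating)
  states <- vector("list", generations + 1L)
  states[[1]] <- state
  cur <- state
  for (g in seq_len(generations)) {
    cur <- deterministic_step(cur, model, mating)
    states[[g + 1L]] <- cur
  }
  out <- dplyr::bind_rows(lapply(states, as_tibble))
  structure(out,
    class = c("kp_trajectory", class(tibble())),
    model = model, mating = mating, mode = "deterministic"
  )
}

#' Wright-Fisher stochastic drive simulation
#'
#' Finite-population counterpart of [run_trajectory()]: each generation, `N`
#' offspring genotypes are drawn multinomially from the deterministic
#' expectation given the current genotype frequencies. Replicate `r` uses
#' `seed + r - 1`, so runs are reproducible and replicates independent.
#'
#' @inheritParams run_trajectory
#' @param N Population size (>= 1).
#' @param seed Integer random seed.
#' @param replicates Number of independent replicate populations.
#' @return A `kp_trajectory` tibble with an extra `replicate` column and
#'   `mode = "wright_fisher"`.
#' @examples
#' pop <- kp_population(s1_model(abort = 0.5, transgenes = character(0)),
#'                      c("g/s" = 1))
#' wright_fisher_sim(pop, generations = 3, N = 100, seed = 1, replicates = 2)
#' @export
wright_fisher_sim <- function(state, generations, N, seed, replicates = 1,
                              model = attr(state, "model"),
                              mating = c("selfing", "random_mating")) {
  stopifnot(inherits(state, "kp_population"), N >= 1, generations >= 0)
  mating <- match.arg(mating)
  runs <- purrr::map_dfr(seq_len(replicates), function(r) {
    set.seed(as.integer(seed) + r - 1L)
    freqs <- setNames(state$freq, state$class)
    rows <- list(tibble(replicate = r, generation = 0L,
                        class = names(freqs), freq = unname(freqs)))
    for (g in seq_len(generations)) {
      p <- next_gen_probs(model, freqs, mating)
      draw <- as.integer(rmultinom(1, N, p))
      freqs <- setNames(draw / N, names(p))
      freqs <- freqs[freqs > 0]
      rows[[g + 1L]] <- tibble(replicate = r, generation = g,
                               class = names(freqs), freq = unname(freqs))
    }
    dplyr::bind_rows(rows)
  })
  structure(runs,
    class = c("kp_trajectory", class(tibble())),
    model = model, mating = mating, mode = "wright_fisher", N = N, seed = seed
  )
}

#' Driver allele frequency along a trajectory
#'
#' @param trajectory A [run_trajectory()] or [wright_fisher_sim()] result.
#' @param locus,allele Locus and allele to track.
#' @return A tibble with `generation` (and `replicate` for stochastic runs)
#'   and `freq` of the allele.
#' @export
driver_frequency <- function(trajectory, locus, allele) {
  stopifnot(inherits(trajectory, "kp_trajectory"))
  model <- attr(trajectory, "model")
  i <- match(locus, names(model$loci))
  if (is.na(i)) abort(sprintf("Unknown locus '%s'.", locus))
  tbl <- as_tibble(trajectory)
  part <- vapply(strsplit(tbl$class, "|", fixed = TRUE), `[[`,
                 character(1), i)
  dos <- vapply(strsplit(part, "/", fixed = TRUE),
                function(a) sum(a == allele), numeric(1))
  tbl$dosage <- dos
  keys <- intersect(c("replicate", "generation"), names(tbl))
  tbl %>%
    group_by(across(all_of(keys))) %>%
    summarise(freq = sum(.data$dosage / 2 * .data$freq), .groups = "drop")
}

#' Export a trajectory as TSV
#'
#' @param trajectory A `kp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  readr::write_tsv(as_tibble(trajectory), path)
  invisible(path)
}
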