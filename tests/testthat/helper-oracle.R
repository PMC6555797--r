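# Independent brute-force oracle for cross predictions: enumerates every
# ordered gamete tuple of each parent with explicit loops (no merging, no
# shared code with the package's cross engine), applies viability weights
# gamete by gamete, and accumulates progeny class probabilities over all
# ordered gamete pairs.

oracle_gametes <- function(model, geno) {
  loci <- names(geno)
  n_loci <- length(loci)
  idx <- rep(1L, n_loci)
  out <- list()
  repeat {
    alleles <- character(n_loci)
    for (i in seq_len(n_loci)) alleles[i] <- geno[[i]][idx[i]]
    names(alleles) <- loci
    out[[length(out) + 1L]] <- alleles
    # odometer increment over {1,2}^L
    j <- 1L
    while (j <= n_loci) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 2L) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n_loci) break
  }
  out
}

oracle_union <- function(model, loci_alleles) {
  comps <- character(0)
  for (loc in names(loci_alleles)) {
    for (a in loci_alleles[[loc]]) {
      comps <- c(comps, model$loci[[loc]][[a]])
    }
  }
  unique(comps)
}

oracle_armed <- function(model, geno) {
  u <- oracle_union(model, geno)
  all(model$killer %in% u)
}

oracle_gamete_weights <- function(model, geno, k) {
  gams <- oracle_gametes(model, geno)
  armed <- oracle_armed(model, geno)
  w <- numeric(length(gams))
  for (i in seq_along(gams)) {
    w[i] <- 0.5^length(geno)
    if (armed) {
      comps <- character(0)
      for (loc in names(gams[[i]])) {
        comps <- c(comps, model$loci[[loc]][[gams[[i]][[loc]]]])
      }
      if (!all(model$protector %in% unique(comps))) {
        w[i] <- w[i] * (1 - k)
      }
    }
  }
  s <- sum(w)
  if (s > 0) w <- w / s else w[] <- 0
  list(gametes = gams, weights = w)
}

oracle_cross <- function(model, mother, father) {
  fem <- oracle_gamete_weights(model, mother, model$abort_female)
  mal <- oracle_gamete_weights(model, father, model$abort_male)
  acc <- new.env()
  for (i in seq_along(fem$gametes)) {
    for (j in seq_along(mal$gametes)) {
      labels <- character(length(mother))
      for (l in seq_along(mother)) {
        loc <- names(mother)[l]
        pair <- c(fem$gametes[[i]][[loc]], mal$gametes[[j]][[loc]])
        pair <- pair[order(pair == "-", pair, method = "radix")]
        labels[l] <- paste(pair, collapse = "/")
      }
      key <- paste(labels, collapse = "|")
      prev <- if (is.null(acc[[key]])) 0 else acc[[key]]
      acc[[key]] <- prev + fem$weights[i] * mal$weights[j]
    }
  }
  keys <- sort(ls(acc))
  stats::setNames(vapply(keys, function(k) acc[[k]], numeric(1)), keys)
}

# Random model + genotype pair generator for property tests.
random_cross_case <- function() {
  pool <- LETTERS[1:6]
  n_loci <- sample(1:3, 1)
  loci <- list()
  for (i in seq_len(n_loci)) {
    n_all <- sample(2:3, 1)
    alleles <- list()
    for (a in seq_len(n_all)) {
      size <- sample(0:3, 1)
      alleles[[paste0("a", i, a)]] <-
        if (size == 0) character(0) else sample(pool, size)
    }
    loci[[paste0("L", i)]] <- alleles
  }
  model <- kp_model(
    loci,
    killer = sample(pool, sample(1:3, 1)),
    protector = sample(pool, sample(1:2, 1)),
    abort_male = stats::runif(1),
    abort_female = stats::runif(1)
  )
  pick <- function() {
    spec <- lapply(model$loci, function(a) sample(names(a), 2, replace = TRUE))
    do.call(kp_genotype, c(list(model), spec))
  }
  list(model = model, mother = pick(), father = pick())
}

# Monte-Carlo multinomial reference p-value for the Pearson statistic.
mc_chisq_pvalue <- function(counts, probs, reps = 10000, seed = 42) {
  set.seed(seed)
  n <- sum(counts)
  expected <- n * probs
  stat_obs <- sum((counts - expected)^2 / expected)
  sims <- stats::rmultinom(reps, n, probs)
  stats <- colSums((sims - expected)^2 / expected)
  mean(stats >= stat_obs - 1e-9)
}
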