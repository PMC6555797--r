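#' Construct an observed genotype-class count table
#'
#' @param locus Locus name.
#' @param counts Named non-negative integer vector, names are diploid class
#'   labels (e.g. `c("g/g" = 35, "g/s" = 41, "s/s" = 10)`).
#' @return A tibble of class `kp_counts` with `locus`, `class`, `count`.
#' @export
observed_counts <- function(locus, counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be a named vector of class counts.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(counts) <= 0) abort("Total count must be positive.")
  structure(
    tibble(locus = locus, class = names(counts),
           count = as.integer(counts)),
    class = c("kp_counts", class(tibble()))
  )
}

#' Read / write observed count tables as TSV
#'
#' The TSV dialect has columns `locus`, `class`, `count`.
#'
#' @param path File path.
#' @param locus Optional locus to filter to on read.
#' @return `read_counts_tsv()` returns a `kp_counts` tibble.
#' @export
read_counts_tsv <- function(path, locus = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    locus = readr::col_character(),
    class = readr::col_character(),
    count = readr::col_integer()
  ))
  if (!is.null(locus)) tbl <- dplyr::filter(tbl, .data$locus == !!locus)
  if (nrow(tbl) == 0L) abort("No counts found.")
  structure(tbl, class = c("kp_counts", class(tibble())))
}

#' @rdname read_counts_tsv
#' @param counts A `kp_counts` tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

align_expected <- function(observed, expected_probs) {
  obs <- as_tibble(observed)
  if (!all(c("class", "count") %in% names(obs))) {
    abort("`observed` needs `class` and `count` columns.")
  }
  if (is.data.frame(expected_probs)) {
    expected_probs <- setNames(expected_probs$prob, expected_probs$class)
  }
  if (is.null(names(expected_probs))) {
    if (length(expected_probs) != nrow(obs)) {
      abort("Unnamed `expected_probs` must match the observed classes.")
    }
    names(expected_probs) <- obs$class
  }
  # classes present in only one table get probability/count 0 on the other side
  classes <- union(obs$class, names(expected_probs))
  count <- setNames(rep(0L, length(classes)), classes)
  count[obs$class] <- obs$count
  prob <- setNames(rep(0, length(classes)), classes)
  prob[names(expected_probs)] <- expected_probs
  if (any(prob < 0)) abort("Expected probabilities must be non-negative.")
  s <- sum(prob)
  if (s <= 0) abort("Expected probabilities must not all be zero.")
  list(classes = classes, count = count, prob = prob / s)
}

#' Chi-square goodness of fit of observed segregation to model expectations
#'
#' Pearson chi-square test of observed genotype-class counts against expected
#' proportions (typically from [expected_class_probs()], or a ratio such as
#' `c(1, 2, 1)`). Classes with expected probability 0 and observed count 0 are
#' dropped before computing the degrees of freedom; an observed count in a
#' zero-probability class contradicts the model outright and raises an error
#' (refit with an abortion probability below 1 instead). No continuity
#' correction is applied.
#'
#' @param observed A [observed_counts()] tibble (or any tibble with `class`
#'   and `count`).
#' @param expected_probs Named probability vector, unnamed vector aligned with
#'   the observed classes (ratios allowed; they are normalised), or a tibble
#'   with `class` and `prob`.
#' @return An object of class `kp_gof`: list with `statistic`, `df`,
#'   `p_value`, and a `table` tibble of per-class observed and expected
#'   counts. Has [tidy()] and [glance()] methods.
#' @examples
#' obs <- observed_counts("S1", c("g/g" = 60, "g/s" = 30, "s/s" = 10))
#' chi_square_gof(obs, c("g/g" = 1, "g/s" = 2, "s/s" = 1))
#' @export
chi_square_gof <- function(observed, expected_probs) {
  al <- align_expected(observed, expected_probs)
  n <- sum(al$count)
  if (n <= 0) abort("Total observed count must be positive.")
  contradiction <- al$prob == 0 & al$count > 0
  if (any(contradiction)) {
    abort(sprintf(
      paste0("Observed counts in class(es) the model assigns probability 0: ",
             "%s. The model is contradicted; consider an abortion ",
             "probability below 1."),
      paste(al$classes[contradiction], collapse = ", ")
    ))
  }
  keep <- al$prob > 0
  expected <- n * al$prob[keep]
  statistic <- sum((al$count[keep] - expected)^2 / expected)
  df <- sum(keep) - 1L
  p <- if (df == 0L) 1 else pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(
      statistic = statistic, df = df, p_value = p, n = n,
      table = tibble(
        class = al$classes[keep],
        observed = unname(al$count[keep]),
        expected = unname(expected),
        prob = unname(al$prob[keep])
      )
    ),
    class = "kp_gof"
  )
}

#' @export
print.kp_gof <- function(x, ...) {
  cat(sprintf(
    "Chi-square goodness of fit: X^2 = %.4g, df = %d, p = %.4g (n = %d)\n",
    x$statistic, x$df, x$p_value, x$n
  ))
  print(x$table)
  invisible(x)
}

#' @export
tidy.kp_gof <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value, n = x$n)
}

#' @export
glance.kp_gof <- function(x, ...) tidy.kp_gof(x)

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Transmission ratio of an allele from observed diploid counts
#'
#' Allele frequency among progeny, `sum(dosage * count) / (2n)`, with a Wilson
#' 95% score interval on the allele-copy proportion. Dosage (0, 1 or 2 copies)
#' is parsed from the `a1/a2` class labels. Frequencies far from 0.5 for a
#' heterozygous parent indicate transmission ratio distortion.
#'
#' @param observed A [observed_counts()] tibble.
#' @param allele Allele name to track.
#' @param conf Confidence level.
#' @return A one-row tibble: `allele`, `frequency`, `conf_low`, `conf_high`,
#'   `n` (individuals).
#' @examples
#' obs <- observed_counts("TPRt", c("T/T" = 758, "T/-" = 242))
#' transmission_ratio(obs, "T")  # 0.879
#' @export
transmission_ratio <- function(observed, allele, conf = 0.95) {
  obs <- as_tibble(observed)
  alleles <- strsplit(obs$class, "/", fixed = TRUE)
  if (!allele %in% unlist(alleles)) {
    abort(sprintf("Allele '%s' does not occur in the observed classes.",
                  allele))
  }
  dosage <- vapply(alleles, function(a) sum(a == allele), numeric(1))
  n <- sum(obs$count)
  copies <- sum(dosage * obs$count)
  ci <- wilson_ci(copies, 2 * n, conf)
  tibble(
    allele = allele,
    frequency = copies / (2 * n),
    conf_low = unname(ci["low"]),
    conf_high = unname(ci["high"]),
    n = n
  )
}

#' Estimate the gamete abortion probability by maximum likelihood
#'
#' Inverts the forward cross model: for a given cross design the expected
#' class probabilities at the scored locus are a function of the abortion
#' probability `k` (applied to both sexes); the multinomial likelihood of the
#' observed counts is maximised over `k` in \[0, 1\] by Brent optimisation
#' (tolerance 1e-8), and a profile-likelihood 95% confidence interval is
#' obtained from the chi-square(1) cutoff. Designs whose class probabilities
#' do not depend on `k` (e.g. no killer present) are rejected as
#' non-identifiable.
#'
#' @param observed A [observed_counts()] tibble for `locus`.
#' @param mother,father Parental [kp_genotype()]s of the cross that produced
#'   the progeny.
#' @param locus Locus the counts are scored at; defaults to the locus named in
#'   `observed`.
#' @param model Model defining the cross; defaults to the mother's. Its abort
#'   probabilities are ignored (k is the free parameter, equal in both sexes).
#' @param conf Confidence level for the profile interval.
#' @return An object of class `kp_kest`: list with `k_hat`, `log_likelihood`,
#'   `ci` (length-2), `conf`, `n`. Has [tidy()]/[glance()] methods.
#' @examples
#' mod <- s1_model()
#' f1 <- kp_genotype(mod, A4A6t = c("46", "-"), TPRt = c("T", "-"))
#' obs <- observed_counts("TPRt", c("T/T" = 379, "T/-" = 111, "-/-" = 10))
#' estimate_killing_efficiency(obs, f1, f1)
#' @export
estimate_killing_efficiency <- function(observed, mother, father = mother,
                                        locus = NULL, model = mother$model,
                                        conf = 0.95) {
  obs <- as_tibble(observed)
  if (is.null(locus)) {
    locus <- unique(obs$locus)
    if (length(locus) != 1L) {
      abort("`observed` must cover exactly one locus (or pass `locus`).")
    }
  }
  design <- cross_design(model, mother$alleles, father$alleles)
  probs_k <- function(k) {
    marginal_core(design_probs(design, abort_female = k, abort_male = k),
                  design$loci, locus)
  }
  # identifiability: class probabilities must vary with k
  grid <- seq(0, 1, length.out = 5)
  pgrid <- vapply(grid, probs_k, probs_k(0))
  if (max(abs(pgrid - pgrid[, 1])) < 1e-10) {
    abort(paste0("Non-identifiable design: class probabilities at locus '",
                 locus, "' do not depend on the abortion probability."))
  }
  counts <- setNames(obs$count, obs$class)
  n <- sum(counts)
  if (n <= 0) abort("Total observed count must be positive.")
  loglik <- function(k) {
    p <- probs_k(k)
    missing_classes <- setdiff(names(counts), names(p))
    if (length(missing_classes) && any(counts[missing_classes] > 0)) {
      return(-1e12)
    }
    p <- p[names(counts)]
    p[is.na(p)] <- 0
    if (any(p == 0 & counts > 0)) return(-1e12)
    sum(counts[counts > 0] * log(p[counts > 0]))
  }
  opt <- optimize(loglik, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(
    c(opt$maximum, opt$objective),
    c(0, loglik(0)),
    c(1, loglik(1))
  )
  best <- cand[which.max(cand[, 2]), ]
  k_hat <- best[[1]]
  ll_max <- best[[2]]
  # profile-likelihood interval: { k : 2(ll_max - ll(k)) <= qchisq(conf, 1) }
  cut <- ll_max - qchisq(conf, 1) / 2
  lo <- if (loglik(0) >= cut) 0 else {
    uniroot(function(k) loglik(k) - cut, c(0, k_hat), tol = 1e-8)$root
  }
  hi <- if (loglik(1) >= cut) 1 else {
    uniroot(function(k) loglik(k) - cut, c(k_hat, 1), tol = 1e-8)$root
  }
  structure(
    list(k_hat = k_hat, log_likelihood = ll_max, ci = c(lo, hi), conf = conf,
         n = n, locus = locus),
    class = "kp_kest"
  )
}

#' @export
print.kp_kest <- function(x, ...) {
  cat(sprintf(
    "Killing efficiency (locus %s): k_hat = %.4f, %d%% CI [%.4f, %.4f], logL = %.3f, n = %d\n",
    x$locus, x$k_hat, round(100 * x$conf), x$ci[1], x$ci[2],
    x$log_likelihood, x$n
  ))
  invisible(x)
}

#' @export
tidy.kp_kest <- function(x, ...) {
  tibble(k_hat = x$k_hat, conf_low = x$ci[1], conf_high = x$ci[2],
         log_likelihood = x$log_likelihood, n = x$n)
}

#' @export
glance.kp_kest <- function(x, ...) tidy.kp_kest(x)
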