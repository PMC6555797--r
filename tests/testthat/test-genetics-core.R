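# Killer arming, gamete enumeration, viability selection, fertility and
# cross predictions for the canonical S1 configuration and random models.

test_that("killer arms on the sporophyte component union, in trans", {
  mod <- s1_model()
  cases <- list(
    # genotype spec, expected armed
    list(list(S1 = c("g", "s")), TRUE),                       # RP-s x NIL-g F1
    list(list(S1 = c("s", "s"), TPRt = c("T", "-")), FALSE),  # one transgene
    list(list(S1 = c("s", "s"), A4A6t = c("46", "-"),
              TPRt = c("T", "-")), TRUE),                     # three in trans
    list(list(S1 = c("gm4", "s")), FALSE),                    # A4 knocked out
    list(list(S1 = c("gm", "s"), TPRt = c("T", "-")), TRUE),  # TPR from trans
    list(list(S1 = c("s", "s")), FALSE)
  )
  for (case in cases) {
    geno <- do.call(kp_genotype, c(list(mod), case[[1]]))
    expect_identical(arm_killer(geno), case[[2]])
  }
  expect_error(kp_genotype(mod, S1 = c("g", "zzz")), "unknown allele")
})

test_that("gamete enumeration gives 2^L merged classes summing to 1", {
  mod <- s1_model()
  het <- kp_genotype(mod, S1 = c("g", "s"))
  g1 <- enumerate_gametes(het)
  expect_setequal(g1$S1, c("g", "s"))
  expect_equal(g1$weight, c(0.5, 0.5))

  f1 <- kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-"))
  g2 <- enumerate_gametes(f1)
  expect_equal(nrow(g2), 4L)
  expect_equal(g2$weight, rep(0.25, 4))
  expect_equal(sum(g2$weight), 1)

  hom <- kp_genotype(mod, S1 = c("g", "g"))
  g3 <- enumerate_gametes(hom)
  expect_equal(nrow(g3), 1L)
  expect_equal(g3$weight, 1)
  expect_identical(attr(g3, "stage"), "pre_selection")
})

test_that("viability selection protects gametes carrying the protector", {
  mod <- s1_model(transgenes = "TPRt")
  f1 <- kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-"))
  pre <- enumerate_gametes(f1)

  post <- apply_viability(pre, killer_armed = TRUE, sex = "male")
  expect_identical(attr(post, "stage"), "post_selection")
  expect_equal(viable_fraction(post), 0.75)
  surviving <- setNames(post$weight, post$gamete)
  expect_equal(unname(surviving[c("g|T", "g|-", "s|T")]), rep(1 / 3, 3))
  expect_equal(unname(surviving["s|-"]), 0)

  # not armed: unchanged, viable fraction 1
  same <- apply_viability(pre, killer_armed = FALSE, sex = "female")
  expect_equal(same$weight, pre$weight)
  expect_equal(viable_fraction(same), 1)

  # partial killing: k = 0.851 on a protected/unprotected half-half pool
  mod_k <- s1_model(abort = 0.851)
  d <- kp_genotype(mod_k, S1 = c("s", "s"), A4A6t = c("46", "46"),
                   TPRt = c("T", "-"))
  gam <- enumerate_gametes(d)
  post_k <- apply_viability(gam, killer_armed = TRUE, sex = "male")
  expect_equal(viable_fraction(post_k), 0.5 + 0.5 * 0.149)
  t_weight <- sum(post_k$weight[post_k$TPRt == "T"])
  expect_equal(t_weight, 0.5 / (0.5 + 0.5 * 0.149), tolerance = 1e-12)
})

test_that("fertility predictions reproduce the hybrid fertility series", {
  mod <- s1_model()
  fert <- function(...) {
    predict_fertility(kp_genotype(mod, ...))$pollen_fertility
  }
  expect_equal(fert(S1 = c("g", "s")), 0.5)                      # semi-sterile
  expect_equal(fert(S1 = c("g", "s"), TPRt = c("T", "-")), 0.75) # rescued
  expect_equal(fert(S1 = c("g", "s"), TPRt = c("T", "T")), 1)    # fully fertile
  expect_equal(fert(S1 = c("g", "g")), 1)    # armed but all gametes protected
  expect_equal(fert(S1 = c("s", "s")), 1)    # killer never arms
  # pollen and spikelet fertility agree under equal-sex abortion
  p <- predict_fertility(kp_genotype(mod, S1 = c("g", "s")))
  expect_equal(p$pollen_fertility, p$spikelet_fertility)
  # no killing at abort 0
  mod0 <- s1_model(abort = 0)
  expect_equal(
    predict_fertility(kp_genotype(mod0, S1 = c("g", "s")))$pollen_fertility, 1
  )
})

test_that("cross predictions reproduce the printed segregation models", {
  mod <- s1_model()

  # protector-transgene x driver cross, selfed F1: 4:4:1 at both loci
  f1 <- kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-"))
  pr <- cross_progeny(f1)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
  s1 <- marginal_locus(pr, "S1")
  expect_equal(setNames(s1$prob, s1$class),
               c("g/g" = 4 / 9, "g/s" = 4 / 9, "s/s" = 1 / 9),
               tolerance = 1e-12)
  tpr <- marginal_locus(pr, "TPRt")
  expect_equal(setNames(tpr$prob, tpr$class),
               c("-/-" = 1 / 9, "T/-" = 4 / 9, "T/T" = 4 / 9),
               tolerance = 1e-12)

  # killer-knockout heterozygote: 1:2:1 at S1, transgene fixed
  f1m <- kp_genotype(mod, S1 = c("gm", "s"), TPRt = c("T", "-"))
  prm <- cross_progeny(f1m)
  s1m <- marginal_locus(prm, "S1")
  expect_equal(setNames(s1m$prob, s1m$class),
               c("gm/gm" = 1 / 4, "gm/s" = 1 / 2, "s/s" = 1 / 4),
               tolerance = 1e-12)
  tprm <- marginal_locus(prm, "TPRt")
  expect_equal(tprm$prob[tprm$class == "T/T"], 1, tolerance = 1e-12)

  # two unlinked transgenes: killer locus Mendelian, protector locus distorted
  d <- kp_genotype(mod, S1 = c("s", "s"), A4A6t = c("46", "-"),
                   TPRt = c("T", "-"))
  prd <- cross_progeny(d)
  a46 <- marginal_locus(prd, "A4A6t")
  expect_equal(setNames(a46$prob, a46$class),
               c("-/-" = 1 / 4, "46/-" = 1 / 2, "46/46" = 1 / 4),
               tolerance = 1e-12)
  tprd <- marginal_locus(prd, "TPRt")
  expect_equal(tprd$prob[tprd$class == "T/T"], 1, tolerance = 1e-12)

  # Mendelian limit at abort 0
  mod0 <- s1_model(abort = 0)
  f10 <- kp_genotype(mod0, S1 = c("g", "s"), TPRt = c("T", "-"))
  for (loc in c("S1", "TPRt")) {
    m <- marginal_locus(cross_progeny(f10), loc)
    expect_equal(sort(m$prob), c(0.25, 0.25, 0.5), tolerance = 1e-12)
  }
})

test_that("allele frequencies are dosage-weighted sums over classes", {
  mod <- s1_model()
  f1 <- kp_genotype(mod, S1 = c("g", "s"), TPRt = c("T", "-"))
  pr <- cross_progeny(f1)
  expect_equal(allele_frequency(pr, "S1", "g"), 2 / 3, tolerance = 1e-12)
  hom <- cross_progeny(kp_genotype(mod, S1 = c("g", "g")))
  expect_equal(allele_frequency(hom, "S1", "g"), 1)
  mend <- cross_progeny(kp_genotype(s1_model(abort = 0), S1 = c("g", "s")))
  expect_equal(allele_frequency(mend, "S1", "g"), 0.5)
  expect_error(allele_frequency(pr, "S1", "zzz"), "does not occur")
})

test_that("cross_progeny matches brute-force enumeration on random cases", {
  set.seed(20260101)
  for (rep in 1:100) {
    case <- random_cross_case()
    got <- cross_progeny(case$mother, case$father, case$model)
    expected <- oracle_cross(case$model, case$mother$alleles,
                             case$father$alleles)
    got_vec <- setNames(got$prob, got$class)
    expect_equal(sort(names(got_vec)), sort(names(expected)))
    expect_equal(got_vec[names(expected)], expected, tolerance = 1e-12)
  }
})

test_that("model invariants hold over randomized genotypes", {
  set.seed(4242)
  for (rep in 1:25) {
    case <- random_cross_case()
    pr <- cross_progeny(case$mother, case$father, case$model)
    expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
    gam <- enumerate_gametes(case$mother)
    expect_equal(sum(gam$weight), 1, tolerance = 1e-12)
    post <- apply_viability(gam, arm_killer(case$mother), case$model, "male")
    expect_equal(sum(post$weight), 1, tolerance = 1e-12)

    # symmetry under equal-sex abortion
    model_eq <- case$model
    model_eq$abort_female <- model_eq$abort_male
    ab <- cross_progeny(case$mother, case$father, model_eq)
    ba <- cross_progeny(case$father, case$mother, model_eq)
    expect_equal(setNames(ab$prob, ab$class)[sort(ab$class)],
                 setNames(ba$prob, ba$class)[sort(ba$class)],
                 tolerance = 1e-12)
  }
})

test_that("fertility is monotone non-increasing in the abortion probability", {
  genos <- list(
    list(S1 = c("g", "s")),
    list(S1 = c("g", "s"), TPRt = c("T", "-")),
    list(S1 = c("s", "s"), A4A6t = c("46", "-"), TPRt = c("T", "-")),
    list(S1 = c("g", "g"))
  )
  ks <- seq(0, 1, by = 0.1)
  for (spec in genos) {
    ferts <- vapply(ks, function(k) {
      mod <- s1_model(abort = k)
      predict_fertility(do.call(kp_genotype, c(list(mod),
                                               spec)))$pollen_fertility
    }, numeric(1))
    expect_true(all(diff(ferts) <= 1e-12))
  }
  # homozygote whose every allele carries the protector stays fully fertile
  for (k in ks) {
    mod <- s1_model(abort = k)
    expect_equal(
      predict_fertility(kp_genotype(mod, S1 = c("g", "g")))$pollen_fertility,
      1
    )
  }
})
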