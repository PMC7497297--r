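# Adduct m/z arithmetic and isotopologue generation.

rules <- default_adduct_rules()
rule_by_name <- function(nm) rules[match(nm, rules$name), ]

test_that("adduct_mz reproduces charge-corrected reference values", {
  expect_equal(adduct_mz(0, rule_by_name("[M+H]+")), 1.0072765,
               tolerance = 1e-6)
  expect_equal(adduct_mz(263.1117352, rule_by_name("[M+H]+")), 264.1190117,
               tolerance = 1e-6)
  expect_equal(adduct_mz(18.0105646, rule_by_name("[M-H]-")), 17.0032935,
               tolerance = 1e-6)
  # removal rule on a tiny mass: discarded with a warning
  expect_warning(res <- adduct_mz(0.5, rule_by_name("[M-H]-")), "discarded")
  expect_true(is.na(res))
})

test_that("default rule set has >= 20 uniquely named rules in both polarities", {
  expect_gte(nrow(rules), 20)
  expect_false(anyDuplicated(rules$name) > 0)
  expect_setequal(unique(rules$polarity), c("+", "-"))
  expect_true(all(rules$x >= 1), all(rules$z >= 1))
})

test_that("adduct_mz is affine in M with slope x/z", {
  set.seed(7)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    M <- runif(1, 100, 500); delta <- runif(1, 0.5, 50)
    expect_equal(adduct_mz(M + delta, r) - adduct_mz(M, r),
                 r$x * delta / r$z, tolerance = 1e-10)
  }
})

test_that("neutral_mass_from_mz inverts adduct_mz for every default rule", {
  set.seed(8)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    M <- runif(3, 80, 600)
    expect_equal(neutral_mass_from_mz(adduct_mz(M, r), r), M,
                 tolerance = 1e-9)
    # and the other composition order, at random m/z
    mz <- runif(3, 200, 600)
    expect_equal(adduct_mz(neutral_mass_from_mz(mz, r), r), mz,
                 tolerance = 1e-9)
  }
})

test_that("isotopologues shift by k*delta/z and follow the binomial ratio", {
  f <- parse_formula("C9H17N3O6")
  specs <- default_isotope_specs()
  c13 <- specs[specs$label == "13C", ]
  r1 <- rule_by_name("[M+H]+")
  base <- adduct_mz(monoisotopic_mass(f), r1)
  v <- isotope_variants(f, base, r1, c13)
  expect_equal(v$mz - base, (1:nrow(v)) * 1.0033548, tolerance = 1e-6)
  expect_equal(v$abundance[1], 9 * (0.0107 / 0.9893), tolerance = 1e-6)
  # doubly charged: spacing halves
  r2 <- rule_by_name("[M+2H]2+")
  base2 <- adduct_mz(monoisotopic_mass(f), r2)
  v2 <- isotope_variants(f, base2, r2, c13)
  expect_equal(v2$mz[1] - base2, 1.0033548 / 2, tolerance = 1e-6)
  # dimer doubles the substitutable atoms
  rd <- rule_by_name("[2M+H]+")
  vd <- isotope_variants(f, adduct_mz(monoisotopic_mass(f), rd), rd, c13)
  expect_equal(vd$abundance[1], 18 * (0.0107 / 0.9893), tolerance = 1e-6)
})

test_that("isotopologue m/z increases and abundance decreases with k", {
  f <- parse_formula("C40H60N10O10")
  r1 <- rule_by_name("[M+H]+")
  base <- adduct_mz(monoisotopic_mass(f), r1)
  specs <- default_isotope_specs()
  v <- isotope_variants(f, base, r1,
                        specs[specs$label == "13C", ],
                        abundance_floor = 0)
  expect_true(all(diff(v$mz) > 0))
  expect_true(all(diff(v$abundance) < 0))
})

test_that("elements absent from the formula yield no isotopologue", {
  v <- isotope_variants(parse_formula("H2O"), 19.018, rule_by_name("[M+H]+"),
                        default_isotope_specs()[1, ])  # 13C spec, no carbon
  expect_equal(nrow(v), 0)
})

test_that("enumerate_variants counts and anchors are right", {
  v <- enumerate_variants("C9H17N3O6", rules, specs = NULL)
  expect_equal(nrow(v), nrow(rules))   # one M0 per rule, no isotopes
  expect_true(all(v$isotope == "M0"))

  specs13 <- default_isotope_specs()
  specs13 <- specs13[specs13$label == "13C", ]
  specs13$n_max <- 2L
  v3 <- enumerate_variants("C9H17N3O6", rules[1, ], specs = specs13,
                           abundance_floor = 0)
  expect_equal(nrow(v3), 3)            # M0, 13C1, 13C2
  expect_equal(v3$isotope, c("M0", "13C1", "13C2"))

  # the worked-example anchor: [M+H]+ of creatine riboside at 264.1190
  vall <- enumerate_variants("C9H17N3O6")
  mh <- vall[vall$adduct == "[M+H]+" & vall$isotope == "M0", ]
  expect_equal(mh$mz, 264.1190117, tolerance = 1e-6)
  expect_true(all(vall$mz > 0))
  expect_true(all(vall$abundance > 0 & vall$abundance <= 1))
})

test_that("rule and isotope tables round-trip through delimited files", {
  rf <- tempfile(fileext = ".tsv")
  utils::write.table(rules, rf, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_adduct_rules(rf)
  expect_equal(back$name, rules$name)
  expect_equal(back$added, rules$added)
  expect_equal(back$removed, rules$removed)

  sf <- tempfile(fileext = ".tsv")
  specs <- default_isotope_specs()
  utils::write.table(specs[, c("label", "element", "n_max")], sf, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  sback <- read_isotope_specs(sf)
  expect_equal(sback$label, specs$label)
  expect_equal(sback$shift, specs$shift)
  expect_error(read_adduct_rules({
    bad <- tempfile(); writeLines("name\tpolarity\n[M+H]+\t+", bad); bad
  }), "missing column")
})
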