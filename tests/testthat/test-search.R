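# ppm-window search, ranking, filtering, prioritization, batch determinism.

test_that("ppm windows are closed, symmetric and proportional to m/z", {
  w <- ppm_window(100, 10)
  expect_equal(w[, "lo"], 99.999, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(w[, "hi"], 100.001, tolerance = 1e-9, ignore_attr = TRUE)
  w60 <- ppm_window(60, 5); w600 <- ppm_window(600, 5)
  expect_equal((w600[, "hi"] - w600[, "lo"]) / (w60[, "hi"] - w60[, "lo"]), 10,
               ignore_attr = TRUE)
})

test_that("a theoretical m/z exactly on the window boundary is included", {
  db <- toy_db(specs = NULL)
  target <- db$variants$mz[1]
  pol <- db$variants$polarity[1]
  ppm <- 2
  # query placed so that the record sits exactly at the window's low edge
  q_lo <- target / (1 - ppm * 1e-6)
  hits <- search_mz(db, q_lo, ppm = ppm, polarity = pol)
  expect_true(any(abs(hits$theoretical_mz - target) < 1e-12))
})

test_that("creatine riboside [M+H]+ is the top hit for 264.1190 at 2 ppm", {
  db <- toy_db()
  hits <- search_mz(db, 264.1190, ppm = 2, polarity = "+")
  expect_gt(nrow(hits), 0)
  expect_equal(hits$name[1], "creatine riboside")
  expect_equal(hits$adduct[1], "[M+H]+")
  expect_equal(hits$formula[1], "C9H17N3O6")
  expect_equal(hits$rank, seq_len(nrow(hits)))
})

test_that("searching finds nothing in empty regions and errors sensibly", {
  db <- toy_db()
  expect_equal(nrow(search_mz(db, 1500, ppm = 2)), 0)
  expect_error(search_mz(db, 264.1190, sources = character(0)),
               "no source databases")
})

test_that("every returned hit is inside tolerance (soundness fuzz)", {
  db <- build_extended_db(gen_compound_db(80, seed = 5), tempfile("fz"))
  set.seed(99)
  for (q in runif(60, 60, 600)) {
    ppm <- sample(c(2, 5, 10, 50), 1)
    hits <- search_mz(db, q, ppm = ppm, polarity = "both")
    if (nrow(hits)) expect_true(all(abs(hits$ppm_error) <= ppm))
  }
})

test_that("hits at a narrow tolerance are a subset of hits at a wide one", {
  db <- build_extended_db(gen_compound_db(80, seed = 5), tempfile("mono"))
  set.seed(13)
  for (q in runif(20, 60, 600)) {
    narrow <- search_mz(db, q, ppm = 3)
    wide <- search_mz(db, q, ppm = 30)
    key <- function(h) paste(h$compound_id, h$adduct, h$isotope)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("indexed search equals the exhaustive linear scan, order included", {
  db <- build_extended_db(gen_compound_db(60, seed = 6), tempfile("lin"))
  set.seed(21)
  queries <- runif(50, 60, 600)
  for (q in queries) {
    for (pol in c("both", "+", "-")) {
      got <- search_mz(db, q, ppm = 10, polarity = pol)
      ref <- linear_scan_search(db, q, ppm = 10, polarity = pol)
      expect_equal(nrow(got), nrow(ref))
      if (nrow(ref)) {
        expect_equal(got$compound_id, ref$compound_id)
        expect_equal(got$adduct, ref$adduct)
        expect_equal(got$isotope, ref$isotope)
        expect_equal(got$theoretical_mz, ref$mz, tolerance = 1e-12)
      }
    }
  }
})

test_that("the main-peak filter removes isotopologues before ranking", {
  db <- toy_db()
  all_hits <- search_mz(db, 265.1224, ppm = 5, polarity = "+")
  expect_true("13C1" %in% all_hits$isotope)
  m0 <- search_mz(db, 265.1224, ppm = 5, polarity = "+",
                  main_peak_only = TRUE)
  expect_true(all(m0$isotope == "M0"))
})

test_that("source selection restricts hits", {
  comp <- rbind(toy_compounds(),
                within(toy_compounds(), { id <- paste0(id, "b"); source <- "alt" }))
  db <- build_extended_db(comp, tempfile("src"), specs = NULL)
  h <- search_mz(db, 264.1190, ppm = 2, polarity = "+", sources = "alt")
  expect_true(all(h$source == "alt"))
})

test_that("prioritization puts M0 first, then protonated adducts, then ppm", {
  base <- search_mz(toy_db(), 264.1190, ppm = 2, polarity = "+")[1, ]
  fake <- function(adduct, isotope, ppm_err) {
    r <- base; r$adduct <- adduct; r$isotope <- isotope; r$ppm_error <- ppm_err; r
  }
  hits <- rbind(fake("[M+Na]+", "M0", 0.1), fake("[M+H]+", "M0", 0.5))
  expect_equal(prioritize_hits(hits)$adduct[1], "[M+H]+")
  hits2 <- rbind(fake("[M+H]+", "13C1", 0.2), fake("[M+H]+", "M0", 1.5))
  expect_equal(prioritize_hits(hits2)$isotope[1], "M0")
  single <- base
  expect_equal(prioritize_hits(single)$adduct, single$adduct)
  expect_equal(nrow(prioritize_hits(base[0, ])), 0)
})

test_that("batch search is independent of worker count and handles errors", {
  db <- build_extended_db(gen_compound_db(40, seed = 7), tempfile("bat"))
  qs <- gen_query_pool(30, seed = 2)
  r1 <- batch_search(db, qs, ppm = 10, workers = 1)
  r2 <- batch_search(db, qs, ppm = 10, workers = 2)
  expect_equal(r1, r2)
  expect_length(batch_search(db, numeric(0)), 0)
  # a bad query yields a condition in its slot, not an abort
  mixed <- batch_search(db, data.frame(mz = c(264.119, -1)))
  expect_s3_class(mixed[[1]], "data.frame")
  expect_s3_class(mixed[[2]], "condition")
})

test_that("hit tables write to TSV with the documented columns", {
  hits <- search_mz(toy_db(), 264.1190, ppm = 2, polarity = "+")
  out <- tempfile(fileext = ".tsv")
  write_hits(hits, out)
  back <- utils::read.delim(out)
  expect_equal(names(back),
               c("query_mz", "source", "compound_id", "name", "formula",
                 "adduct", "isotope", "theoretical_mz", "ppm_error", "rank"))
  expect_equal(nrow(back), nrow(hits))
})
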