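test_that("fixture generation is byte-identical for identical (spec, seed)", {
  spec <- mad_architecture()
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- make_cluster(spec, seed = 7, dir = d1)
  b2 <- make_cluster(spec, seed = 7, dir = d2)
  for (f in names(b1$paths))
    expect_identical(unname(tools::md5sum(b1$paths[[f]])),
                     unname(tools::md5sum(b2$paths[[f]])), info = f)
})

test_that("different seeds change sequences but not the ground truth calls", {
  spec <- random_architecture(seed = 101)
  b1 <- make_cluster(spec, seed = 1)
  b2 <- make_cluster(spec, seed = 2)
  expect_false(identical(b1$cluster$genes$pksA$sequence,
                         b2$cluster$genes$pksA$sequence))
  expect_identical(b1$truth, b2$truth)
  rec <- function(b) {
    calls <- annotate_cluster(b$cluster)
    as.data.frame(calls)[, c("module", "kind", "subtype", "active",
                             "stereo_outcome")]
  }
  expect_identical(rec(b1), rec(b2))
})

test_that("zero-mutation sequences equal the scaffolds away from anchors", {
  spec <- mad_architecture()
  b0 <- make_cluster(spec, seed = 1, mutation_rate = 0)
  sc <- load_scaffolds()
  # an extension module KS with the default C residue IS the scaffold
  expect_identical(b0$cluster$modules[[2]]$domains$KS, sc$KS$sequence)
  # the loading KS differs from the scaffold at exactly the planted anchor
  lm_ks <- strsplit(b0$cluster$modules[[1]]$domains$KS, "")[[1]]
  ref <- strsplit(sc$KS$sequence, "")[[1]]
  diff <- which(lm_ks != ref)
  expect_identical(diff, sc$KS$anchors$cat_cys)
  expect_identical(lm_ks[diff], "Q")
})

test_that("the annotator blindly recovers ground truth over random specs", {
  # acceptance-scale property: >= 100 seeded random architectures
  for (seed in 1:100) {
    spec <- random_architecture(seed = 1000 + seed)
    b <- make_cluster(spec, seed = seed)
    calls <- annotate_cluster(b$cluster)
    expect_length(attr(calls, "errors"), 0)
    got <- as.data.frame(calls)[, c("module", "kind", "subtype", "active",
                                    "stereo_outcome")]
    key <- function(df) df[order(df$module, df$kind), ]
    expect_equal(key(got), key(b$truth), ignore_attr = TRUE,
                 info = sprintf("spec seed %d", seed))
  }
})

test_that("recovery stays exact up to 20% mutation and degrades to errors only", {
  spec <- random_architecture(seed = 555, n_modules = 3)
  for (rate in c(0.05, 0.10, 0.20)) {
    b <- make_cluster(spec, seed = 77, mutation_rate = rate)
    calls <- annotate_cluster(b$cluster)
    expect_length(attr(calls, "errors"), 0)
    got <- as.data.frame(calls)[, c("module", "kind", "subtype", "active",
                                    "stereo_outcome")]
    key <- function(df) df[order(df$module, df$kind), ]
    expect_equal(key(got), key(b$truth), ignore_attr = TRUE,
                 info = sprintf("mutation rate %.2f", rate))
  }
  # at full mutation of non-anchor positions the aligner must refuse, and any
  # call that is still emitted must agree with the ground truth: no silent
  # wrong calls at any rate
  b_max <- make_cluster(spec, seed = 77, mutation_rate = 1.0)
  calls_max <- annotate_cluster(b_max$cluster)
  errs <- attr(calls_max, "errors")
  expect_gt(length(errs), 0)
  expect_true(all(grepl("unalignable domain",
                        vapply(errs, `[[`, character(1), "message"))))
  if (nrow(calls_max)) {
    merged <- merge(as.data.frame(calls_max), b_max$truth,
                    by = c("module", "kind"), suffixes = c(".got", ".exp"))
    expect_true(all(merged$subtype.got == merged$subtype.exp &
                    merged$active.got == merged$active.exp))
  }
})

test_that("simulated peak lists behave as specified at the edges", {
  f <- parse_formula("C42H64O11")
  p0 <- make_peaks(f, mz_noise_sd = 0, seed = 1)
  expect_equal(p0$mz, sort(compute_adducts(f, "average")$mz), tolerance = 1e-9)
  # noisy list still diagnoses against the reference compound
  ref <- parse_formula("C42H64O12")
  p_ref <- make_peaks(ref, mz_noise_sd = 0, seed = 1)
  p_noisy <- make_peaks(f, mz_noise_sd = 0.1, seed = 7)
  d <- diagnose_delta(ref, p_ref, p_noisy)
  expect_equal(d$shift, -16)
  # empty adduct list gives an empty but well-formed CSV
  csv <- tempfile(fileext = ".csv")
  make_peaks(f, adducts = pk_adducts()[0, ], mz_noise_sd = 0, seed = 1,
             path = csv)
  expect_equal(nrow(read_peaks(csv)), 0)
  expect_error(make_peaks(f, mz_noise_sd = -1), "mz_noise_sd")
})

test_that("architecture validation rejects out-of-vocabulary motif states", {
  g <- list(list(gene_id = "pksA", product_label = "PKS"))
  mk <- function(doms) architecture_spec("x", g, list(
    list(module_index = "LM", gene_id = "pksA",
         domains = list(KS = list(cat_residue = "Q"), AT = list(motif = "HASH"),
                        ACP = list())),
    list(module_index = 1, gene_id = "pksA", domains = doms)))
  expect_error(mk(list(KS = list(cat_residue = "CC"), AT = list(), ACP = list())),
               "single amino-acid")
  expect_error(mk(list(KS = list(), AT = list(motif = "YAS"), ACP = list())),
               "4 letters")
  expect_error(mk(list(KS = list(), AT = list(motif = "YASB"), ACP = list())),
               "'B'")
  expect_error(mk(list(KS = list(wrong_field = 1), AT = list(), ACP = list())),
               "unknown KS state")
  expect_error(mk(list(KS = list(), AT = list())), "ACP")
})
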