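test_that("capability detection works from labels alone", {
  cl <- mad_bundle()$cluster
  caps <- detect_capabilities(cl)
  expect_true(caps$has_glycerate_operon)
  expect_true(caps$has_methoxymalonate_subcluster)
  expect_true(caps$has_epoxidase_hydrolase_pair)
  expect_true(caps$pyrE3_like_cyclase)
  expect_true(caps$vstJ_like_cyclase)
  expect_equal(caps$p450_count, 2)
  expect_setequal(caps$evidence$has_glycerate_operon,
                  c("mad7", "mad14", "mad8", "mad12", "mad16", "mad17", "mad18"))
  # removing the O-methyltransferase kills the methoxymalonate subcluster
  cl2 <- cl; cl2$genes$mad15 <- NULL
  expect_false(detect_capabilities(cl2)$has_methoxymalonate_subcluster)
  expect_true(detect_capabilities(cl2)$has_glycerate_operon)
  # an empty cluster has no capabilities
  empty <- cluster_model("empty", list(gene_record("x", "other")))
  caps0 <- detect_capabilities(empty)
  expect_false(any(unlist(caps0[c("has_glycerate_operon",
                                  "has_methoxymalonate_subcluster",
                                  "has_epoxidase_hydrolase_pair",
                                  "pyrE3_like_cyclase", "vstJ_like_cyclase")])))
  expect_equal(caps0$p450_count, 0)
})

test_that("the full pathway reaches the C42H64O12 endpoint in 9 steps", {
  caps <- detect_capabilities(mad_bundle()$cluster)
  pw <- build_pathway(caps, mad_target())
  expect_length(pw, 9)
  wt <- simulate_pathway(pw)
  expect_identical(format(wt$formula), "C42H64O12")
  expect_identical(wt$product_label, "tetromadurin (1)")
  expect_equal(nrow(wt$blocked_steps), 0)
})

test_that("missing capabilities drop steps with a warning", {
  cl <- mad_bundle()$cluster
  cl$genes$mad31 <- NULL
  caps <- detect_capabilities(cl)
  expect_warning(pw <- build_pathway(caps, mad_target()), "XVII")
  expect_false("XVII" %in% vapply(pw, `[[`, character(1), "id"))
  # without the glycerate operon no tetronate chemistry happens at all
  cl2 <- mad_bundle()$cluster
  cl2$genes$mad16 <- NULL
  w <- capture_warnings(pw2 <- build_pathway(detect_capabilities(cl2),
                                             mad_target()))
  expect_true(any(grepl("IX", w)))
  ids <- vapply(pw2, `[[`, character(1), "id")
  expect_false(any(c("IX", "XII", "XIII") %in% ids))
})

test_that("knockout simulation reproduces the observed products", {
  caps <- detect_capabilities(mad_bundle()$cluster)
  pw <- build_pathway(caps, mad_target())
  wt <- simulate_pathway(pw)
  ko10 <- simulate_pathway(pw, knockouts = "mad10")
  expect_identical(format(ko10$formula), "C42H64O11")
  expect_identical(ko10$product_label, "T-17 candidate (15)")
  expect_setequal(ko10$blocked_steps$id, c("XV", "XVII", "XVIII"))
  expect_equal(formula_mass(wt$formula, "nominal") -
               formula_mass(ko10$formula, "nominal"), 16)
  ko31 <- simulate_pathway(pw, knockouts = "mad31")
  expect_identical(ko31$blocked_steps$id, "XVII")
  expect_identical(format(ko31$formula), "C42H64O12")
  ko30 <- simulate_pathway(pw, knockouts = "mad30")
  expect_identical(format(ko30$formula), "C42H64O11")
  expect_identical(ko30$product_label, "des-C38-hydroxy candidate (16)")
  # the XVIII-after-XVII policy makes the C38 hydroxyl wait for the THP ring
  pw2 <- build_pathway(caps, mad_target(), c38_requires = "XVII")
  ko31b <- simulate_pathway(pw2, knockouts = "mad31")
  expect_setequal(ko31b$blocked_steps$id, c("XVII", "XVIII"))
  expect_identical(format(ko31b$formula), "C42H64O11")
  expect_error(simulate_pathway(pw, knockouts = "madZZ"), "unknown gene")
})

test_that("knocking out methoxymalonate supply removes the product entirely", {
  caps <- detect_capabilities(mad_bundle()$cluster)
  pw <- build_pathway(caps, mad_target())
  st <- simulate_pathway(pw, knockouts = "mad15")
  expect_null(st$formula)
  expect_identical(st$product_label, "no product (extender unavailable)")
  # a chain that never uses the extender is unaffected by the same knockout
  plain <- linear_chain(monomer_state("LM", "propionate"),
                        list(monomer_state(1, "acetate", "ketone")),
                        "from_target")
  st2 <- simulate_pathway(pw, chain = plain, knockouts = "mad15")
  expect_false(is.null(st2$formula))
})

test_that("blocked sets grow monotonically and bookkeeping is order-free", {
  caps <- detect_capabilities(mad_bundle()$cluster)
  pw <- build_pathway(caps, mad_target())
  genes <- unique(unlist(lapply(pw, `[[`, "genes")))
  set.seed(7)
  for (i in 1:20) {
    ko1 <- sample(genes, sample(0:2, 1))
    ko2 <- union(ko1, sample(genes, 1))
    b1 <- simulate_pathway(pw, knockouts = ko1)$blocked_steps$id
    b2 <- simulate_pathway(pw, knockouts = ko2)$blocked_steps$id
    expect_true(all(b1 %in% b2))
  }
  # a gene no step requires changes nothing
  base <- simulate_pathway(pw)
  noop <- simulate_pathway(pw, knockouts = "mad20",
                           genes = c(genes, "mad20"))
  expect_identical(format(noop$formula), format(base$formula))
  expect_identical(noop$applied_steps, base$applied_steps)
  # applying the unblocked deltas in any order gives the same formula
  f0 <- chain_formula(mad_target())
  deltas <- lapply(pw, `[[`, "delta")
  ref <- Reduce(fml_apply, deltas, f0)
  for (i in 1:10) {
    perm <- sample(deltas)
    expect_identical(format(Reduce(fml_apply, perm, f0)), format(ref))
  }
})

test_that("cyclic prerequisite configurations are rejected", {
  caps <- detect_capabilities(mad_bundle()$cluster)
  steps <- read_tailoring_steps()
  steps[[1]]$prerequisites <- "XVIII"  # IX <- XVIII <- XV <- XI <- X <- IX
  expect_error(build_pathway(caps, mad_target(), steps = steps), "cyclic")
})
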