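test_that("monomer states enforce the stereo/state invariants", {
  expect_error(monomer_state(1, "acetate", "hydroxyl", "none"),
               "beta_stereo")
  expect_error(monomer_state(1, "acetate", "ketone", "D"), "beta_stereo")
  expect_error(monomer_state(1, "acetate", "ketone", alpha_stereo = "D"),
               "alpha_stereo")
  expect_error(monomer_state("LM", "propionate", "ketone"), "starter")
  expect_error(monomer_state(1, "butyrate", "ketone"), "unknown extender")
})

test_that("the reduction ladder maps domain tallies to beta states", {
  calls <- mad_calls()
  ch <- assemble_from_calls(calls, c("LM", as.character(1:14)),
                            resolve_hybrid = "propionate")
  beta <- vapply(ch$extensions, `[[`, character(1), "beta_state")
  expect_identical(beta[c(2, 4, 8, 11)], rep("methylene", 4))
  expect_identical(beta[c(5, 7)], rep("hydroxyl", 2))
  expect_identical(beta[c(12, 14)], rep("ketone", 2))
  expect_identical(beta[c(1, 3, 6, 9, 10, 13)], rep("enoyl_double_bond", 6))
  # inactive-DH module 5 keeps the B1 hydroxyl with D stereochemistry
  expect_identical(ch$extensions[[5]]$beta_stereo, "D")
  # module 12: DH is active but has no KR product to act on
  expect_match(ch$extensions[[12]]$note, "enoyl product is an open alternative")
  # alpha stereo: ER-derived in 4/11, B1-derived in 7
  a_st <- vapply(ch$extensions, `[[`, character(1), "alpha_stereo")
  expect_identical(a_st[c(4, 7, 11)], rep("D", 3))
  expect_identical(ch$extensions[[13]]$alpha_substituent, "methoxy")
})

test_that("a single unreduced module yields a one-extension beta-keto chain", {
  calls <- rbind(call_ks(load_scaffolds()$KS$sequence, module = "1"),
                 call_at({
                   sc <- load_scaffolds()$AT
                   ch <- strsplit(sc$sequence, "")[[1]]
                   ch[sc$anchors$motif[1]:sc$anchors$motif[2]] <- c("H","A","F","H")
                   paste(ch, collapse = "")
                 }, module = "1"))
  ch <- assemble_from_calls(calls, "1")
  expect_length(ch$extensions, 1)
  expect_identical(ch$extensions[[1]]$beta_state, "ketone")
})

test_that("the packaged target decomposition has the published composition", {
  ch <- mad_target()
  expect_length(ch$extensions, 14)
  units <- c(ch$starter$extender,
             vapply(ch$extensions, `[[`, character(1), "extender"))
  expect_equal(sum(units == "propionate"), 8)
  expect_equal(sum(units == "acetate"), 6)
  expect_equal(sum(units == "methoxymalonate"), 1)
  expect_equal(backbone_carbons(ch), 31)       # 3 + 14 x 2
  expect_equal(total_carbons(ch), 39)          # + 7 methyls + 1 methoxy C
  expect_equal(total_carbons(ch) + 3, 42)      # + glycerate unit = C42
  # carbon numbering: position 12's beta carbon is C7
  cn <- ch$carbon_numbering
  expect_equal(cn$carbonyl_carbon[cn$position == "11"], 7)
  expect_equal(cn$carbonyl_carbon[cn$position == "LM"], 29)
})

test_that("malformed decompositions fail with the offending position", {
  dec <- list(starter = list(extender = "propionate"),
              extensions = list(list(position = 1, extender = "acetate",
                                     beta_state = "hydroxyl",
                                     beta_stereo = "none")))
  expect_error(chain_from_target(dec), "extension 1")
  dec$extensions[[1]]$position <- 2
  expect_error(chain_from_target(dec), "position")
  # starter-only decomposition is fine
  ch0 <- chain_from_target(list(starter = list(extender = "propionate"),
                                extensions = list()))
  expect_equal(backbone_carbons(ch0), 3)
})

test_that("chain comparison flags the single C7 discrepancy and nothing else", {
  calls <- mad_calls()
  ch13 <- assemble_from_calls(calls, c("LM", as.character(1:14)),
                              resolve_hybrid = "propionate")
  ch14 <- mad_target()
  expect_identical(compare_chains(ch13, ch13)$verdict, "collinear")
  d <- compare_chains(ch13, ch14)
  expect_identical(d$verdict, "near_collinear")
  expect_gte(d$n_discrepancies, 1)
  expect_identical(unique(d$discrepancies$position), "12")
  beta_row <- d$discrepancies[d$discrepancies$field == "beta_state", ]
  expect_identical(c(beta_row$value_a, beta_row$value_b),
                   c("ketone", "hydroxyl"))
  expect_match(beta_row$note, "trans-acting KR")
  # symmetry up to value swap
  d2 <- compare_chains(ch14, ch13)
  expect_identical(d2$discrepancies$value_a, d$discrepancies$value_b)
  expect_identical(d2$discrepancies$value_b, d$discrepancies$value_a)
  # length mismatch is incompatible, not an error
  short <- linear_chain(ch14$starter, ch14$extensions[1:3], "from_target")
  expect_identical(compare_chains(ch13, short)$verdict, "incompatible")
})

test_that("chain formulas agree with drawn structures", {
  prop <- linear_chain(monomer_state("LM", "propionate"), list(), "from_target")
  expect_identical(format(chain_formula(prop)), "C3H6O2")  # propionic acid
  keto <- linear_chain(monomer_state("LM", "propionate"),
                       list(monomer_state(1, "acetate", "ketone")),
                       "from_target")
  expect_identical(format(chain_formula(keto)), "C5H8O3")  # 3-oxopentanoic acid
  expect_identical(format(chain_formula(mad_target())), "C39H64O7")
  expect_identical(as.character(chain_to_smiles(prop)), "CCC(=O)O")
})

test_that("SMILES element counts equal the formula bookkeeping (openbabel)", {
  set.seed(2026)
  chains <- replicate(200, random_chain(), simplify = FALSE)
  smiles <- vapply(chains, chain_to_smiles, character(1))
  want <- vapply(chains, function(ch) format(chain_formula(ch)), character(1))
  got <- obabel_formulas(smiles)
  expect_identical(got, want)
})

test_that("an unresolved hybrid starter refuses formula and SMILES output", {
  ch <- linear_chain(monomer_state("LM", "relaxed_hybrid"), list(),
                     "from_modules")
  expect_error(chain_formula(ch), "unresolved hybrid")
  expect_error(chain_to_smiles(ch), "unresolved hybrid")
  # the stereo sidecar carries the D/L labels that SMILES omits
  smi <- chain_to_smiles(mad_target())
  st <- attr(smi, "stereo")
  expect_setequal(st$position[st$site == "beta_hydroxyl"], c(5, 7, 12))
  expect_true(all(st$label == "D"))
})
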