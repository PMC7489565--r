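test_that("a scaffold aligned to itself maps every anchor to its own residue", {
  sc <- load_scaffolds()
  for (kind in c("KS", "AT", "DH", "KR", "ER")) {
    s <- sc[[kind]]
    aln <- anchor_align(s$sequence, s)
    expect_equal(aln$pid, 1.0)
    ref <- strsplit(s$sequence, "")[[1]]
    for (a in s$anchors) {
      pos <- if (length(a) == 2) a[1]:a[2] else a
      expect_identical(aln$map[pos], ref[pos])
    }
  }
})

test_that("a shuffled sequence is rejected as unalignable, not miscalled", {
  sc <- load_scaffolds()
  set.seed(31)
  shuffled <- paste(sample(strsplit(sc$KS$sequence, "")[[1]]), collapse = "")
  expect_error(anchor_align(shuffled, sc$KS), "unalignable domain")
  expect_error(anchor_align("MKTAY", sc$KS), "too short")
})

test_that("KS calls follow the catalytic-residue rule", {
  sc <- load_scaffolds()
  plant <- function(res) {
    ch <- strsplit(sc$KS$sequence, "")[[1]]
    ch[sc$KS$anchors$cat_cys] <- res
    paste(ch, collapse = "")
  }
  expect_identical(call_ks(plant("C"))$subtype, "extension")
  q <- call_ks(plant("Q"), module = "LM")
  expect_identical(q$subtype, "KSQ")
  expect_true(q$active)
  # KSQ away from the loading module is flagged, not fatal
  expect_match(call_ks(plant("Q"), module = "3")$note, "outside the loading")
  a <- call_ks(plant("A"))
  expect_false(a$active)
})

test_that("AT motif patterns are matched in fixed priority order", {
  sc <- load_scaffolds()
  plant <- function(motif) {
    ch <- strsplit(sc$AT$sequence, "")[[1]]
    ch[sc$AT$anchors$motif[1]:sc$AT$anchors$motif[2]] <- strsplit(motif, "")[[1]]
    paste(ch, collapse = "")
  }
  expect_identical(call_at(plant("HASH"))$subtype, "relaxed_hybrid")
  for (m in c("HAFH", "TAFH", "VAFH", "YAFH"))
    expect_identical(call_at(plant(m))$subtype, "acetate")
  for (m in c("YASH", "VASH", "WASH"))
    expect_identical(call_at(plant(m))$subtype, "propionate")
  u <- call_at(plant("QQQQ"))
  expect_identical(u$subtype, "unknown")
  expect_false(u$active)
})

test_that("KR typing follows the tyrosine / LDD / proline / NADPH rules", {
  sc <- load_scaffolds()
  plant <- function(tyr = "Y", ldd = "LDD", plus2 = "A", del_nadph = FALSE) {
    ch <- strsplit(sc$KR$sequence, "")[[1]]
    ch[sc$KR$anchors$cat_tyr] <- tyr
    ch[sc$KR$anchors$ldd[1]:sc$KR$anchors$ldd[2]] <- strsplit(ldd, "")[[1]]
    ch[sc$KR$anchors$tyr_plus2] <- plus2
    if (del_nadph) ch <- ch[-(sc$KR$anchors$nadph[1]:sc$KR$anchors$nadph[2])]
    paste(ch, collapse = "")
  }
  b1 <- call_kr(plant())
  expect_identical(c(b1$subtype, b1$stereo_outcome), c("B1", "D"))
  b2 <- call_kr(plant(plus2 = "P"))
  expect_identical(c(b2$subtype, b2$stereo_outcome), c("B2", "D"))
  for (ldd in c("VDD", "IDD"))
    expect_identical(call_kr(plant(ldd = ldd))$subtype, "B1")
  a <- call_kr(plant(ldd = "AAD"))
  expect_identical(c(a$subtype, a$stereo_outcome), c("A", "L"))
  no_tyr <- call_kr(plant(tyr = "F"))
  expect_identical(no_tyr$subtype, "inactive")
  expect_identical(no_tyr$stereo_outcome, "none")
  nad <- call_kr(plant(del_nadph = TRUE))
  expect_identical(nad$subtype, "inactive")
  expect_match(nad$note, "NADPH")
})

test_that("DH activity needs both the YGP tyrosine and the catalytic aspartate", {
  sc <- load_scaffolds()
  plant <- function(y = "Y", d = "D") {
    ch <- strsplit(sc$DH$sequence, "")[[1]]
    ch[sc$DH$anchors$ygp_tyr] <- y
    ch[sc$DH$anchors$cat_asp] <- d
    paste(ch, collapse = "")
  }
  expect_true(call_dh(plant())$active)
  expect_match(call_dh(plant(y = "F"))$note, "YGP tyrosine")
  # a conservative D -> E substitution still kills activity
  e <- call_dh(plant(d = "E"))
  expect_false(e$active)
  expect_match(e$note, "aspartate")
})

test_that("ER stereochemistry is keyed on the single tyrosine anchor", {
  sc <- load_scaffolds()
  plant <- function(res) {
    ch <- strsplit(sc$ER$sequence, "")[[1]]
    ch[sc$ER$anchors$key_tyr] <- res
    paste(ch, collapse = "")
  }
  expect_identical(call_er(plant("Y"))$stereo_outcome, "L")
  expect_identical(call_er(plant("V"))$stereo_outcome, "D")
})

test_that("the packaged mad fixture reproduces the published annotation", {
  calls <- mad_calls()
  expect_length(attr(calls, "errors"), 0)
  inactive_kr <- calls$module[calls$kind == "KR" & !calls$active]
  expect_setequal(inactive_kr, c("12", "14"))
  inactive_dh <- calls$module[calls$kind == "DH" & !calls$active]
  expect_identical(inactive_dh, "5")
  expect_identical(calls$module[calls$subtype == "KSQ"], "LM")
  expect_equal(sum(calls$kind == "KS" & calls$subtype == "extension" &
                   calls$active), 14)
  # ER stereo: D-configuring in the two propionate full-reduction modules
  expect_identical(calls$stereo_outcome[calls$kind == "ER" &
                                        calls$module %in% c("4", "11")],
                   c("D", "D"))
  # module-13 AT: YASH motif re-labelled by the methoxymalonate override
  at13 <- calls[calls$kind == "AT" & calls$module == "13", ]
  expect_identical(at13$subtype, "methoxymalonate_override")
  expect_match(at13$motif_evidence, "motif=YASH")
  expect_match(at13$motif_evidence, "override")
  # without a target the same module reads as plain propionate
  calls_blind <- annotate_cluster(mad_bundle()$cluster)
  expect_identical(calls_blind$subtype[calls_blind$kind == "AT" &
                                       calls_blind$module == "13"],
                   "propionate")
  # extender tally after hybrid resolution matches the precursor count
  expect_identical(extender_tally(calls),
                   c(acetate = 6L, propionate = 8L, methoxymalonate = 1L,
                     unknown = 0L))
})

test_that("mutating one planted anchor flips exactly that call", {
  b <- mad_bundle()
  cl <- b$cluster
  base <- annotate_cluster(cl)
  sc <- load_scaffolds()
  # flip the module-3 KS catalytic cysteine (module list index 4)
  ch <- strsplit(cl$modules[[4]]$domains$KS, "")[[1]]
  expect_identical(ch[sc$KS$anchors$cat_cys], "C")
  ch[sc$KS$anchors$cat_cys] <- "A"
  cl$modules[[4]]$domains$KS <- paste(ch, collapse = "")
  mut <- annotate_cluster(cl)
  changed <- which(!(base$subtype == mut$subtype & base$active == mut$active))
  expect_length(changed, 1)
  expect_identical(mut$module[changed], "3")
  expect_identical(mut$kind[changed], "KS")
  expect_false(mut$active[changed])
})
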