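# Linear polyketide chains: assembly from module annotations, derivation from
# a retrobiosynthetic target decomposition, position-by-position comparison,
# and formula / SMILES output.
#
# Conventions. Extension position 1 is the first-extended unit (the loading
# module provides the starter); backbone carbons are numbered from C1 at the
# carboxy/tetronate-proximal end. Extension i of an n-extension chain
# contributes carbonyl carbon C(2(n-i)+1) and alpha carbon C(2(n-i)+2); the
# beta carbon its reductive domains act on is C(2(n-i)+3). Beta-carbon states
# are recorded on the extension whose module processed them.

.EXTENDERS <- list(
  acetate         = list(total_carbons = 2L, side_group = "none"),
  propionate      = list(total_carbons = 3L, side_group = "methyl"),
  methoxymalonate = list(total_carbons = 3L, side_group = "methoxy"),
  glycerate       = list(total_carbons = 3L, side_group = "none"),
  relaxed_hybrid  = list(total_carbons = NA_integer_, side_group = "unresolved")
)

.BETA_STATES <- c("ketone", "hydroxyl", "enoyl_double_bond", "methylene")

#' Extender-unit definitions
#'
#' Total-carbon accounting per unit: acetate (malonyl-CoA) 2 C; propionate
#' ((2S)-methylmalonyl-CoA), methoxymalonate ((2R)-methoxymalonyl-ACP) and
#' glycerate (glyceryl-ACP) 3 C each.
#'
#' @return data frame with columns `name`, `total_carbons`, `side_group`.
#' @export
extender_units <- function() {
  nm <- setdiff(names(.EXTENDERS), "relaxed_hybrid")
  data.frame(name = nm,
             total_carbons = vapply(.EXTENDERS[nm], `[[`, integer(1), "total_carbons"),
             side_group = vapply(.EXTENDERS[nm], `[[`, character(1), "side_group"),
             row.names = NULL)
}

#' One monomer of a linear chain
#'
#' @param position extension index (1-based) or `"LM"` for the starter.
#' @param extender extender-unit name.
#' @param beta_state `"ketone"`, `"hydroxyl"`, `"enoyl_double_bond"` or
#'   `"methylene"` (NA for the starter, which has no beta carbon).
#' @param beta_stereo `"D"`, `"L"` or `"none"`; must be non-none exactly when
#'   `beta_state == "hydroxyl"`.
#' @param alpha_substituent `"none"`, `"methyl"` or `"methoxy"`.
#' @param alpha_stereo `"D"`, `"L"` or `"none"`; non-none only for a methyl
#'   substituent.
#' @return list of class `monomer_state`.
#' @export
monomer_state <- function(position, extender, beta_state = NA_character_,
                          beta_stereo = "none", alpha_substituent = "none",
                          alpha_stereo = "none") {
  if (!extender %in% names(.EXTENDERS)) stop("unknown extender: ", extender)
  starter <- identical(as.character(position), "LM")
  if (starter) {
    if (!is.na(beta_state)) stop("the starter has no beta_state")
  } else {
    if (!beta_state %in% .BETA_STATES)
      stop("position ", position, ": invalid beta_state '", beta_state, "'")
  }
  if ((beta_stereo != "none") != identical(beta_state, "hydroxyl"))
    stop("position ", position,
         ": beta_stereo must be D/L exactly when beta_state is hydroxyl")
  if (alpha_stereo != "none" && alpha_substituent != "methyl")
    stop("position ", position,
         ": alpha_stereo requires a methyl alpha substituent")
  structure(list(position = position, extender = extender,
                 beta_state = beta_state, beta_stereo = beta_stereo,
                 alpha_substituent = alpha_substituent,
                 alpha_stereo = alpha_stereo),
            class = "monomer_state")
}

#' Assemble a linear chain object
#'
#' @param starter a [monomer_state] with position `"LM"`.
#' @param extensions ordered list of [monomer_state] (position 1 first).
#' @param provenance `"from_modules"` or `"from_target"`.
#' @return list of class `linear_chain` with a `carbon_numbering` data frame
#'   mapping each position to its carbonyl/alpha (and starter) carbon numbers.
#' @export
linear_chain <- function(starter, extensions,
                         provenance = c("from_modules", "from_target")) {
  provenance <- match.arg(provenance)
  n <- length(extensions)
  for (i in seq_len(n))
    if (as.character(extensions[[i]]$position) != as.character(i))
      stop("extension ", i, " has position ", extensions[[i]]$position)
  starter_c <- .EXTENDERS[[starter$extender]]$total_carbons
  cn <- data.frame(
    position = c(vapply(seq_len(n), as.character, character(1)), "LM"),
    carbonyl_carbon = c(2L * (n - seq_len(n)) + 1L, 2L * n + 1L),
    alpha_carbon = c(2L * (n - seq_len(n)) + 2L, NA_integer_))
  structure(list(starter = starter, extensions = extensions,
                 carbon_numbering = cn, provenance = provenance),
            class = "linear_chain")
}

#' @export
print.linear_chain <- function(x, ...) {
  cat(sprintf("<linear_chain> %s: starter %s + %d extensions (%d backbone C)\n",
              x$provenance, x$starter$extender, length(x$extensions),
              backbone_carbons(x)))
  invisible(x)
}

#' Number of main-chain carbons
#' @param chain a [linear_chain].
#' @return integer: starter carbons + 2 per extension.
#' @export
backbone_carbons <- function(chain) {
  sc <- .EXTENDERS[[chain$starter$extender]]$total_carbons
  if (is.na(sc)) stop("unresolved hybrid starter: backbone count undefined")
  sc + 2L * length(chain$extensions)
}

#' Total carbons of a chain (backbone + side groups)
#' @param chain a [linear_chain].
#' @return integer.
#' @export
total_carbons <- function(chain) {
  side <- vapply(chain$extensions, function(e)
    switch(e$alpha_substituent, none = 0L, methyl = 1L, methoxy = 1L), integer(1))
  backbone_carbons(chain) + sum(side)
}

#' Assemble the chain implied by module annotations
#'
#' Walks the modules in order and applies the reduction ladder to each
#' extension: no active KR leaves a beta-ketone; an active KR alone (or with
#' an inactive DH) a beta-hydroxyl with the KR's stereochemistry; active
#' KR + DH an enoyl double bond; active KR + DH + ER a fully saturated
#' methylene. Alpha-methyl stereochemistry comes from the ER call in fully
#' reducing propionate modules, or from the B1-KR rule in hydroxyl-bearing
#' ones. A module whose DH is active but whose KR is inactive is recorded as
#' a ketone with a note that an enoyl product is an open alternative.
#'
#' @param calls calls data frame from [annotate_cluster()].
#' @param module_order module labels in assembly order, starting with `"LM"`
#'   when a loading module is present.
#' @param resolve_hybrid optional extender name a relaxed-hybrid loading AT
#'   resolves to (e.g. taken from a target decomposition). Without it the
#'   starter stays `relaxed_hybrid` and stereo/formula output for the chain
#'   is refused downstream.
#' @return a [linear_chain] with provenance `"from_modules"`.
#' @export
assemble_from_calls <- function(calls, module_order, resolve_hybrid = NULL) {
  getcall <- function(mod, kind) {
    r <- calls[calls$module == mod & calls$kind == kind, , drop = FALSE]
    if (nrow(r) == 0) NULL else r
  }
  ext_of <- function(at) {
    switch(at$subtype,
           acetate = "acetate", propionate = "propionate",
           methoxymalonate_override = "methoxymalonate",
           relaxed_hybrid = "relaxed_hybrid",
           stop("unknown AT subtype '", at$subtype, "' in module ", at$module))
  }
  has_lm <- module_order[1] == "LM"
  ext_mods <- if (has_lm) module_order[-1] else module_order
  # KSQ anywhere but the first module is suspicious but not fatal
  ksq <- calls$module[calls$kind == "KS" & calls$subtype == "KSQ"]
  off <- setdiff(ksq, module_order[1])
  if (length(off))
    warning("KSQ domain outside the first module: ", paste(off, collapse = ", "))
  if (has_lm) {
    at <- getcall("LM", "AT")
    if (is.null(at)) stop("loading module has no AT call")
    st_ext <- ext_of(at)
    if (st_ext == "relaxed_hybrid" && !is.null(resolve_hybrid))
      st_ext <- resolve_hybrid
    starter <- monomer_state("LM", st_ext)
  } else {
    starter <- monomer_state("LM", "propionate")
  }
  extensions <- vector("list", length(ext_mods))
  for (i in seq_along(ext_mods)) {
    mod <- ext_mods[i]
    ks <- getcall(mod, "KS"); at <- getcall(mod, "AT")
    if (is.null(ks) || is.null(at))
      stop("module ", mod, " lacks a KS or AT call")
    extd <- ext_of(at)
    if (extd == "relaxed_hybrid")
      stop("extension module ", mod, " has an unresolved hybrid AT")
    kr <- getcall(mod, "KR"); dh <- getcall(mod, "DH"); er <- getcall(mod, "ER")
    kr_on <- !is.null(kr) && kr$active
    dh_on <- !is.null(dh) && dh$active
    er_on <- !is.null(er) && er$active
    note <- ""
    if (!kr_on) {
      beta <- "ketone"; bst <- "none"
      if (dh_on) note <- "DH active but KR inactive: enoyl product is an open alternative"
    } else if (!dh_on) {
      beta <- "hydroxyl"; bst <- kr$stereo_outcome
    } else if (!er_on) {
      beta <- "enoyl_double_bond"; bst <- "none"
    } else {
      beta <- "methylene"; bst <- "none"
    }
    alpha <- .EXTENDERS[[extd]]$side_group
    ast <- "none"
    if (alpha == "methyl") {
      if (beta == "methylene" && er_on) ast <- er$stereo_outcome
      else if (beta == "hydroxyl" && kr_on && kr$subtype == "B1") ast <- "D"
    }
    m <- monomer_state(i, extd, beta, bst, alpha, ast)
    m$note <- note
    extensions[[i]] <- m
  }
  linear_chain(starter, extensions, "from_modules")
}

#' Read a retrobiosynthetic target decomposition
#'
#' @param x path to a decomposition JSON file (the packaged tetromadurin
#'   instance is `pk_extdata("tetromadurin_target.json")`) or an equivalent
#'   list with `starter` and `extensions`.
#' @return a [linear_chain] with provenance `"from_target"`.
#' @export
chain_from_target <- function(x) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = FALSE)
  if (is.null(x$starter) || is.null(x$extensions))
    stop("decomposition must contain 'starter' and 'extensions'")
  get <- function(e, f, d) if (is.null(e[[f]])) d else e[[f]]
  starter <- monomer_state("LM", x$starter$extender)
  extensions <- lapply(seq_along(x$extensions), function(i) {
    e <- x$extensions[[i]]
    pos <- get(e, "position", i)
    if (!identical(as.integer(pos), as.integer(i)))
      stop("decomposition extension ", i, " carries position ", pos)
    tryCatch(
      monomer_state(i, e$extender, get(e, "beta_state", NA_character_),
                    get(e, "beta_stereo", "none"),
                    get(e, "alpha_substituent", "none"),
                    get(e, "alpha_stereo", "none")),
      error = function(err)
        stop("decomposition extension ", i, ": ", conditionMessage(err)))
  })
  ch <- linear_chain(starter, extensions, "from_target")
  attr(ch, "notes") <- x$notes
  ch
}

#' Compare two linear chains position by position
#'
#' @param a,b [linear_chain] objects (conventionally the module-derived and
#'   the target-derived chain).
#' @return list of class `chain_diff`: `verdict` (`"collinear"`,
#'   `"near_collinear"` or `"incompatible"`), `n_discrepancies`, and a
#'   `discrepancies` data frame (position, field, value_a, value_b, note).
#' @export
compare_chains <- function(a, b) {
  mk <- function(verdict, n, df) structure(
    list(verdict = verdict, n_discrepancies = n, discrepancies = df),
    class = "chain_diff")
  empty <- data.frame(position = character(), field = character(),
                      value_a = character(), value_b = character(),
                      note = character())
  if (length(a$extensions) != length(b$extensions) ||
      !identical(a$starter$extender, b$starter$extender))
    return(mk("incompatible", NA_integer_, empty))
  fields <- c("extender", "beta_state", "beta_stereo", "alpha_substituent",
              "alpha_stereo")
  rows <- list()
  for (i in seq_along(a$extensions)) {
    for (f in fields) {
      va <- a$extensions[[i]][[f]]; vb <- b$extensions[[i]][[f]]
      if (!identical(va, vb)) {
        note <- ""
        if (f == "beta_state" &&
            ("ketone" %in% c(va, vb)) && ("hydroxyl" %in% c(va, vb)))
          note <- "trans-acting KR candidate (adjacent module)"
        rows[[length(rows) + 1L]] <- data.frame(
          position = as.character(i), field = f,
          value_a = as.character(va), value_b = as.character(vb), note = note)
      }
    }
  }
  if (length(rows) == 0) return(mk("collinear", 0L, empty))
  df <- do.call(rbind, rows)
  mk("near_collinear", nrow(df), df)
}

#' @export
print.chain_diff <- function(x, ...) {
  cat("<chain_diff> verdict:", x$verdict)
  if (x$verdict == "near_collinear")
    cat(" (", x$n_discrepancies, " field discrepancies)", sep = "")
  cat("\n")
  if (nrow(x$discrepancies)) print(x$discrepancies)
  invisible(x)
}

#' Molecular formula of a chain's free acid
#'
#' Monomer-wise bookkeeping relative to the saturated unbranched acid
#' C(n)H(2n)O2 with n backbone carbons: each methyl side group adds CH2, each
#' methoxy adds CH2O; a beta-ketone adds O and removes 2 H, a beta-hydroxyl
#' adds O, an enoyl double bond removes 2 H, a methylene changes nothing.
#'
#' @param chain a [linear_chain].
#' @return a [pk_formula].
#' @examples
#' ch <- linear_chain(monomer_state("LM", "propionate"), list(), "from_target")
#' chain_formula(ch)  # C3H6O2, propionic acid
#' @export
chain_formula <- function(chain) {
  n <- backbone_carbons(chain)  # errors on unresolved hybrid starter
  C <- n; H <- 2 * n; O <- 2
  for (e in chain$extensions) {
    if (e$alpha_substituent == "methyl") { C <- C + 1; H <- H + 2 }
    if (e$alpha_substituent == "methoxy") { C <- C + 1; H <- H + 2; O <- O + 1 }
    switch(e$beta_state,
           ketone = { O <- O + 1; H <- H - 2 },
           hydroxyl = { O <- O + 1 },
           enoyl_double_bond = { H <- H - 2 },
           methylene = NULL)
  }
  pk_formula(c(C = C, H = H, O = O))
}

#' SMILES of a chain's free acid
#'
#' Deterministic linear SMILES written from the starter methyl end to the
#' carboxylic acid, without stereo descriptors; the D/L labels are exported
#' as an annotation attribute (`attr(, "stereo")`). The element counts of the
#' SMILES equal [chain_formula()] by construction.
#'
#' @param chain a [linear_chain].
#' @return SMILES string with a `stereo` attribute (data frame of position,
#'   site, label).
#' @export
chain_to_smiles <- function(chain) {
  sc <- .EXTENDERS[[chain$starter$extender]]$total_carbons
  if (is.na(sc)) stop("unresolved hybrid starter: SMILES undefined")
  out <- paste(rep("C", sc - 1L), collapse = "")  # starter minus its carbonyl
  stereo <- list()
  n <- length(chain$extensions)
  for (i in seq_along(chain$extensions)) {
    e <- chain$extensions[[i]]
    # beta carbon (the previous unit's carbonyl) in the state recorded here
    beta <- switch(e$beta_state,
                   ketone = "C(=O)", hydroxyl = "C(O)",
                   enoyl_double_bond = "C=", methylene = "C")
    alpha <- switch(e$alpha_substituent,
                    none = "C", methyl = "C(C)", methoxy = "C(OC)")
    out <- paste0(out, beta, alpha)
    if (e$beta_stereo != "none")
      stereo[[length(stereo) + 1L]] <- data.frame(
        position = i, site = "beta_hydroxyl", label = e$beta_stereo)
    if (e$alpha_stereo != "none")
      stereo[[length(stereo) + 1L]] <- data.frame(
        position = i, site = "alpha_methyl", label = e$alpha_stereo)
  }
  out <- paste0(out, "C(=O)O")
  attr(out, "stereo") <- if (length(stereo)) do.call(rbind, stereo) else
    data.frame(position = integer(), site = character(), label = character())
  out
}
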