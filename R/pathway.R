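# Post-PKS tailoring: capability detection from gene labels, the ordered
# reaction table with formula deltas and gene dependencies, and wild-type /
# knockout product simulation.

#' Detect a cluster's tailoring capabilities from gene labels
#'
#' Flags are computed purely from the controlled product labels: the five-gene
#' glycerate-utilisation operon (FkbH-like, standalone ACP, FabH-like,
#' Agg4-like acyltransferase, Agg5-like dehydratase), the five-gene
#' methoxymalonate subcluster (FkbH-like, ACP, two dehydrogenases,
#' O-methyltransferase), the epoxidase/epoxide-hydrolase pair, the P450
#' count, and the two cyclase families.
#'
#' @param cluster a [cluster_model].
#' @return list of class `capability_report` with boolean flags, `p450_count`,
#'   and `evidence` (gene ids per flag).
#' @export
detect_capabilities <- function(cluster) {
  labels <- vapply(cluster$genes, function(g) g$product_label, character(1))
  ids <- names(cluster$genes)
  of <- function(lbl) ids[labels == lbl]
  n <- function(lbl) sum(labels == lbl)
  glycerate <- c("FkbH-like", "ACP", "FabH-like", "acyltransferase(Agg4-like)",
                 "dehydratase(Agg5-like)")
  has_glyc <- all(vapply(glycerate, n, numeric(1)) >= 1)
  has_mm <- n("FkbH-like") >= 1 && n("ACP") >= 1 && n("dehydrogenase") >= 2 &&
    n("O-methyltransferase") >= 1
  structure(list(
    has_glycerate_operon = has_glyc,
    has_methoxymalonate_subcluster = has_mm,
    has_epoxidase_hydrolase_pair = n("epoxidase") >= 1 && n("epoxide-hydrolase") >= 1,
    p450_count = n("P450"),
    pyrE3_like_cyclase = n("PyrE3-like-cyclase") >= 1,
    vstJ_like_cyclase = n("VstJ-like-cyclase") >= 1,
    evidence = list(
      has_glycerate_operon = if (has_glyc) unlist(lapply(glycerate, of)) else character(0),
      has_methoxymalonate_subcluster = if (has_mm)
        c(of("FkbH-like"), of("ACP"), of("dehydrogenase"),
          of("O-methyltransferase")) else character(0),
      has_epoxidase_hydrolase_pair = c(of("epoxidase"), of("epoxide-hydrolase")),
      p450 = of("P450"),
      pyrE3_like_cyclase = of("PyrE3-like-cyclase"),
      vstJ_like_cyclase = of("VstJ-like-cyclase")),
    label_index = split(ids, labels)),
    class = "capability_report")
}

#' @export
print.capability_report <- function(x, ...) {
  cat("<capability_report>\n")
  for (f in c("has_glycerate_operon", "has_methoxymalonate_subcluster",
              "has_epoxidase_hydrolase_pair", "pyrE3_like_cyclase",
              "vstJ_like_cyclase"))
    cat(sprintf("  %-32s %s\n", f, x[[f]]))
  cat(sprintf("  %-32s %d\n", "p450_count", x$p450_count))
  invisible(x)
}

.cap_ok <- function(caps, name) {
  switch(name,
         two_p450s = caps$p450_count >= 2,
         isTRUE(caps[[name]]))
}

#' Read a tailoring reaction table
#'
#' @param path YAML reaction table; defaults to the packaged tetronate table
#'   (steps IX-XVIII with the Mad gene assignments).
#' @return list of step records (id, name, genes, capability, delta,
#'   prerequisites, site).
#' @export
read_tailoring_steps <- function(path = pk_extdata("tailoring_steps.yaml")) {
  y <- yaml::read_yaml(path)
  lapply(y$steps, function(s) {
    s$delta <- if (length(s$delta)) unlist(s$delta) else numeric(0)
    s$genes <- as.character(unlist(s$genes))
    s$prerequisites <- as.character(unlist(s$prerequisites))
    s
  })
}

#' Build the tailoring pathway a cluster can execute
#'
#' Instantiates the reaction table against a capability report: steps whose
#' capability is missing are omitted with a warning. The composite
#' hydration + tetrahydropyran step is formula-neutral (the pathway is
#' agnostic about whether the hemiacetal or the ketone form is the cyclase
#' substrate), and the final C38 hydroxylation by default requires only the
#' oxadecalin-forming step, not tetrahydropyran formation.
#'
#' @param capabilities a `capability_report` from [detect_capabilities()].
#' @param chain the [linear_chain] the pathway will act on (recorded; the
#'   methoxymalonate extender gate is checked at simulation time).
#' @param steps reaction table (default packaged).
#' @param c38_requires `"XV"` (default) or `"XVII"`: the prerequisite of the
#'   final hydroxylation step XVIII.
#' @return list of class `pk_pathway` (ordered steps), with the capability
#'   report and chain attached as attributes.
#' @export
build_pathway <- function(capabilities, chain,
                          steps = read_tailoring_steps(),
                          c38_requires = c("XV", "XVII")) {
  c38_requires <- match.arg(c38_requires)
  kept <- list()
  for (s in steps) {
    if (identical(s$id, "XVIII")) s$prerequisites <- c38_requires
    if (!is.null(s$capability) && !.cap_ok(capabilities, s$capability)) {
      warning("step ", s$id, " (", s$name, ") omitted: capability ",
              s$capability, " not present")
      next
    }
    kept[[length(kept) + 1L]] <- s
  }
  ids <- vapply(kept, `[[`, character(1), "id")
  # prerequisite graph must be acyclic (checked by topological elimination)
  pending <- stats::setNames(lapply(kept, function(s)
    intersect(s$prerequisites, ids)), ids)
  while (length(pending)) {
    free <- names(pending)[vapply(pending, length, integer(1)) == 0]
    if (length(free) == 0) stop("cyclic prerequisites in reaction table")
    pending <- pending[!names(pending) %in% free]
    pending <- lapply(pending, setdiff, free)
  }
  structure(kept, class = "pk_pathway", capabilities = capabilities,
            chain = chain)
}

#' @export
print.pk_pathway <- function(x, ...) {
  cat("<pk_pathway>", length(x), "steps:\n")
  for (s in x)
    cat(sprintf("  %-6s %-20s %s\n", s$id, paste(s$genes, collapse = ","),
                s$name))
  invisible(x)
}

#' Simulate the pathway product for a set of gene knockouts
#'
#' Steps are applied in table order; a step is blocked if any required gene is
#' knocked out or any prerequisite step is blocked. Knocking out a gene of
#' the methoxymalonate subcluster while the chain uses that extender yields
#' no product at all. Formula bookkeeping is exact, so the result is
#' independent of the order in which the unblocked steps are applied.
#'
#' @param pathway a `pk_pathway` from [build_pathway()].
#' @param chain the [linear_chain] substrate (default: the chain the pathway
#'   was built for).
#' @param knockouts character vector of knocked-out gene ids (may be empty).
#' @param genes known gene ids used to validate `knockouts` (default: the
#'   genes of the capability evidence plus all step genes).
#' @return list of class `pathway_state`: `formula` ([pk_formula] or NULL),
#'   `applied_steps`, `blocked_steps` (data frame id/reason),
#'   `product_label`.
#' @export
simulate_pathway <- function(pathway, chain = attr(pathway, "chain"),
                             knockouts = character(), genes = NULL) {
  caps <- attr(pathway, "capabilities")
  step_genes <- unique(unlist(lapply(pathway, `[[`, "genes")))
  if (is.null(genes))
    genes <- unique(c(step_genes, unlist(caps$evidence)))
  unknown <- setdiff(knockouts, genes)
  if (length(unknown))
    stop("unknown gene(s) in knockouts: ", paste(unknown, collapse = ", "))
  chain_uses_mm <- any(vapply(chain$extensions, function(e)
    identical(e$extender, "methoxymalonate"), logical(1)))
  # extender supply survives a knockout as long as the remaining genes still
  # satisfy the subcluster's label counts (two FkbH-like proteins and two
  # ACPs exist; losing one of either pool is tolerated)
  mm_starved <- if (chain_uses_mm && !is.null(caps$label_index)) {
    left <- function(lbl) length(setdiff(caps$label_index[[lbl]], knockouts))
    isTRUE(caps$has_methoxymalonate_subcluster) &&
      (left("FkbH-like") < 1 || left("ACP") < 1 ||
       left("dehydrogenase") < 2 || left("O-methyltransferase") < 1)
  } else FALSE
  if (mm_starved)
    return(structure(list(formula = NULL, applied_steps = character(),
                          blocked_steps = data.frame(
                            id = "precursor-supply",
                            reason = "methoxymalonate extender unavailable"),
                          product_label = "no product (extender unavailable)"),
                     class = "pathway_state"))
  f <- chain_formula(chain)
  applied <- character()
  blocked <- data.frame(id = character(), reason = character())
  for (s in pathway) {
    ko <- intersect(s$genes, knockouts)
    missing_pre <- intersect(s$prerequisites, blocked$id)
    if (length(ko)) {
      blocked <- rbind(blocked, data.frame(
        id = s$id, reason = paste0("gene knocked out: ", paste(ko, collapse = ","))))
    } else if (length(missing_pre)) {
      blocked <- rbind(blocked, data.frame(
        id = s$id, reason = paste0("prerequisite blocked: ",
                                   paste(missing_pre, collapse = ","))))
    } else {
      f <- fml_apply(f, s$delta)
      applied <- c(applied, s$id)
    }
  }
  all_ids <- vapply(pathway, `[[`, character(1), "id")
  label <-
    if (length(blocked$id) == 0) "tetromadurin (1)"
    else if (setequal(blocked$id, intersect(c("XV", "XVII", "XVIII"), all_ids)))
      "T-17 candidate (15)"
    else if (identical(blocked$id, "XVIII"))
      "des-C38-hydroxy candidate (16)"
    else if (identical(blocked$id, "XVII"))
      "non-tetrahydropyran product (unobserved)"
    else "partial pathway product"
  structure(list(formula = f, applied_steps = applied, blocked_steps = blocked,
                 product_label = label),
            class = "pathway_state")
}

#' @export
print.pathway_state <- function(x, ...) {
  cat("<pathway_state>", x$product_label, "\n")
  if (!is.null(x$formula))
    cat("  formula:", format(x$formula),
        sprintf("(nominal %d Da)", as.integer(formula_mass(x$formula, "nominal"))),
        "\n")
  cat("  applied:", paste(x$applied_steps, collapse = " "), "\n")
  if (nrow(x$blocked_steps))
    cat("  blocked:", paste(x$blocked_steps$id, collapse = " "), "\n")
  invisible(x)
}
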