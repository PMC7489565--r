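# Architecture specs: the declarative ground-truth description of a cluster
# (per-module domain inventory and intended motif states, per-gene labels)
# that the fixture generator consumes and the annotator is tested against.

.KR_TYPES <- c("B1", "B2", "A", "inactive")

# closed per-domain state vocabularies; NULL entries are filled with defaults
.default_domain_state <- function(kind) {
  switch(kind,
    KS  = list(cat_residue = "C"),
    AT  = list(motif = "YASH"),
    DH  = list(ygp_tyr = TRUE, cat_asp = TRUE),
    KR  = list(cat_tyr = TRUE, ldd = TRUE, pro_at_tyr_plus2 = FALSE,
               nadph_deletion = FALSE),
    ER  = list(key_tyr = FALSE),
    ACP = list(),
    stop("unknown domain kind: ", kind))
}

.validate_domain_state <- function(kind, state, where) {
  def <- .default_domain_state(kind)
  extra <- setdiff(names(state), names(def))
  if (length(extra))
    stop(sprintf("%s: unknown %s state field(s): %s", where, kind,
                 paste(extra, collapse = ", ")))
  st <- utils::modifyList(def, state)
  if (kind == "KS" && !(is.character(st$cat_residue) &&
                        nchar(st$cat_residue) == 1 && st$cat_residue %in% .AA20))
    stop(where, ": KS cat_residue must be a single amino-acid letter")
  if (kind == "AT") {
    if (!grepl("^[A-Z]{4}$", st$motif)) stop(where, ": AT motif must be 4 letters")
    .check_aa(st$motif, paste0(where, " AT motif"))
  }
  st
}

#' Read an architecture spec from JSON
#'
#' @param path JSON file (see `inst/extdata/mad_architecture.json` for the
#'   schema and the packaged mad cluster instance).
#' @return list of class `architecture_spec` with `cluster_id`, `genes`
#'   (gene_id + product_label, optional cds_length_nt), and `modules`
#'   (module_index, gene_id, domains: kind -> motif-state list).
#' @export
read_architecture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  architecture_spec(x$cluster_id,
                    genes = x$genes,
                    modules = x$modules,
                    comment = x$comment)
}

#' Construct and validate an architecture spec
#'
#' @param cluster_id cluster identifier.
#' @param genes list of lists with `gene_id`, `product_label`
#'   (and optionally `cds_length_nt`).
#' @param modules list of lists with `module_index`, `gene_id`, `domains`
#'   (named list `kind -> state list`; missing state fields take defaults).
#' @param comment optional free-text notes carried through serialisation.
#' @return list of class `architecture_spec`.
#' @export
architecture_spec <- function(cluster_id, genes, modules, comment = NULL) {
  stopifnot(is.character(cluster_id), length(genes) > 0)
  genes <- lapply(genes, function(g) {
    if (!g$product_label %in% .PRODUCT_LABELS)
      stop("gene ", g$gene_id, ": unknown product_label ", g$product_label)
    g[intersect(names(g), c("gene_id", "product_label", "cds_length_nt"))]
  })
  idx <- vapply(modules, function(m) as.character(m$module_index), character(1))
  if (anyDuplicated(idx)) stop("duplicate module indices in architecture spec")
  modules <- lapply(modules, function(m) {
    where <- paste0("module ", m$module_index)
    kinds <- names(m$domains)
    for (k in c("KS", "AT", "ACP"))
      if (!k %in% kinds) stop(where, " must declare a ", k, " domain")
    m$domains <- stats::setNames(lapply(kinds, function(k)
      .validate_domain_state(k, m$domains[[k]], where)), kinds)
    # canonical domain order
    m$domains <- m$domains[intersect(.DOMAIN_KINDS, kinds)]
    m[c("module_index", "gene_id", "domains")]
  })
  structure(list(cluster_id = cluster_id, genes = genes, modules = modules,
                 comment = comment),
            class = "architecture_spec")
}

#' Write an architecture spec to JSON
#'
#' The canonical serialisation round-trips losslessly through
#' [read_architecture()].
#'
#' @param spec an [architecture_spec].
#' @param path output JSON path.
#' @export
write_architecture <- function(spec, path) {
  x <- unclass(spec)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("<architecture_spec> %s: %d genes, %d modules\n",
              x$cluster_id, length(x$genes), length(x$modules)))
  invisible(x)
}

#' The packaged mad-cluster architecture spec
#'
#' Transcribes the published module inventory and motif states of the seven
#' tetromadurin PKS proteins (loading module + 14 extension modules) and the
#' tailoring-gene labels. Per-module acetate/propionate assignments that the
#' source figures encode only as colour are documented in the spec's comment
#' field.
#'
#' @return an [architecture_spec].
#' @export
mad_architecture <- function() {
  read_architecture(pk_extdata("mad_architecture.json"))
}

#' Path to a packaged data file
#' @param ... file name components under the package's `extdata`.
#' @return file path.
#' @export
pk_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "pksmith", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged file not found: ", file.path(...))
  p
}
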