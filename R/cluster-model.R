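# Core data model: gene clusters, PKS modules and domains, plus readers and
# writers for the formats the rest of the pipeline consumes.

.PRODUCT_LABELS <- c(
  "FkbH-like", "FabH-like", "acyltransferase(Agg4-like)",
  "dehydratase(Agg5-like)", "epoxidase", "epoxide-hydrolase", "P450",
  "PyrE3-like-cyclase", "VstJ-like-cyclase", "O-methyltransferase", "ACP",
  "dehydrogenase", "PKS", "regulator", "transporter", "other")

.DOMAIN_KINDS <- c("KS", "AT", "DH", "ER", "KR", "ACP")

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Hard error naming the first offending position; B/Z/X/U are rejected so that
# motif residues are never ambiguous.
.check_aa <- function(seq, context = "sequence") {
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% .AA20)
  if (length(bad))
    stop(sprintf("non-standard amino-acid letter '%s' at position %d in %s",
                 ch[bad[1]], bad[1], context))
  invisible(TRUE)
}

#' Create a gene record
#'
#' @param gene_id gene identifier, e.g. `"mad10"` or `"madAI"`.
#' @param product_label one of the controlled functional labels
#'   (see Details); free text is rejected so that pathway capability
#'   detection cannot be silently disabled by a typo.
#' @param sequence optional amino-acid sequence (20 standard letters only).
#' @param cds_length_nt optional CDS length; when both sequence and length are
#'   given, `cds_length_nt == 3 * (nchar(sequence) + 1)` is checked and a
#'   mismatch is reported as a warning (never silently patched).
#' @details Labels: `r paste0('\x60', .PRODUCT_LABELS, '\x60', collapse = ", ")`.
#' @return list of class `gene_record`.
#' @export
gene_record <- function(gene_id, product_label, sequence = NULL,
                        cds_length_nt = NULL) {
  stopifnot(is.character(gene_id), nzchar(gene_id))
  if (!product_label %in% .PRODUCT_LABELS)
    stop("unknown product_label '", product_label, "' for gene ", gene_id,
         " (use one of the controlled labels, or 'other')")
  if (!is.null(sequence)) .check_aa(sequence, paste0("gene ", gene_id))
  if (!is.null(cds_length_nt)) {
    stopifnot(cds_length_nt > 0)
    if (!is.null(sequence) && cds_length_nt != 3 * (nchar(sequence) + 1))
      warning(sprintf(
        "gene %s: cds_length_nt (%d) != 3*(protein length + 1) = %d",
        gene_id, cds_length_nt, 3 * (nchar(sequence) + 1)))
  }
  structure(list(gene_id = gene_id, product_label = product_label,
                 sequence = sequence, cds_length_nt = cds_length_nt),
            class = "gene_record")
}

#' Create a cluster model
#'
#' @param cluster_id cluster identifier.
#' @param genes list of [gene_record] objects (order preserved).
#' @param modules ordered list of module records, each a list with
#'   `module_index` ("LM" or a positive integer label), `gene_id`, and
#'   `domains`: a named list `kind -> amino-acid sequence`. The loading
#'   module, if present, must come first, and module indices must be unique.
#'   Every module must carry exactly one KS, one AT and one ACP; domain order
#'   deviating from KS-AT-(DH)-(ER)-(KR)-ACP is kept but flagged.
#' @return list of class `cluster_model`.
#' @export
cluster_model <- function(cluster_id, genes, modules = list()) {
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate gene_id in cluster")
  names(genes) <- ids
  idx <- vapply(modules, function(m) as.character(m$module_index), character(1))
  if (anyDuplicated(idx)) stop("duplicate module indices")
  if ("LM" %in% idx && idx[1] != "LM")
    stop("the loading module (LM) must be first in pks_modules")
  if (sum(idx == "LM") > 1) stop("module LM appears more than once")
  for (m in modules) {
    kinds <- names(m$domains)
    bad <- setdiff(kinds, .DOMAIN_KINDS)
    if (length(bad)) stop("unknown domain kind: ", paste(bad, collapse = ","))
    for (k in c("KS", "AT", "ACP"))
      if (sum(kinds == k) != 1)
        stop(sprintf("module %s must have exactly one %s domain",
                     m$module_index, k))
    canonical <- intersect(.DOMAIN_KINDS, kinds)
    if (!identical(kinds, canonical))
      warning(sprintf("module %s: domain order %s deviates from KS-AT-DH-ER-KR-ACP",
                      m$module_index, paste(kinds, collapse = "-")))
    if (!m$gene_id %in% ids)
      stop("module ", m$module_index, " references unknown gene ", m$gene_id)
  }
  structure(list(cluster_id = cluster_id, genes = genes, modules = modules),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %s: %d genes, %d PKS modules\n",
              x$cluster_id, length(x$genes), length(x$modules)))
  invisible(x)
}

#' Module index labels of a cluster, in assembly order
#' @param cluster a [cluster_model].
#' @return character vector, e.g. `c("LM", "1", ..., "14")`.
#' @export
module_order <- function(cluster) {
  vapply(cluster$modules, function(m) as.character(m$module_index), character(1))
}

#' Read a protein cluster from FASTA plus a module map
#'
#' FASTA headers carry gene ids. The module map (JSON, see the packaged mad
#' fixture for the schema) lists every gene with its functional label, and for
#' PKS genes the module/domain coordinate ranges, 0-based half-open on the
#' protein sequence.
#'
#' @param path protein FASTA file.
#' @param module_map path to a module-map JSON file, or the already-parsed list.
#' @return a [cluster_model] whose domain sequences are substrings of the
#'   input protein sequences.
#' @export
read_cluster_fasta <- function(path, module_map) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in FASTA file: ", path)
  headers <- sub("\\s.*$", "", names(seqs))
  map <- if (is.character(module_map)) read_module_map(module_map) else module_map
  gene_tab <- map$genes
  known <- vapply(gene_tab, function(g) g$gene_id, character(1))
  missing <- setdiff(headers, known)
  if (length(missing))
    stop("FASTA header(s) absent from module map: ",
         paste(missing, collapse = ", "))
  genes <- lapply(gene_tab, function(g) {
    seq <- if (g$gene_id %in% headers)
      as.character(seqs[[match(g$gene_id, headers)]]) else NULL
    if (!is.null(seq)) .check_aa(seq, paste0("gene ", g$gene_id))
    gene_record(g$gene_id, g$product_label, sequence = seq,
                cds_length_nt = g$cds_length_nt)
  })
  modules <- lapply(map$modules, function(m) {
    if (!m$gene_id %in% headers)
      stop("module ", m$module_index, " maps to gene ", m$gene_id,
           " which is not in the FASTA")
    prot <- as.character(seqs[[match(m$gene_id, headers)]])
    doms <- lapply(m$domains, function(rng) {
      # rng is c(start, end), 0-based half-open
      if (rng[1] < 0 || rng[2] > nchar(prot) || rng[1] >= rng[2])
        stop("domain range [", rng[1], ",", rng[2], ") out of bounds for gene ",
             m$gene_id)
      substr(prot, rng[1] + 1, rng[2])
    })
    list(module_index = m$module_index, gene_id = m$gene_id, domains = doms)
  })
  cluster_model(map$cluster_id, genes, modules)
}

#' Read a module map JSON file
#' @param path JSON path.
#' @return parsed map (list with `cluster_id`, `genes`, `modules`).
#' @export
read_module_map <- function(path) {
  map <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(map$cluster_id) || is.null(map$genes))
    stop("module map must contain cluster_id and genes: ", path)
  map$modules <- lapply(map$modules, function(m) {
    m$domains <- lapply(m$domains, function(r) as.integer(unlist(r)))
    m
  })
  map
}

#' Write the protein sequences of a cluster as FASTA
#'
#' Inverse of [read_cluster_fasta()]: genes carrying a sequence are written
#' in cluster order, one record per gene, header = gene_id.
#'
#' @param cluster a [cluster_model].
#' @param path output FASTA path.
#' @export
write_cluster_fasta <- function(cluster, path) {
  keep <- Filter(function(g) !is.null(g$sequence), cluster$genes)
  set <- Biostrings::AAStringSet(vapply(keep, function(g) g$sequence, character(1)))
  names(set) <- vapply(keep, function(g) g$gene_id, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a GenBank flat file into a cluster model
#'
#' Minimal reader for local GenBank records: one [gene_record] per CDS
#' feature, taking the id from `/gene` (falling back to `/locus_tag`), the
#' protein sequence from `/translation`, and the label from `/product` when it
#' matches the controlled vocabulary (otherwise `"other"`). CDS features
#' without a translation are skipped with a warning. PKS module splitting is
#' deferred to a module map or the annotator.
#'
#' @param path GenBank flat file.
#' @return a [cluster_model] with no modules.
#' @export
read_cluster_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (missing LOCUS line): ", path)
  if (!any(grepl("^//\\s*$", lines)))
    stop("truncated GenBank record (missing // terminator): ", path)
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]][2]
  feat_start <- grep("^FEATURES", lines)
  feat_end <- grep("^(ORIGIN|//)", lines)[1]
  if (is.na(feat_start[1]) || is.na(feat_end))
    stop("unparseable GenBank record: ", path)
  fl <- lines[(feat_start[1] + 1):(feat_end - 1)]
  # split the feature table into features (new feature = key in column 6)
  is_key <- grepl("^ {5}\\S", fl)
  idx <- cumsum(is_key)
  genes <- list()
  for (i in seq_len(max(idx, 0))) {
    block <- fl[idx == i]
    key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
    if (key != "CDS") next
    txt <- paste(trimws(block[-1]), collapse = "\n")
    get_q <- function(q) {
      m <- regmatches(txt, regexpr(sprintf('/%s="[^"]*"', q), txt))
      if (length(m) == 0) return(NULL)
      gsub("\n", "", sub(sprintf('^/%s="', q), "", sub('"$', "", m)))
    }
    id <- get_q("gene")
    if (is.null(id)) id <- get_q("locus_tag")
    if (is.null(id)) id <- sprintf("CDS_%d", length(genes) + 1L)
    transl <- get_q("translation")
    if (is.null(transl)) {
      warning("CDS ", id, " lacks /translation; skipped")
      next
    }
    transl <- gsub("\\s", "", transl)
    prod <- get_q("product")
    label <- if (!is.null(prod) && prod %in% .PRODUCT_LABELS) prod else "other"
    genes[[length(genes) + 1L]] <- gene_record(id, label, sequence = transl)
  }
  if (length(genes) == 0) warning("GenBank record contains no usable CDS features")
  cluster_model(locus, genes)
}

#' Write the annotation table
#'
#' One TSV row per domain call with a stable column order and a deterministic
#' row order: modules in cluster order, domains in KS < AT < DH < ER < KR < ACP
#' order within each module.
#'
#' @param cluster a [cluster_model].
#' @param calls a calls data frame from [annotate_cluster()] (or built by
#'   hand with the same columns).
#' @param path output TSV path.
#' @export
write_annotation_table <- function(cluster, calls, path) {
  cols <- c("gene", "module", "kind", "subtype", "active", "motif_evidence",
            "stereo_outcome")
  if (nrow(calls)) {
    stopifnot(all(cols %in% names(calls)))
    known <- module_order(cluster)
    bad <- setdiff(unique(calls$module), known)
    if (length(bad))
      stop("call references unknown module(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(calls[, c("module", "kind")]))
      stop("duplicate (module, kind) calls")
    o <- order(match(calls$module, known), match(calls$kind, .DOMAIN_KINDS))
    calls <- calls[o, , drop = FALSE]
  }
  utils::write.table(calls[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
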