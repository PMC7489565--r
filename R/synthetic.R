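# Synthetic fixture generation: clusters with planted motif states and stored
# ground truth, GC-rich nucleotide templates with primer sites and deletions,
# and noisy peak lists. Everything is seeded and regenerates byte-identically.

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

# positions that must never be mutated: anchors plus a guard band
.protected_positions <- function(scaffold, guard = 2L) {
  prot <- integer(0)
  for (a in scaffold$anchors) {
    rng <- if (length(a) == 2) a[1]:a[2] else a
    prot <- c(prot, (min(rng) - guard):(max(rng) + guard))
  }
  unique(prot[prot >= 1 & prot <= nchar(scaffold$sequence)])
}

# Build one domain sequence: plant the spec's motif residues at the anchor
# columns of the packaged scaffold, then apply seeded neutral substitutions
# away from the anchors.
.make_domain <- function(kind, state, scaffolds, mutation_rate, guard, seed) {
  sc <- scaffolds[[kind]]
  ch <- strsplit(sc$sequence, "")[[1]]
  plant <- function(name, residues) {
    a <- sc$anchors[[name]]
    pos <- if (length(a) == 2) a[1]:a[2] else a
    if (length(pos) != nchar(residues))
      stop(kind, " anchor '", name, "': cannot plant ", nchar(residues),
           " residue(s) at a ", length(pos), "-column site")
    ch[pos] <<- strsplit(residues, "")[[1]]
  }
  delete <- integer(0)
  switch(kind,
    KS = plant("cat_cys", state$cat_residue),
    AT = plant("motif", state$motif),
    DH = {
      plant("ygp_tyr", if (isTRUE(state$ygp_tyr)) "Y" else "F")
      plant("cat_asp", if (isTRUE(state$cat_asp)) "D" else "E")
    },
    KR = {
      plant("cat_tyr", if (isTRUE(state$cat_tyr)) "Y" else "F")
      plant("ldd", if (isTRUE(state$ldd)) "LDD" else "AAD")
      plant("tyr_plus2", if (isTRUE(state$pro_at_tyr_plus2)) "P" else "A")
      if (isTRUE(state$nadph_deletion)) {
        a <- sc$anchors$nadph
        delete <- a[1]:a[2]
      }
    },
    ER = plant("key_tyr", if (isTRUE(state$key_tyr)) "Y" else "V"),
    ACP = NULL)
  prot <- .protected_positions(sc, guard)
  eligible <- setdiff(seq_along(ch), c(prot, delete))
  .with_seed(seed, {
    n_mut <- floor(mutation_rate * length(eligible))
    if (n_mut > 0) {
      at <- sample(eligible, n_mut)
      for (p in at) ch[p] <- sample(setdiff(.AA20, ch[p]), 1)
    }
  })
  if (length(delete)) ch <- ch[-delete]
  paste(ch, collapse = "")
}

# stable small-integer sub-seed per domain (kept well below 2^31)
.domain_seed <- function(seed, module_i, kind) {
  (seed %% 100000L) * 10000L + module_i * 10L + match(kind, .DOMAIN_KINDS)
}

#' Generate a synthetic cluster fixture from an architecture spec
#'
#' For every declared domain the packaged reference scaffold is copied, the
#' spec's motif residues are planted at the anchor columns, and seeded neutral
#' substitutions (default 10% of positions, never touching an anchor or its
#' 2-residue guard band) make the sequences non-identical to the scaffolds.
#' PKS proteins are the concatenation of their modules' domains; the module
#' map records the 0-based half-open domain coordinates.
#'
#' @param spec an [architecture_spec].
#' @param seed integer seed; identical (spec, seed) pairs regenerate
#'   byte-identical bundles.
#' @param dir output directory (created if needed); `NULL` returns the bundle
#'   in memory without writing files.
#' @param mutation_rate fraction of non-anchor positions substituted.
#' @param guard protected band (residues) around each anchor.
#' @param scaffolds scaffold set.
#' @return list of class `fixture_bundle`: `cluster` ([cluster_model]),
#'   `module_map`, `truth` (expected calls data frame), `manifest`, and file
#'   `paths` when `dir` was given.
#' @export
make_cluster <- function(spec, seed, dir = NULL, mutation_rate = 0.10,
                         guard = 2L, scaffolds = load_scaffolds()) {
  stopifnot(inherits(spec, "architecture_spec"))
  pks_ids <- unique(vapply(spec$modules, `[[`, character(1), "gene_id"))
  prot <- stats::setNames(rep("", length(pks_ids)), pks_ids)
  map_modules <- list()
  modules <- list()
  for (mi in seq_along(spec$modules)) {
    m <- spec$modules[[mi]]
    dom_seqs <- list()
    dom_coords <- list()
    for (kind in names(m$domains)) {
      s <- .make_domain(kind, m$domains[[kind]], scaffolds, mutation_rate,
                        guard, .domain_seed(seed, mi, kind))
      start <- nchar(prot[[m$gene_id]])
      prot[[m$gene_id]] <- paste0(prot[[m$gene_id]], s)
      dom_seqs[[kind]] <- s
      dom_coords[[kind]] <- c(start, start + nchar(s))
    }
    modules[[mi]] <- list(module_index = m$module_index, gene_id = m$gene_id,
                          domains = dom_seqs)
    map_modules[[mi]] <- list(module_index = m$module_index,
                              gene_id = m$gene_id, domains = dom_coords)
  }
  genes <- lapply(spec$genes, function(g)
    gene_record(g$gene_id, g$product_label,
                sequence = if (g$gene_id %in% pks_ids) prot[[g$gene_id]],
                cds_length_nt = g$cds_length_nt))
  cluster <- cluster_model(spec$cluster_id, genes, modules)
  map <- list(cluster_id = spec$cluster_id,
              genes = lapply(spec$genes, function(g)
                g[intersect(names(g), c("gene_id", "product_label",
                                        "cds_length_nt"))]),
              modules = map_modules)
  truth <- expected_calls(spec)
  manifest <- list(generator = "pksmith::make_cluster",
                   cluster_id = spec$cluster_id, seed = seed,
                   mutation_rate = mutation_rate, guard = guard,
                   scaffold_version = attr(scaffolds, "version"))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "cluster.fasta"),
                  module_map = file.path(dir, "module_map.json"),
                  truth = file.path(dir, "ground_truth.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    write_cluster_fasta(cluster, paths$fasta)
    jsonlite::write_json(map, paths$module_map, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  structure(list(cluster = cluster, module_map = map, truth = truth,
                 manifest = manifest, paths = paths),
            class = "fixture_bundle")
}

#' Expected annotator calls implied by an architecture spec
#'
#' The ground truth the annotator is tested against, derived purely from the
#' declared motif states (no sequences involved).
#'
#' @param spec an [architecture_spec].
#' @return data frame with columns module, kind, subtype, active,
#'   stereo_outcome.
#' @export
expected_calls <- function(spec) {
  rows <- list()
  add <- function(module, kind, subtype, active, stereo = "none")
    rows[[length(rows) + 1L]] <<- data.frame(
      module = as.character(module), kind = kind, subtype = subtype,
      active = active, stereo_outcome = stereo)
  for (m in spec$modules) {
    idx <- m$module_index
    for (kind in names(m$domains)) {
      st <- m$domains[[kind]]
      switch(kind,
        KS = if (st$cat_residue == "C") add(idx, "KS", "extension", TRUE)
             else if (st$cat_residue == "Q") add(idx, "KS", "KSQ", TRUE)
             else add(idx, "KS", "extension", FALSE),
        AT = {
          w <- st$motif
          sub <- if (w == "HASH") "relaxed_hybrid"
                 else if (grepl("^[HTVY]AFH$", w)) "acetate"
                 else if (grepl("^[YVW]ASH$", w)) "propionate"
                 else "unknown"
          add(idx, "AT", sub, sub != "unknown")
        },
        DH = if (isTRUE(st$ygp_tyr) && isTRUE(st$cat_asp))
               add(idx, "DH", "active", TRUE)
             else add(idx, "DH", "inactive", FALSE),
        KR = if (!isTRUE(st$cat_tyr) || isTRUE(st$nadph_deletion))
               add(idx, "KR", "inactive", FALSE)
             else if (isTRUE(st$ldd)) {
               if (isTRUE(st$pro_at_tyr_plus2)) add(idx, "KR", "B2", TRUE, "D")
               else add(idx, "KR", "B1", TRUE, "D")
             } else add(idx, "KR", "A", TRUE, "L"),
        ER = if (isTRUE(st$key_tyr)) add(idx, "ER", "L_configuring", TRUE, "L")
             else add(idx, "ER", "D_configuring", TRUE, "D"),
        ACP = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw a random architecture spec from the supported vocabulary
#'
#' Used for blind-recovery property testing: a loading module (KS^Q, hybrid
#' AT) followed by 2-6 extension modules with uniformly drawn AT motifs,
#' optional DH/ER/KR domains and random motif states.
#'
#' @param seed integer seed.
#' @param n_modules number of extension modules (default drawn from 2:6).
#' @return an [architecture_spec].
#' @export
random_architecture <- function(seed, n_modules = NULL) {
  .with_seed(seed, {
    if (is.null(n_modules)) n_modules <- sample(2:6, 1)
    at_motifs <- c("HAFH", "TAFH", "VAFH", "YAFH", "YASH", "VASH", "WASH",
                   "HASH", "QQQQ")
    mods <- list(list(module_index = "LM", gene_id = "pksA",
                      domains = list(KS = list(cat_residue = "Q"),
                                     AT = list(motif = "HASH"),
                                     ACP = list())))
    for (i in seq_len(n_modules)) {
      doms <- list(KS = list(cat_residue = sample(c("C", "C", "C", "Q", "A"), 1)),
                   AT = list(motif = sample(at_motifs, 1)))
      if (stats::runif(1) < 0.6)
        doms$DH <- list(ygp_tyr = stats::runif(1) < 0.7,
                        cat_asp = stats::runif(1) < 0.8)
      if (stats::runif(1) < 0.3)
        doms$ER <- list(key_tyr = stats::runif(1) < 0.5)
      if (stats::runif(1) < 0.8)
        doms$KR <- list(cat_tyr = stats::runif(1) < 0.8,
                        ldd = stats::runif(1) < 0.7,
                        pro_at_tyr_plus2 = stats::runif(1) < 0.3,
                        nadph_deletion = stats::runif(1) < 0.15)
      doms$ACP <- list()
      mods[[length(mods) + 1L]] <- list(module_index = i, gene_id = "pksA",
                                        domains = doms)
    }
    architecture_spec(sprintf("random-%d", seed),
                      genes = list(list(gene_id = "pksA",
                                        product_label = "PKS")),
                      modules = mods)
  })
}

#' Generate a nucleotide template with planted primer sites
#'
#' A seeded random template with a configurable GC fraction (default 0.70,
#' mimicking actinomycete DNA), with the forward primer planted on the plus
#' strand and the reverse complement of the reverse primer planted downstream,
#' and optionally a deletion applied between the two sites.
#'
#' @param length template length (nt) before any deletion.
#' @param fwd,rev primer sequences, 5'->3'.
#' @param fwd_pos,rev_pos 1-based start positions of the forward primer site
#'   and of the reverse-complement site.
#' @param deletion optional `c(start, length)` removed from the template;
#'   must not overlap a primer site.
#' @param seed integer seed.
#' @param gc GC fraction of the random background.
#' @param path optional FASTA output path.
#' @return template sequence string (written as FASTA when `path` is given).
#' @export
make_template <- function(length, fwd, rev, fwd_pos, rev_pos, deletion = NULL,
                          seed = 1L, gc = 0.70, path = NULL) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
  stopifnot(fwd_pos >= 1, rev_pos + nchar(rc) - 1 <= length,
            rev_pos > fwd_pos + nchar(fwd) - 1)
  ch <- .with_seed(seed, sample(c("G", "C", "A", "T"), length, replace = TRUE,
                                prob = c(gc / 2, gc / 2, (1 - gc) / 2,
                                         (1 - gc) / 2)))
  sites <- rbind(c(fwd_pos, fwd_pos + nchar(fwd) - 1L),
                 c(rev_pos, rev_pos + nchar(rc) - 1L))
  ch[sites[1, 1]:sites[1, 2]] <- strsplit(fwd, "")[[1]]
  ch[sites[2, 1]:sites[2, 2]] <- strsplit(rc, "")[[1]]
  if (!is.null(deletion)) {
    del <- deletion[1]:(deletion[1] + deletion[2] - 1L)
    overlaps <- any(vapply(1:2, function(i)
      any(del >= sites[i, 1] & del <= sites[i, 2]), logical(1)))
    if (overlaps) stop("deletion overlaps a primer site")
    ch <- ch[-del]
  }
  seq <- paste(ch, collapse = "")
  if (!is.null(path)) {
    set <- Biostrings::DNAStringSet(seq)
    names(set) <- sprintf("synthetic_template_seed%d", seed)
    Biostrings::writeXStringSet(set, path, width = 70L)
  }
  seq
}

#' Simulate a positive-mode peak list for a formula
#'
#' One peak per adduct at the computed average m/z plus seeded Gaussian
#' noise; intensities are drawn log-uniformly.
#'
#' @param f a [pk_formula].
#' @param adducts adduct definitions (default [pk_adducts()]).
#' @param mz_noise_sd Gaussian m/z noise, Da (>= 0).
#' @param seed integer seed.
#' @param path optional CSV output path.
#' @return a [pk_peaks] data frame.
#' @export
make_peaks <- function(f, adducts = pk_adducts(), mz_noise_sd = 0, seed = 1L,
                       path = NULL) {
  stopifnot(mz_noise_sd >= 0)
  if (nrow(adducts) == 0) {
    pk <- pk_peaks(numeric(0), numeric(0), "synthetic")
  } else {
    mz <- vapply(seq_len(nrow(adducts)), function(i)
      adduct_mz(f, list(delta = adducts$delta[[i]],
                        charge = adducts$charge[i]), "average"), numeric(1))
    pk <- .with_seed(seed, {
      noisy <- mz + stats::rnorm(length(mz), 0, mz_noise_sd)
      inten <- exp(stats::runif(length(mz), log(10), log(100)))
      pk_peaks(noisy, inten, sprintf("synthetic %s", format(f)))
    })
  }
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(pk), path, row.names = FALSE, quote = FALSE)
  }
  pk
}
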