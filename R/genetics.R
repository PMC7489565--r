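# In-frame deletion design validation, screening-amplicon arithmetic, primer
# site location on templates, and start-codon revision analysis.

#' Validate an in-frame deletion design
#'
#' @param gene_cds_length_nt CDS length of the target gene (nt).
#' @param deleted_length_nt length of the deleted segment (nt),
#'   `0 < deleted <= gene length`.
#' @param gene_id optional identifier carried into the report.
#' @return list: `gene_id`, `in_frame` (deleted length divisible by 3),
#'   `remaining_nt`, `deleted_fraction`. An out-of-frame design additionally
#'   raises a warning (it would frameshift the downstream coding sequence).
#' @examples
#' validate_inframe(1404, 906)  # in frame, 498 nt remain
#' @export
validate_inframe <- function(gene_cds_length_nt, deleted_length_nt,
                             gene_id = NA_character_) {
  stopifnot(gene_cds_length_nt > 0, deleted_length_nt > 0)
  if (deleted_length_nt > gene_cds_length_nt)
    stop("deleted length (", deleted_length_nt,
         ") exceeds the gene CDS length (", gene_cds_length_nt, ")")
  in_frame <- deleted_length_nt %% 3 == 0
  if (!in_frame)
    warning("deletion of ", deleted_length_nt,
            " nt is not a multiple of 3: out-of-frame design")
  list(gene_id = gene_id, in_frame = in_frame,
       remaining_nt = as.integer(gene_cds_length_nt - deleted_length_nt),
       deleted_fraction = deleted_length_nt / gene_cds_length_nt)
}

#' Predict the mutant screening-amplicon size
#'
#' Exact integer arithmetic: the screening primers flank the deletion, so the
#' mutant PCR product is the wild-type product minus the deleted length.
#'
#' @param wt_amplicon_nt wild-type PCR product size (nt).
#' @param deleted_length_nt deleted segment length (nt); must be smaller than
#'   the amplicon (the primers must flank the deletion).
#' @return integer mutant amplicon size.
#' @examples
#' predict_mutant_amplicon(1913, 906)  # 1007
#' @export
predict_mutant_amplicon <- function(wt_amplicon_nt, deleted_length_nt) {
  stopifnot(wt_amplicon_nt > 0, deleted_length_nt > 0)
  if (deleted_length_nt >= wt_amplicon_nt)
    stop("deletion (", deleted_length_nt, " nt) must be smaller than the ",
         "amplicon (", wt_amplicon_nt, " nt): primers must flank the deletion")
  as.integer(wt_amplicon_nt - deleted_length_nt)
}

#' Locate a PCR amplicon on a template
#'
#' Exact-match search: the forward primer on the plus strand and the reverse
#' complement of the reverse primer on the plus strand downstream of it. The
#' amplicon span is inclusive of both primer footprints (the standard PCR
#' product definition). Zero candidate amplicons and ambiguous layouts
#' (multiple forward or reverse sites that could pair) raise distinct errors.
#'
#' @param template nucleotide sequence (string).
#' @param fwd,rev primer sequences, 5'->3', at least 15 nt.
#' @return list: `start`, `end` (1-based inclusive), `length`.
#' @export
locate_amplicon <- function(template, fwd, rev) {
  stopifnot(nchar(fwd) >= 15, nchar(rev) >= 15,
            nchar(template) >= max(nchar(fwd), nchar(rev)))
  tm <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(fwd), tm)
  rcr <- Biostrings::reverseComplement(Biostrings::DNAString(rev))
  rhits <- Biostrings::matchPattern(rcr, tm)
  pairs <- expand.grid(f = seq_along(fhits), r = seq_along(rhits))
  if (nrow(pairs)) {
    ok <- Biostrings::start(rhits)[pairs$r] > Biostrings::end(fhits)[pairs$f]
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0)
    stop("no amplicon: primer pair does not define a product on this template")
  if (nrow(pairs) > 1)
    stop("ambiguous: ", nrow(pairs), " candidate amplicons on this template")
  s <- Biostrings::start(fhits)[pairs$f]
  e <- Biostrings::end(rhits)[pairs$r]
  list(start = s, end = e, length = e - s + 1L)
}

#' Scan for alternative upstream start codons
#'
#' Walks upstream of an annotated ATG in steps of one codon, stopping at the
#' first in-frame stop codon, and reports every in-frame ATG found together
#' with the peptide the revised start would prepend to the annotated protein.
#'
#' @param nt_context nucleotide sequence containing the annotated start and
#'   its upstream context.
#' @param annotated_start 1-based offset of the annotated ATG in `nt_context`.
#' @return list of class `start_revision`: `candidates` data frame
#'   (`offset_codons`, `position`, `added_peptide`); empty when no upstream
#'   in-frame ATG exists before a stop.
#' @export
revise_start <- function(nt_context, annotated_start) {
  stopifnot(annotated_start >= 1,
            annotated_start + 2 <= nchar(nt_context))
  if (toupper(substr(nt_context, annotated_start, annotated_start + 2)) != "ATG")
    warning("annotated start is not ATG")
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  k <- 1L
  repeat {
    pos <- annotated_start - 3L * k
    if (pos < 1) break
    codon <- toupper(substr(nt_context, pos, pos + 2))
    if (codon %in% stops) break
    if (codon == "ATG") {
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(
        substr(nt_context, pos, annotated_start - 1L))))
      rows[[length(rows) + 1L]] <- data.frame(
        offset_codons = k, position = pos, added_peptide = pep)
    }
    k <- k + 1L
  }
  candidates <- if (length(rows)) do.call(rbind, rev(rows)) else
    data.frame(offset_codons = integer(), position = integer(),
               added_peptide = character())
  structure(list(annotated_start = annotated_start, candidates = candidates),
            class = "start_revision")
}

#' @export
print.start_revision <- function(x, ...) {
  cat("<start_revision>", nrow(x$candidates), "upstream candidate(s)\n")
  if (nrow(x$candidates)) print(x$candidates)
  invisible(x)
}

#' Read the packaged deletion designs
#'
#' @param path JSON file of deletion designs (default: the packaged designs
#'   for the two cyclase knockouts and the tetronomycin-cluster homologue).
#' @return list of design records (gene_id, gene_cds_length_nt,
#'   deleted_length_nt, wt_amplicon_nt, notes).
#' @export
read_deletion_designs <- function(path = pk_extdata("deletion_designs.json")) {
  jsonlite::read_json(path, simplifyVector = FALSE)$designs
}
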