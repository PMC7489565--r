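# Positive-mode adduct m/z computation, peak matching, and the Delta-mass
# diagnosis used to identify the knockout shunt metabolite from its spectrum.

.ADDUCT_TABLE <- list(
  "[M+H]+"       = list(delta = c(H = 1), charge = 1L),
  "[M+Na]+"      = list(delta = c(Na = 1), charge = 1L),
  "[M+NH4]+"     = list(delta = c(N = 1, H = 4), charge = 1L),
  "[M+H-H2O]+"   = list(delta = c(H = -1, O = -1), charge = 1L),
  "[M+H-2H2O]+"  = list(delta = c(H = -3, O = -2), charge = 1L)
)

# Rounded nominal shift -> interpretation and the formula delta it implies.
.LOSS_TABLE <- list(
  "0"   = list(label = "same formula",            delta = c()),
  "-14" = list(label = "demethylation (-CH2)",    delta = c(C = -1, H = -2)),
  "-16" = list(label = "absent hydroxyl (-O)",    delta = c(O = -1)),
  "-18" = list(label = "dehydration (-H2O)",      delta = c(H = -2, O = -1)),
  "16"  = list(label = "additional hydroxyl (+O)", delta = c(O = 1))
)

#' The packaged positive-mode adduct definitions
#'
#' @return data frame with columns `name`, `charge` and a list-column `delta`
#'   of signed element counts. The five adducts are \code{[M+H]+},
#'   \code{[M+Na]+}, \code{[M+NH4]+}, \code{[M+H-H2O]+}, \code{[M+H-2H2O]+}.
#' @export
pk_adducts <- function() {
  data.frame(
    name = names(.ADDUCT_TABLE),
    charge = vapply(.ADDUCT_TABLE, function(a) a$charge, integer(1)),
    delta = I(lapply(.ADDUCT_TABLE, function(a) a$delta)),
    row.names = NULL
  )
}

#' m/z of an adduct ion
#'
#' The electron mass is subtracted once per positive charge.
#'
#' @param f neutral molecule [pk_formula].
#' @param adduct adduct name (see [pk_adducts()]) or a list with elements
#'   `delta` (signed element counts) and `charge`.
#' @param mode mass mode passed to [formula_mass()].
#' @return m/z in Th (Da for singly charged ions).
#' @examples
#' adduct_mz(parse_formula("H2O"), "[M+H]+", "nominal")  # 19
#' @export
adduct_mz <- function(f, adduct, mode = c("average", "monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  if (is.character(adduct)) {
    if (!adduct %in% names(.ADDUCT_TABLE))
      stop("unknown adduct: ", adduct)
    adduct <- .ADDUCT_TABLE[[adduct]]
  }
  ion <- fml_apply(f, adduct$delta)  # errors if an element would go negative
  (formula_mass(ion, mode) - .ELECTRON_MASS * adduct$charge) / adduct$charge
}

#' All packaged adduct m/z values for a formula
#'
#' @inheritParams adduct_mz
#' @return data frame with columns `adduct`, `mz`.
#' @export
compute_adducts <- function(f, mode = c("average", "monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  nm <- names(.ADDUCT_TABLE)
  mz <- vapply(nm, function(a) {
    tryCatch(adduct_mz(f, a, mode), error = function(e) NA_real_)
  }, numeric(1))
  data.frame(adduct = nm, mz = unname(mz), row.names = NULL)
}

#' Read a peak list from CSV
#'
#' Expects columns `mz` and `intensity`; lines starting with `#` are treated
#' as provenance comments. Peaks are sorted ascending on load.
#'
#' @param path CSV file path.
#' @param source_label optional label stored as an attribute.
#' @return data frame of class `pk_peaks`, sorted by m/z.
#' @export
read_peaks <- function(path, source_label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak list must have columns mz, intensity: ", path)
  pk_peaks(df$mz, df$intensity, source_label)
}

#' Construct a peak list
#'
#' @param mz strictly positive m/z values.
#' @param intensity non-negative intensities (default 1).
#' @param source_label free-text origin label.
#' @return data frame of class `pk_peaks`, sorted by m/z.
#' @export
pk_peaks <- function(mz, intensity = rep(1, length(mz)), source_label = "") {
  if (length(mz) && any(mz <= 0)) stop("m/z values must be strictly positive")
  if (length(intensity) && any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  out <- data.frame(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
  attr(out, "source_label") <- source_label
  class(out) <- c("pk_peaks", "data.frame")
  out
}

#' Match observed peaks to the computed adducts of a formula
#'
#' Candidate (adduct, peak) pairs within `tolerance` are assigned greedily,
#' smallest absolute mass error first; each peak and each adduct is used at
#' most once.
#'
#' @param peaks a [pk_peaks] data frame.
#' @param f neutral molecule [pk_formula].
#' @param tolerance match window in Da (default 0.5, unit-resolution ion trap).
#' @param mode mass mode (default `"average"`).
#' @return list with `matches` (data frame: adduct, mz_calc, mz_obs,
#'   delta_da, delta_ppm, intensity) and `unmatched_adducts` (character).
#' @export
match_peaks <- function(peaks, f, tolerance = 0.5, mode = "average") {
  stopifnot(tolerance > 0)
  ad <- compute_adducts(f, mode)
  ad <- ad[!is.na(ad$mz), , drop = FALSE]
  cand <- expand.grid(ai = seq_len(nrow(ad)), pi = seq_len(nrow(peaks)))
  if (nrow(ad) == 0 || nrow(peaks) == 0) cand <- cand[0, , drop = FALSE]
  if (nrow(cand)) {
    cand$err <- peaks$mz[cand$pi] - ad$mz[cand$ai]
    cand <- cand[abs(cand$err) <= tolerance, , drop = FALSE]
    cand <- cand[order(abs(cand$err), cand$ai, cand$pi), , drop = FALSE]
  }
  used_a <- logical(nrow(ad)); used_p <- logical(nrow(peaks))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    ai <- cand$ai[i]; pi <- cand$pi[i]
    if (used_a[ai] || used_p[pi]) next
    used_a[ai] <- TRUE; used_p[pi] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      adduct = ad$adduct[ai], mz_calc = ad$mz[ai], mz_obs = peaks$mz[pi],
      delta_da = cand$err[i], delta_ppm = 1e6 * cand$err[i] / ad$mz[ai],
      intensity = peaks$intensity[pi])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(adduct = character(), mz_calc = numeric(), mz_obs = numeric(),
               delta_da = numeric(), delta_ppm = numeric(), intensity = numeric())
  matches <- matches[order(match(matches$adduct, ad$adduct)), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches, unmatched_adducts = ad$adduct[!used_a])
}

#' Diagnose the mass shift between a reference and an unknown metabolite
#'
#' Assigns the reference peaks to the computed adducts of `ref_formula`,
#' estimates the modal integer mass shift between those assigned ions and the
#' unknown peak list, interprets the shift through a small loss table
#' (absent hydroxyl, dehydration, demethylation, additional hydroxyl),
#' proposes a formula for the unknown, and confirms it by re-matching.
#'
#' @param ref_formula [pk_formula] of the reference compound.
#' @param peaks_ref,peaks_unknown [pk_peaks] for the two spectra.
#' @param tolerance matching tolerance in Da.
#' @param mode mass mode (default `"average"`).
#' @param max_shift largest |shift| considered when voting (Da).
#' @return list of class `pk_diagnosis`: `status` ("diagnosed"/"undiagnosed"),
#'   `shift` (modal integer shift in Da), `interpretation`,
#'   `proposed_formula`, `confirmation` (match_peaks result), `votes`.
#' @export
diagnose_delta <- function(ref_formula, peaks_ref, peaks_unknown,
                           tolerance = 0.5, mode = "average", max_shift = 50) {
  if (nrow(peaks_ref) == 0 || nrow(peaks_unknown) == 0)
    stop("both peak lists must be non-empty")
  ref_match <- match_peaks(peaks_ref, ref_formula, tolerance, mode)
  assigned <- ref_match$matches
  undiag <- function(reason) {
    structure(list(status = "undiagnosed", reason = reason, shift = NA_real_,
                   interpretation = NA_character_, proposed_formula = NULL,
                   confirmation = NULL, votes = integer()),
              class = "pk_diagnosis")
  }
  if (nrow(assigned) == 0)
    return(undiag("no reference peak could be assigned to an adduct"))
  shifts <- outer(peaks_unknown$mz, assigned$mz_obs, "-")
  shifts <- shifts[abs(shifts) <= max_shift]
  if (length(shifts) == 0)
    return(undiag("no unknown peak within the shift window"))
  votes <- table(round(shifts))
  top <- votes[votes == max(votes)]
  # tie-break toward the smallest absolute shift
  shift <- as.integer(names(top)[order(abs(as.integer(names(top))))][1])
  if (max(votes) < 2 && nrow(assigned) >= 2)
    return(undiag("no consistent shift across adducts"))
  key <- as.character(shift)
  if (!key %in% names(.LOSS_TABLE))
    return(undiag(sprintf("shift %+d Da not in the loss table", shift)))
  loss <- .LOSS_TABLE[[key]]
  proposed <- fml_apply(ref_formula, loss$delta)
  conf <- match_peaks(peaks_unknown, proposed, tolerance, mode)
  structure(list(status = "diagnosed", shift = shift,
                 interpretation = loss$label, proposed_formula = proposed,
                 confirmation = conf, votes = votes),
            class = "pk_diagnosis")
}

#' @export
print.pk_diagnosis <- function(x, ...) {
  cat("<mass-shift diagnosis>\n")
  if (x$status == "undiagnosed") {
    cat("  undiagnosed:", x$reason, "\n")
  } else {
    cat(sprintf("  modal shift: %+d Da (%s)\n", x$shift, x$interpretation))
    cat("  proposed formula:", format(x$proposed_formula), "\n")
    cat("  confirmed adducts:", nrow(x$confirmation$matches), "\n")
  }
  invisible(x)
}
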