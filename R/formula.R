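# Molecular formula arithmetic.
#
# A pk_formula is a named integer vector of non-negative element counts kept in
# Hill order (C, H, then alphabetically). Signed element-count maps (reaction
# deltas, adduct deltas) are plain named numerics and are only ever combined
# with a pk_formula through fml_apply(), which enforces non-negativity of the
# result.

.ELEMENT_MASS <- list(
  monoisotopic = c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                   O = 15.9949146196, Na = 22.9897692809, S = 31.97207100,
                   P = 30.97376163),
  average      = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                   Na = 22.98976928, S = 32.06, P = 30.973761998),
  nominal      = c(C = 12, H = 1, N = 14, O = 16, Na = 23, S = 32, P = 31)
)

.ELECTRON_MASS <- 0.00054857990907

.hill_order <- function(elements) {
  rest <- sort(setdiff(elements, c("C", "H")))
  intersect(c("C", "H", rest), elements)
}

#' Create a molecular formula
#'
#' @param counts named numeric vector of non-negative integer element counts,
#'   e.g. `c(C = 42, H = 64, O = 12)`. Zero counts are dropped.
#' @return an object of class `pk_formula` (named integer vector, Hill order).
#' @examples
#' pk_formula(c(C = 42, H = 64, O = 12))
#' @export
pk_formula <- function(counts) {
  if (length(counts) == 0) {
    out <- integer(0)
    class(out) <- "pk_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("element counts must be named")
  unknown <- setdiff(names(counts), names(.ELEMENT_MASS$nominal))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(counts < 0))
    stop("element counts must be non-negative")
  if (any(counts != round(counts)))
    stop("element counts must be integers")
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0]
  out <- as.integer(counts[.hill_order(names(counts))])
  names(out) <- .hill_order(names(counts))
  class(out) <- "pk_formula"
  out
}

#' Parse a Hill-notation formula string
#'
#' @param x a string such as `"C42H64O12"`.
#' @return a [pk_formula].
#' @examples
#' parse_formula("C42H64O12")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  x <- trimws(x)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", x))
    stop("cannot parse formula string: '", x, "'")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.numeric(n), 1)
  pk_formula(stats::setNames(n, el))
}

#' @method format pk_formula
#' @export
format.pk_formula <- function(x, ...) {
  if (length(x) == 0) return("")
  paste0(names(x), ifelse(unclass(x) > 1, unclass(x), ""), collapse = "")
}

#' @export
print.pk_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.pk_formula <- function(x, ...) format(x)

#' Apply a signed element-count delta to a formula
#'
#' @param f a [pk_formula].
#' @param delta named numeric vector of signed element counts (may be empty).
#' @return a [pk_formula]; errors if any element count would go negative.
#' @export
fml_apply <- function(f, delta) {
  stopifnot(inherits(f, "pk_formula"))
  if (length(delta) == 0) return(f)
  els <- union(names(f), names(delta))
  v <- stats::setNames(numeric(length(els)), els)
  v[names(f)] <- v[names(f)] + unclass(f)
  for (e in names(delta)) v[e] <- v[e] + delta[[e]]
  if (any(v < 0))
    stop("delta makes element count negative: ",
         paste(names(v)[v < 0], collapse = ", "))
  pk_formula(v)
}

#' Signed element-count difference between two formulas
#'
#' @param a,b [pk_formula] objects.
#' @return named numeric vector `a - b` (zeros dropped).
#' @export
fml_diff <- function(a, b) {
  els <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(els)), els)
  v[names(a)] <- v[names(a)] + unclass(a)
  v[names(b)] <- v[names(b)] - unclass(b)
  v[v != 0]
}

#' Mass of a molecular formula
#'
#' @param f a [pk_formula].
#' @param mode `"average"` (default), `"monoisotopic"` or `"nominal"`
#'   (integer element masses).
#' @return mass in Da.
#' @examples
#' formula_mass(parse_formula("H2O"), "nominal")  # 18
#' @export
formula_mass <- function(f, mode = c("average", "monoisotopic", "nominal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(f, "pk_formula"))
  tab <- .ELEMENT_MASS[[mode]]
  unknown <- setdiff(names(f), names(tab))
  if (length(unknown))
    stop("no mass for element(s): ", paste(unknown, collapse = ", "))
  sum(tab[names(f)] * unclass(f))
}
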