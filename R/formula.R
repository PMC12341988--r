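## Elemental formula utilities.
##
## Formulas follow the flat convention used by genome-scale models
## ("C10H12N5O13P3"); element symbols are one capital letter optionally
## followed by a lowercase letter, counts may be fractional (lumped
## pseudo-metabolites). "R" and "X" are placeholder symbols for residues
## of unspecified composition; metabolites carrying them are excluded
## from balance checking.

.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.99, Mg = 24.305, Cl = 35.45, K = 39.098, Ca = 40.078,
  Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546,
  Zn = 65.38, Se = 78.971, Mo = 95.95, W = 183.84
)

#' Parse an elemental formula
#'
#' @param formula a formula string such as `"CH4"` or `"C21H26N7O14P2"`;
#'   counts may be fractional.
#' @return named numeric vector of element counts; `numeric(0)` for an
#'   empty or `NA` formula.
#' @examples
#' parse_formula("CH4")
#' parse_formula("C3H5.5O2")
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  pieces <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula))[[1]]
  if (sum(nchar(pieces)) != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  els <- sub("^([A-Z][a-z]?).*$", "\\1", pieces)
  cnt <- sub("^[A-Z][a-z]?", "", pieces)
  cnt <- ifelse(nzchar(cnt), suppressWarnings(as.numeric(cnt)), 1)
  if (anyNA(cnt)) stop("malformed formula: '", formula, "'")
  tapply_sum <- tapply(cnt, els, sum)
  out <- as.numeric(tapply_sum)
  names(out) <- names(tapply_sum)
  out[out != 0]
}

#' Does a formula contain placeholder residues?
#' @param formula formula string.
#' @return logical; `TRUE` for R-group / X placeholders or missing formulas.
#' @export
has_placeholder <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(TRUE)
  counts <- tryCatch(parse_formula(formula), error = function(e) NULL)
  if (is.null(counts)) return(TRUE)
  any(names(counts) %in% c("R", "X"))
}

#' Molecular weight from a formula
#'
#' @param formula formula string (or named count vector from
#'   [parse_formula()]).
#' @return weight in g/mol; `NA` if the formula is missing, malformed or
#'   contains placeholder residues or unknown elements.
#' @examples
#' molecular_weight("CH4")   # 16.043
#' molecular_weight("CO2")   # 44.009
#' @export
molecular_weight <- function(formula) {
  counts <- if (is.character(formula)) {
    tryCatch(parse_formula(formula), error = function(e) return(NA))
  } else formula
  if (length(counts) == 1 && is.na(counts[1])) return(NA_real_)
  if (length(counts) == 0) return(NA_real_)
  if (!all(names(counts) %in% names(.atomic_weights))) return(NA_real_)
  sum(.atomic_weights[names(counts)] * counts)
}

#' Render element counts back to a formula string
#' @param counts named numeric vector of element counts.
#' @return formula string in Hill-ish order (C, H, then alphabetical).
#' @keywords internal
format_formula <- function(counts) {
  counts <- counts[abs(counts) > 1e-12]
  if (!length(counts)) return("")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  counts <- counts[ord]
  fmt1 <- function(x) {
    if (abs(x - round(x)) < 1e-9) {
      if (round(x) == 1) "" else as.character(round(x))
    } else sub("0+$", "", sprintf("%.6f", x))
  }
  paste0(vapply(seq_along(counts), function(i) {
    paste0(names(counts)[i], fmt1(counts[i]))
  }, character(1)), collapse = "")
}
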