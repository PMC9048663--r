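#' Chemical formula objects
#'
#' A `chem_formula` is a bag of element counts plus a flag marking formulas
#' that contain generic-group tokens (`R`, `X`, `*`) and therefore do not
#' determine an exact elemental composition. Such formulas take part in
#' mass-balance checking only insofar as they force the result to
#' "undetermined".
#'
#' @param counts named numeric vector of element counts; names are element
#'   symbols (`[A-Z][a-z]?`) or generic-group tokens, values positive integers.
#' @param indeterminate logical; `TRUE` when the formula contains a
#'   generic-group token.
#' @return An object of class `chem_formula`.
#' @export
chem_formula <- function(counts, indeterminate = any(names(counts) %in% .generic_tokens)) {
  counts <- counts[order(names(counts))]
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("formula counts must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  structure(list(counts = counts, indeterminate = isTRUE(indeterminate)),
            class = "chem_formula")
}

.generic_tokens <- c("R", "X", "*")

#' Parse a chemical formula string
#'
#' Grammar: a sequence of tokens, each an element symbol `[A-Z][a-z]?`
#' followed by an optional positive integer, a generic-group token (`R`, `X`
#' or `*`) with optional multiplier, or a single-level parenthesized group
#' followed by an integer multiplier, e.g. `"CH3(CH2)2CH3"`. Repeated symbols
#' are summed; generic groups flag the formula as indeterminate. `R` and `X`
#' followed by a lowercase letter are ordinary two-letter elements (Rb, Xe,
#' ...), not generic groups.
#'
#' @param text formula string.
#' @return A [chem_formula()].
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CH3(CH2)2CH3")   # C4 H10
#' parse_formula("C5H8NO4R")       # indeterminate
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula", call. = FALSE)
  acc <- numeric(0)
  add <- function(sym, n) {
    acc[sym] <<- if (is.na(acc[sym])) n else acc[sym] + n
  }
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    if (substr(rest, 1, 1) == "(") {
      m <- regmatches(rest, regexec("^\\(([^()]+)\\)([0-9]+)?", rest))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("unbalanced parenthesis in formula at position %d", i), call. = FALSE)
      }
      inner <- parse_formula(m[2])
      mult <- if (nzchar(m[3])) as.numeric(m[3]) else 1
      for (sym in names(inner$counts)) add(sym, inner$counts[[sym]] * mult)
      i <- i + nchar(m[1])
    } else {
      m <- regmatches(rest, regexec("^([A-Z][a-z]?|\\*)([0-9]+)?", rest))[[1]]
      if (length(m) == 0L || !nzchar(m[1])) {
        stop(sprintf("illegal character '%s' in formula at position %d",
                     substr(rest, 1, 1), i), call. = FALSE)
      }
      cnt <- if (nzchar(m[3])) as.numeric(m[3]) else 1
      if (cnt == 0) {
        stop(sprintf("zero count for '%s' at position %d", m[2], i), call. = FALSE)
      }
      add(m[2], cnt)
      i <- i + nchar(m[1])
    }
  }
  chem_formula(acc)
}

#' Render a formula in Hill order
#'
#' Carbon first, then hydrogen, then all remaining symbols alphabetically
#' (generic-group tokens last). Counts of one are omitted. The output parses
#' back to an equal `chem_formula`.
#'
#' @param formula a [chem_formula()] or `NULL`.
#' @return A single string, or `NA_character_` for `NULL` input.
#' @export
formula_to_string <- function(formula) {
  if (is.null(formula)) return(NA_character_)
  stopifnot(inherits(formula, "chem_formula"))
  syms <- names(formula$counts)
  generic <- syms %in% .generic_tokens
  lead <- intersect(c("C", "H"), syms[!generic])
  ordered <- c(lead, setdiff(sort(syms[!generic]), lead), sort(syms[generic]))
  paste0(vapply(ordered, function(s) {
    k <- formula$counts[[s]]
    if (k == 1) s else paste0(s, format(k, scientific = FALSE))
  }, character(1)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", formula_to_string(x),
      if (x$indeterminate) " (indeterminate)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) formula_to_string(x)
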