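#' @keywords internal
"_PACKAGE"

#' @useDynLib grnsets
#' @importFrom rlang .data %||% abort
#' @importFrom stats optim predict setNames median rnorm runif cor
#' @importFrom utils head
NULL

# Canonical vocabulary -------------------------------------------------------

#' Genes and regulators of the mouth-form network
#'
#' The network comprises three genes, each with an associated protein that can
#' act as a regulator: *eud-1* (protein EUD-1, symbol `"E"`), *nhr-40*
#' (NHR-40, `"N"`) and *sult-1* (SULT-1, `"S"`).
#'
#' @return `grn_genes()` returns the gene names in canonical order;
#'   `grn_regulators()` the corresponding one-letter protein symbols.
#' @export
#' @examples
#' grn_genes()
#' grn_regulators()
grn_genes <- function() c("eud-1", "nhr-40", "sult-1")

#' @rdname grn_genes
#' @export
grn_regulators <- function() c("E", "N", "S")

# gene <-> protein symbol maps
gene_to_regulator <- function(gene) {
  m <- setNames(grn_regulators(), grn_genes())
  unname(m[gene])
}

regulator_to_gene <- function(reg) {
  m <- setNames(grn_genes(), grn_regulators())
  unname(m[reg])
}

# Production terms -----------------------------------------------------------

#' Construct a Hill-type production term
#'
#' A production term is a product of one or two Hill factors in the regulator
#' proteins, multiplying the maximal regulated transcription rate of a target
#' gene. Each factor is either an activation `x/(K + x)` or a repression
#' `K/(K + x)`. Single-factor terms may carry a Hill exponent of 2
#' (cooperative binding); two-factor terms must use distinct regulators and
#' exponent 1. A term with zero factors (constant 0, i.e. no regulated
#' production, only basal) arises from knock-out reduction.
#'
#' @param regulators character vector (length 0-2) of regulator symbols from
#'   [grn_regulators()].
#' @param signs character vector, same length, each `"activation"` or
#'   `"repression"`.
#' @param exponent integer Hill exponent, 1 or 2 (2 only for single factors).
#' @return An object of class `grn_term`.
#' @export
#' @examples
#' grn_term("N", "activation")
#' grn_term("E", "activation", exponent = 2)
#' grn_term(c("N", "S"), c("activation", "repression"))
grn_term <- function(regulators = character(), signs = character(),
                     exponent = 1L) {
  regulators <- as.character(regulators)
  signs <- as.character(signs)
  exponent <- as.integer(exponent)
  if (length(regulators) != length(signs)) {
    abort("`regulators` and `signs` must have the same length.")
  }
  if (length(regulators) > 2) {
    abort("a production term has at most two Hill factors.")
  }
  if (!all(regulators %in% grn_regulators())) {
    abort("regulators must be drawn from grn_regulators().")
  }
  if (!all(signs %in% c("activation", "repression"))) {
    abort('signs must be "activation" or "repression".')
  }
  if (!exponent %in% c(1L, 2L)) abort("`exponent` must be 1 or 2.")
  if (length(regulators) == 2) {
    if (regulators[1] == regulators[2]) {
      abort("two-factor terms must use distinct regulators.")
    }
    if (exponent != 1L) {
      abort("two-factor terms must have exponent 1.")
    }
  }
  structure(
    list(regulators = regulators, signs = signs, exponent = exponent),
    class = "grn_term"
  )
}

#' @export
format.grn_term <- function(x, ...) term_signature(x)

#' @export
print.grn_term <- function(x, ...) {
  cat("<grn_term> ", term_signature(x), "\n", sep = "")
  invisible(x)
}

#' Compact text signature of a production term
#'
#' @param term a [grn_term()].
#' @return A string such as `"act(N)*act(S)"` or `"act(E)^2"`; the empty term
#'   renders as `"0"`.
#' @export
term_signature <- function(term) {
  stopifnot(inherits(term, "grn_term"))
  if (length(term$regulators) == 0) return("0")
  abbrev <- c(activation = "act", repression = "rep")
  parts <- paste0(abbrev[term$signs], "(", term$regulators, ")")
  sig <- paste(parts, collapse = "*")
  if (term$exponent == 2L) sig <- paste0(sig, "^2")
  sig
}

#' Regulators referenced by a term
#' @param term a [grn_term()].
#' @return Character vector of regulator symbols (possibly empty).
#' @export
term_regulators <- function(term) term$regulators

#' Enumerate the production-term library for a set of regulators
#'
#' Generates, in a fixed documented order, every admissible Hill-type
#' production term over the available regulator proteins: for `r` regulators
#' there are `4 r + 4 choose(r, 2)` terms (24 for the full three-regulator
#' library, 12 when one protein is removed by a knock-out).
#'
#' The canonical ordering is: for each regulator in E, N, S order, the single
#' activation then the single repression (2r terms); then the squared
#' (cooperative) activation and repression in the same regulator order (2r);
#' then, for each regulator pair in (E,N), (E,S), (N,S) order, the four sign
#' combinations act*act, act*rep, rep*act, rep*rep.
#'
#' @param regulators character vector of available regulator symbols, a
#'   nonempty subset of [grn_regulators()].
#' @return A list of [grn_term()] objects.
#' @export
#' @examples
#' length(enumerate_terms(c("E", "N", "S"))) # 24
#' length(enumerate_terms(c("N", "S")))      # 12
enumerate_terms <- function(regulators = grn_regulators()) {
  regulators <- unique(as.character(regulators))
  if (length(regulators) == 0) abort("at least one regulator is required.")
  if (!all(regulators %in% grn_regulators())) {
    abort("regulators must be drawn from grn_regulators().")
  }
  regs <- grn_regulators()[grn_regulators() %in% regulators]
  terms <- list()
  for (r in regs) {
    terms <- c(terms, list(grn_term(r, "activation"), grn_term(r, "repression")))
  }
  for (r in regs) {
    terms <- c(terms, list(
      grn_term(r, "activation", exponent = 2L),
      grn_term(r, "repression", exponent = 2L)
    ))
  }
  if (length(regs) >= 2) {
    pairs <- utils::combn(regs, 2, simplify = FALSE)
    sign_combos <- list(
      c("activation", "activation"), c("activation", "repression"),
      c("repression", "activation"), c("repression", "repression")
    )
    for (pr in pairs) {
      for (sc in sign_combos) terms <- c(terms, list(grn_term(pr, sc)))
    }
  }
  terms
}

#' Tabulate a term library
#'
#' @param terms a list of [grn_term()]s, e.g. from [enumerate_terms()].
#' @return A tibble with columns `term_index` (0-based), `signature`,
#'   `n_factors`, `exponent` and logical `uses_E`, `uses_N`, `uses_S`.
#' @export
term_table <- function(terms) {
  tibble::tibble(
    term_index = seq_along(terms) - 1L,
    signature = vapply(terms, term_signature, character(1)),
    n_factors = vapply(terms, function(t) length(t$regulators), integer(1)),
    exponent = vapply(terms, function(t) t$exponent, integer(1)),
    uses_E = vapply(terms, function(t) "E" %in% t$regulators, logical(1)),
    uses_N = vapply(terms, function(t) "N" %in% t$regulators, logical(1)),
    uses_S = vapply(terms, function(t) "S" %in% t$regulators, logical(1))
  )
}
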