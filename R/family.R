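# Combinatorial model families and individual network structures.

#' Build a combinatorial family of regulatory network models
#'
#' A family assigns to every modelled gene one production term from the term
#' library over the available regulators; with `b` library terms and `g` genes
#' the family has `b^g` members. The wild-type family over all three genes has
#' `24^3 = 13824` members; each knock-out family has `12^2 = 144`.
#'
#' Families are lazy: individual members are materialized on demand with
#' [model_from_index()].
#'
#' @param regulators available regulator symbols (proteins present).
#' @param genes modelled target genes, in canonical order.
#' @param knockout the knocked-out gene, or `NULL` for wild type.
#' @return An object of class `grn_family` with fields `regulators`, `genes`,
#'   `terms` (the term library), `base` (terms per gene), `size`, `knockout`.
#' @export
#' @examples
#' build_family()$size                   # 13824
#' knockout_family("eud-1")$size         # 144
build_family <- function(regulators = grn_regulators(), genes = grn_genes(),
                         knockout = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0) abort("at least one target gene is required.")
  if (!all(genes %in% grn_genes())) abort("unknown gene name.")
  genes <- grn_genes()[grn_genes() %in% genes]
  if (!is.null(knockout)) {
    if (knockout %in% genes) abort("the knocked-out gene cannot be modelled.")
    if (gene_to_regulator(knockout) %in% regulators) {
      abort("the knocked-out gene's protein cannot remain a regulator.")
    }
  }
  terms <- enumerate_terms(regulators)
  structure(
    list(
      regulators = grn_regulators()[grn_regulators() %in% regulators],
      genes = genes,
      terms = terms,
      base = length(terms),
      size = length(terms)^length(genes),
      knockout = knockout
    ),
    class = "grn_family"
  )
}

#' @rdname build_family
#' @param gene gene to knock out, `"eud-1"` or `"sult-1"`.
#' @export
knockout_family <- function(gene) {
  reduce_for_knockout(build_family(), gene)
}

#' @export
print.grn_family <- function(x, ...) {
  cat("<grn_family> ", x$size, " models: ", x$base, " terms per gene over {",
      paste(x$genes, collapse = ", "), "}",
      if (!is.null(x$knockout)) paste0(" [", x$knockout, " knock-out]"), "\n",
      sep = "")
  invisible(x)
}

#' Materialize one model structure from its family index
#'
#' Model indices are 0-based and encode the per-gene term choices in mixed
#' radix: `index = i1 * b^(g-1) + i2 * b^(g-2) + ... + ig`, with `b` the
#' number of library terms, digits in canonical gene order (*eud-1*,
#' *nhr-40*, *sult-1*) and `i` the 0-based term index.
#'
#' @param family a [build_family()] object.
#' @param index integer in `[0, family$size)`.
#' @return An object of class `grn_model`: a named list of production terms
#'   per gene plus `knockout`, `regulators` and `model_index`.
#' @export
#' @examples
#' fam <- build_family()
#' model_from_index(fam, 11574)
model_from_index <- function(family, index) {
  stopifnot(inherits(family, "grn_family"))
  index <- as.numeric(index)
  if (length(index) != 1 || is.na(index) || index != floor(index) ||
      index < 0 || index >= family$size) {
    abort(sprintf("`index` must be an integer in [0, %d).", family$size))
  }
  digits <- index_to_digits(index, family$base, length(family$genes))
  terms <- setNames(family$terms[digits + 1L], family$genes)
  new_grn_model(terms, family$knockout, family$regulators, index)
}

index_to_digits <- function(index, base, n) {
  digits <- integer(n)
  for (k in n:1) {
    digits[k] <- index %% base
    index <- index %/% base
  }
  digits
}

new_grn_model <- function(terms, knockout, regulators, model_index = NA_real_) {
  structure(
    list(terms = terms, knockout = knockout, regulators = regulators,
         model_index = model_index),
    class = "grn_model"
  )
}

#' @export
print.grn_model <- function(x, ...) {
  cat("<grn_model>",
      if (!is.na(x$model_index)) paste0(" index ", format(x$model_index, scientific = FALSE)),
      if (!is.null(x$knockout)) paste0(" [", x$knockout, " knock-out]"),
      "\n", sep = "")
  for (g in names(x$terms)) {
    cat("  ", format(g, width = 7), " <- ", term_signature(x$terms[[g]]), "\n",
        sep = "")
  }
  invisible(x)
}

#' Recover the family index of a model structure
#'
#' The exact inverse of [model_from_index()]: matches each gene's term to the
#' family's term library by signature and re-encodes the mixed-radix index.
#'
#' @param family a [build_family()] object.
#' @param model a `grn_model` whose genes equal the family's genes.
#' @return The 0-based integer index.
#' @export
index_of_model <- function(family, model) {
  stopifnot(inherits(family, "grn_family"), inherits(model, "grn_model"))
  if (!identical(names(model$terms), family$genes)) {
    abort("model genes do not match the family's genes.")
  }
  sigs <- vapply(family$terms, term_signature, character(1))
  index <- 0
  for (g in family$genes) {
    i <- match(term_signature(model$terms[[g]]), sigs)
    if (is.na(i)) {
      abort(sprintf("term %s of gene %s is not in the family's library.",
                    term_signature(model$terms[[g]]), g))
    }
    index <- index * family$base + (i - 1L)
  }
  index
}

#' Reduce a model or family for a gene knock-out
#'
#' Knocking out a gene removes its mRNA and protein equations and every Hill
#' factor involving its protein from the remaining genes' production terms.
#' For a family this restricts the term library to the 12 terms over the two
#' remaining regulators; for an individual model, a two-factor term keeps its
#' retained factor, and a term that is purely a function of the knocked-out
#' protein collapses to no regulated production (basal transcription only).
#'
#' @param x a `grn_family` or `grn_model`.
#' @param gene the gene to knock out.
#' @return The reduced object of the same class. A reduced individual model
#'   keeps a `model_index` only if every reduced term is in the knock-out
#'   library (an empty term is not).
#' @export
#' @examples
#' reduce_for_knockout(build_family(), "eud-1")$size  # 144
reduce_for_knockout <- function(x, gene) {
  UseMethod("reduce_for_knockout")
}

#' @export
reduce_for_knockout.grn_family <- function(x, gene) {
  if (!gene %in% x$genes) abort(sprintf("gene %s is not in the family.", gene))
  build_family(
    regulators = setdiff(x$regulators, gene_to_regulator(gene)),
    genes = setdiff(x$genes, gene),
    knockout = gene
  )
}

#' @export
reduce_for_knockout.grn_model <- function(x, gene) {
  if (!gene %in% names(x$terms)) {
    abort(sprintf("gene %s is not in the model.", gene))
  }
  ko_reg <- gene_to_regulator(gene)
  keep_genes <- setdiff(names(x$terms), gene)
  regulators <- setdiff(x$regulators, ko_reg)
  terms <- lapply(x$terms[keep_genes], function(term) {
    keep <- term$regulators != ko_reg
    grn_term(term$regulators[keep], term$signs[keep],
             exponent = if (any(keep)) term$exponent else 1L)
  })
  reduced <- new_grn_model(terms, gene, regulators)
  fam <- build_family(regulators, keep_genes, knockout = gene)
  sigs <- vapply(fam$terms, term_signature, character(1))
  representable <- all(vapply(terms, function(t) term_signature(t) %in% sigs,
                              logical(1)))
  if (representable) reduced$model_index <- index_of_model(fam, reduced)
  reduced
}

#' Network structures printed as explicit equation systems
#'
#' Two reference structures used throughout the analyses, transcribed from
#' their printed equations rather than from any index convention:
#' `"model_11574"` (*eud-1* activated by N and S, *nhr-40* activated by N,
#' *sult-1* cooperatively activated by E) and `"unified"` (the structure in
#' the intersection of the three experiments' model sets: *eud-1* and
#' *nhr-40* each activated by E and N, *sult-1* activated by N and S).
#'
#' @return A named list of `grn_model` objects, each carrying the
#'   `model_index` it receives under this package's canonical encoding.
#' @export
#' @examples
#' named_models()$unified
named_models <- function() {
  fam <- build_family()
  structures <- list(
    model_11574 = list(
      `eud-1` = grn_term(c("N", "S"), c("activation", "activation")),
      `nhr-40` = grn_term("N", "activation"),
      `sult-1` = grn_term("E", "activation", exponent = 2L)
    ),
    unified = list(
      `eud-1` = grn_term(c("E", "N"), c("activation", "activation")),
      `nhr-40` = grn_term(c("E", "N"), c("activation", "activation")),
      `sult-1` = grn_term(c("N", "S"), c("activation", "activation"))
    )
  )
  lapply(structures, function(terms) {
    m <- new_grn_model(terms, NULL, grn_regulators())
    m$model_index <- index_of_model(fam, m)
    m
  })
}

# JSON serialization ---------------------------------------------------------

#' Serialize a model structure to/from JSON
#'
#' The document has the shape
#' `{"knockout": null|gene, "terms": {gene: {"factors": [[regulator, sign],
#' ...], "exponent": 1|2}}}`.
#'
#' @param model a `grn_model`.
#' @param path file path; for `model_to_json` with `path = NULL` the JSON
#'   string is returned.
#' @return `model_to_json` returns the path (or JSON string) invisibly;
#'   `model_from_json` returns a `grn_model`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "grn_model"))
  doc <- list(
    knockout = model$knockout,
    terms = lapply(model$terms, function(t) {
      list(
        factors = purrr::map2(t$regulators, t$signs, function(r, s) list(r, s)),
        exponent = t$exponent
      )
    })
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json a JSON string or file path (for `model_from_json`).
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  terms <- lapply(doc$terms, function(t) {
    regs <- vapply(t$factors, function(f) f[[1]], character(1))
    signs <- vapply(t$factors, function(f) f[[2]], character(1))
    grn_term(regs, signs, exponent = t$exponent)
  })
  regulators <- setdiff(grn_regulators(),
                        if (!is.null(doc$knockout)) gene_to_regulator(doc$knockout))
  new_grn_model(terms, doc$knockout, regulators)
}
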