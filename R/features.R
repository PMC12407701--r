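# Binarized structural features of wild-type models.

#' Names of the 21 binary structural features
#'
#' The feature schema, in fixed documented order: for each target gene
#' (*eud-1*, *nhr-40*, *sult-1*) whether its production term involves each
#' regulator protein (9 features), then per gene whether the term contains
#' any activating factor (3), any repressing factor (3), whether the gene is
#' autoregulated, i.e. its term involves its own protein (3), and whether the
#' term is cooperative (squared Hill factor) (3).
#'
#' @return Character vector of length 21.
#' @export
feature_names <- function() {
  genes <- c("eud1", "nhr40", "sult1")
  c(
    as.vector(t(outer(genes, grn_regulators(),
                      function(g, r) paste0(g, "_regulated_by_", r)))),
    paste0(genes, "_any_activation"),
    paste0(genes, "_any_repression"),
    paste0(genes, "_autoregulated"),
    paste0(genes, "_cooperative")
  )
}

term_feature_block <- function(term, own_regulator) {
  c(
    vapply(grn_regulators(), function(r) as.integer(r %in% term$regulators),
           integer(1)),
    any_activation = as.integer("activation" %in% term$signs),
    any_repression = as.integer("repression" %in% term$signs),
    autoregulated = as.integer(own_regulator %in% term$regulators),
    cooperative = as.integer(term$exponent == 2L)
  )
}

#' Binarize the structural features of a wild-type model
#'
#' @param model a wild-type (3-gene) `grn_model`.
#' @return A named integer vector of length 21 (see [feature_names()]).
#' @export
#' @examples
#' featurize(named_models()$model_11574)
featurize <- function(model) {
  stopifnot(inherits(model, "grn_model"))
  if (!is.null(model$knockout) || length(model$terms) != 3) {
    abort("featurization is defined on the wild-type (3-gene) family.")
  }
  genes <- grn_genes()
  blocks <- lapply(genes, function(g) {
    term_feature_block(model$terms[[g]], gene_to_regulator(g))
  })
  out <- c(
    unlist(lapply(blocks, function(b) b[1:3])),
    vapply(blocks, function(b) b[["any_activation"]], integer(1)),
    vapply(blocks, function(b) b[["any_repression"]], integer(1)),
    vapply(blocks, function(b) b[["autoregulated"]], integer(1)),
    vapply(blocks, function(b) b[["cooperative"]], integer(1))
  )
  setNames(as.integer(out), feature_names())
}

#' Feature matrix of an entire family
#'
#' Computes the 21 binary features for every member of the wild-type family
#' without materializing the models: each library term's feature block is
#' computed once and assembled along the mixed-radix digits. Identical to
#' applying [featurize()] member by member.
#'
#' @param family the wild-type [build_family()].
#' @return A tibble with `model_index` and the 21 feature columns.
#' @export
family_feature_matrix <- function(family = build_family()) {
  stopifnot(inherits(family, "grn_family"))
  if (!is.null(family$knockout) || length(family$genes) != 3) {
    abort("featurization is defined on the wild-type (3-gene) family.")
  }
  b <- family$base
  genes <- family$genes
  # per-gene term-level blocks: base x 7 (reg E/N/S, act, rep, auto, coop)
  blocks <- lapply(genes, function(g) {
    t(vapply(family$terms, function(term) {
      term_feature_block(term, gene_to_regulator(g))
    }, integer(7)))
  })
  idx <- seq_len(family$size) - 1
  digits <- cbind(idx %/% (b^2), (idx %/% b) %% b, idx %% b) + 1
  per_gene <- lapply(1:3, function(g) blocks[[g]][digits[, g], , drop = FALSE])
  mat <- cbind(
    per_gene[[1]][, 1:3], per_gene[[2]][, 1:3], per_gene[[3]][, 1:3],
    vapply(per_gene, function(m) m[, 4], integer(family$size)),
    vapply(per_gene, function(m) m[, 5], integer(family$size)),
    vapply(per_gene, function(m) m[, 6], integer(family$size)),
    vapply(per_gene, function(m) m[, 7], integer(family$size))
  )
  colnames(mat) <- feature_names()
  dplyr::bind_cols(tibble::tibble(model_index = idx), tibble::as_tibble(mat))
}
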