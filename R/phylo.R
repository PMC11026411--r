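#' Brownian-motion correlation matrix of a phylogeny
#'
#' Expected trait correlation between species under Brownian motion:
#' shared root-to-MRCA path length scaled by the geometric mean of the two
#' root-to-tip depths, i.e. `ape::vcv.phylo(tree, corr = TRUE)` restricted and
#' reordered to the requested species. Tip matching normalises case and
#' space/underscore differences.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param species Character vector of species to keep, in the desired order.
#' @return List of class `"bm_correlation"` with elements `rho` (the
#'   correlation matrix, unit diagonal) and `Lambda` (fixed at 1).
#' @export
bm_correlation <- function(tree, species) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_allomi("tree has no branch lengths", "allomi_validation_error")
  tips_norm <- normalize_species(tree$tip.label)
  if (anyDuplicated(tips_norm))
    stop_allomi("tree tip labels are not unique after normalisation",
                "allomi_validation_error")
  idx <- match(normalize_species(species), tips_norm)
  if (anyNA(idx)) {
    stop_allomi(paste0("species missing from the tree: ",
                       paste(species[is.na(idx)], collapse = ", ")),
                "allomi_validation_error")
  }
  V <- ape::vcv.phylo(tree, corr = TRUE)
  rho <- V[idx, idx, drop = FALSE]
  dimnames(rho) <- list(species, species)
  diag(rho) <- 1
  structure(list(rho = rho, Lambda = 1), class = "bm_correlation")
}

#' Apply Pagel's Lambda scaling to a correlation structure
#'
#' Multiplies all off-diagonal correlations by `Lambda`, leaving the unit
#' diagonal unchanged: `rho(Lambda) = Lambda * rho + (1 - Lambda) * I`.
#' `Lambda = 0` gives a star phylogeny (independence), `Lambda = 1` returns
#' the input. The matrix stays positive semi-definite for any
#' `Lambda` in `[0, 1]`.
#'
#' @param structure A [bm_correlation()] object (or bare correlation matrix).
#' @param Lambda Scalar in `[0, 1]`.
#' @return Same type as `structure`, with scaled correlations and the
#'   `Lambda` field updated.
#' @export
pagel_scale <- function(structure, Lambda) {
  if (!is.numeric(Lambda) || length(Lambda) != 1L || Lambda < 0 || Lambda > 1)
    stop_allomi("Pagel's Lambda must be a single value in [0, 1]",
                "allomi_domain_error")
  rho <- if (inherits(structure, "bm_correlation")) structure$rho else structure
  out <- Lambda * rho
  diag(out) <- 1
  if (inherits(structure, "bm_correlation"))
    structure(list(rho = out, Lambda = Lambda * structure$Lambda),
              class = "bm_correlation")
  else out
}

#' Simulate an ultrametric pure-birth tree
#'
#' Yule (pure-birth) tree with the total depth rescaled to 1, so branch
#' lengths are fractions of total evolutionary time. Reproducible: the same
#' `(n, seed)` always yields the same Newick string.
#'
#' @param n Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n))
  tree
}
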