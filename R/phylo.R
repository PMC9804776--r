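# Phylogenetic correlation structure for the species-level random effect.
# Branch lengths follow Grafen's method: the height of each internal node is
# ((number of descendant tips - 1) / (total tips - 1))^rho, tips sit at height
# 0 and the root at 1, so the tree is ultrametric by construction and shared
# path length from the root doubles as a correlation.

#' Parse a Newick tree
#'
#' Reads a rooted tree from a Newick string or file. Any branch lengths in
#' the input are ignored downstream: [grafen_lengths()] recomputes them.
#'
#' @param text Newick string (must contain a semicolon) or a file path.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @export
parse_newick <- function(text) {
  tr <- if (grepl(";", text, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = text),
             error = function(e) stop("Newick parse error: ",
                                      conditionMessage(e)))
  } else {
    if (!file.exists(text)) stop("file not found: ", text)
    ape::read.tree(text)
  }
  if (is.null(tr)) stop("Newick parse error: could not read tree")
  if (length(tr$tip.label) < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Assign Grafen branch lengths
#'
#' Sets node heights to `((descendant tips - 1)/(total tips - 1))^rho`, tips
#' at height 0 and the root at height 1, giving an ultrametric tree whether
#' or not the input carried branch lengths. Polytomies are handled by the
#' same rule.
#'
#' @param tree A rooted `"phylo"` object.
#' @param rho Power applied to the relative node heights; must be positive.
#'   The default 1 is Grafen's original proposal.
#' @return The tree with recomputed branch lengths.
#' @export
grafen_lengths <- function(tree, rho = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) {
    stop("rho must be a single positive number")
  }
  # note: a basal polytomy (incl. the star tree) is fine; the height rule
  # only needs a designated root node, which the phylo object always has
  out <- ape::compute.brlen(tree, method = "Grafen", power = rho)
  if (!ape::is.ultrametric(out, tol = 1e-9)) {
    stop("internal error: Grafen lengths did not produce an ultrametric tree")
  }
  out
}

#' Phylogenetic correlation matrix from an ultrametric tree
#'
#' For an ultrametric tree with unit root height, the correlation between
#' two species is the depth (from the root) of their most recent common
#' ancestor; the diagonal is 1. This matrix is the covariance structure of
#' the phylogenetic random effect in the meta-analytic model.
#'
#' @param tree Ultrametric `"phylo"` object (apply [grafen_lengths()] first).
#' @return Symmetric positive semi-definite matrix with unit diagonal,
#'   dimnames set to the tip labels.
#' @export
phylo_correlation <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; run grafen_lengths() first")
  }
  if (!ape::is.ultrametric(tree, tol = 1e-9)) {
    stop("tree is not ultrametric; run grafen_lengths() first")
  }
  A <- ape::vcv(tree, corr = TRUE)
  # vcv can leave ~1e-16 asymmetries; the model code expects exact symmetry
  A <- (A + t(A)) / 2
  A
}

#' Check that every species in a table is covered by a correlation matrix
#'
#' The phylogenetic variance component requires a complete correlation
#' matrix: species present in the data but absent from the tree are a hard
#' error, never silently pruned.
#'
#' @param records Effect-size table with a `species` column.
#' @param A Phylogenetic correlation matrix with species dimnames.
#' @return Invisibly, the species used.
#' @export
check_species_coverage <- function(records, A) {
  sp <- unique(as.character(records$species))
  missing_sp <- setdiff(sp, rownames(A))
  if (length(missing_sp) > 0L) {
    stop("species missing from the phylogenetic correlation matrix: ",
         paste(missing_sp, collapse = ", "))
  }
  invisible(sp)
}

#' Write a correlation matrix as TSV with species labels
#' @param A Correlation matrix.
#' @param path Output path.
#' @export
write_correlation_tsv <- function(A, path) {
  df <- data.frame(species = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
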