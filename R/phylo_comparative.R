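# Phylogenetic signal (Blomberg's K, multivariate K) and phylogenetic
# PCA over a species tree whose tips match the specimens of the
# functional space.
#
# All methods work through the Brownian-motion covariance matrix C of
# the tree: C[i, j] is the shared branch length from the root to the
# most recent common ancestor of tips i and j.

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree] that enforces the contracts the
#' comparative methods rely on: labelled, unique tips and branch
#' lengths present. Polytomies and zero-length branches are allowed.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("tree has unlabeled tips")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; compute them first ",
         "(e.g. ape::compute.brlen for Grafen-style lengths)")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  invisible(tree)
}

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the root-to-MRCA path length shared by tips `i` and
#' `j`; the diagonal holds root-to-tip depths. Symmetric positive
#' semi-definite by construction.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return A tip-by-tip numeric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

# Precomputed quantities reused across permutations: C, its inverse,
# and the Brownian expectation of the variance ratio.
signal_prep <- function(tree) {
  C <- phylo_covariance(tree)
  n <- nrow(C)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance; adjust zero/tiny branch ",
         "lengths (", conditionMessage(e), ")"))
  sum_cinv <- sum(Cinv)
  list(C = C, Cinv = Cinv, n = n,
       colsum_cinv = colSums(Cinv), sum_cinv = sum_cinv,
       expected_ratio = (sum(diag(C)) - n / sum_cinv) / (n - 1))
}

# core K statistic for a trait matrix already ordered as C's tips;
# columns are descriptors (one column = univariate K)
k_stat <- function(X, prep) {
  X <- as.matrix(X)
  a <- drop(prep$colsum_cinv %*% X) / prep$sum_cinv   # GLS (phylogenetic) mean
  D <- sweep(X, 2, a)
  num <- sum(D * D)
  den <- sum(D * (prep$Cinv %*% D))
  if (num < .Machine$double.eps)
    stop("undefined signal: trait is constant across tips")
  (num / den) / prep$expected_ratio
}

match_tips <- function(X, tree, what = "trait") {
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    missing_tips <- setdiff(tree$tip.label, rownames(X))
    extra <- setdiff(rownames(X), tree$tip.label)
    if (length(missing_tips) || length(extra))
      stop(what, " rows and tree tips do not match; missing: ",
           paste(missing_tips, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
    X <- X[tree$tip.label, , drop = FALSE]
  } else {
    if (nrow(X) != length(tree$tip.label))
      stop(what, " has ", nrow(X), " rows but the tree has ",
           length(tree$tip.label), " tips")
    rownames(X) <- tree$tip.label
  }
  if (!all(is.finite(X))) stop(what, " contains non-finite values")
  X
}

#' Blomberg's K for a single trait
#'
#' Ratio of the observed partitioning of trait variance (mean squared
#' error about the phylogenetically weighted mean over its GLS
#' counterpart under the tree covariance C) to its expectation under
#' Brownian motion. K = 1 under pure Brownian motion; K < 1 indicates
#' less, K > 1 more, resemblance among relatives than Brownian motion
#' predicts.
#'
#' @param trait Numeric vector, one value per tip, named by tip label
#'   (unnamed input is taken in tip order).
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Positive scalar K.
#' @export
blomberg_k <- function(trait, tree) {
  X <- match_tips(cbind(trait), tree)
  k_stat(X, signal_prep(tree))
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Generalisation of Blomberg's K to a multivariate trait: squared
#' deviations are replaced by squared Euclidean distances about the
#' multivariate GLS mean, with numerator and denominator summed over
#' descriptors before the ratio is taken. Reduces exactly to
#' [blomberg_k] for a single column.
#'
#' @param traits Numeric matrix, one row per tip (rownames = tip
#'   labels), >= 1 column.
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Positive scalar.
#' @export
k_mult <- function(traits, tree) {
  X <- match_tips(traits, tree)
  k_stat(X, signal_prep(tree))
}

#' Permutation test for phylogenetic signal
#'
#' Shuffles trait rows across the tips (tree fixed), recomputes the
#' statistic for each permutation, and reports the add-one permutation
#' p-value `(1 + #{K_perm >= K_obs}) / (1 + n_permutations)`, which can
#' never be exactly zero.
#'
#' @param traits Vector or matrix of tip traits (rownames/names = tip
#'   labels).
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param n_permutations Number of permutations (>= 99; default 9999).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `signal_result`: `statistic_name` (`"K"`
#'   or `"K_mult"`), `observed`, `permutation_values`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permutation_test <- function(traits, tree, n_permutations = 9999L, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the permutation test")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 99L) stop("n_permutations must be >= 99")
  X <- match_tips(cbind(traits), tree)
  prep <- signal_prep(tree)
  obs <- k_stat(X, prep)
  set.seed(seed)
  perms <- vapply(seq_len(n_permutations), function(i) {
    k_stat(X[sample.int(nrow(X)), , drop = FALSE], prep)
  }, numeric(1))
  p <- (1 + sum(perms >= obs)) / (1 + n_permutations)
  structure(list(
    statistic_name = if (ncol(X) > 1L) "K_mult" else "K",
    observed = obs, permutation_values = perms, p_value = p,
    n_permutations = n_permutations, seed = seed),
    class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(x$statistic_name, " = ", signif(x$observed, 6),
      "; p = ", signif(x$p_value, 4),
      " (", x$n_permutations, " permutations, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Phylogenetic principal component analysis
#'
#' PCA that accounts for shared ancestry: the mean is the GLS
#' (phylogenetically weighted) mean `a = (1'C^-1 1)^-1 1'C^-1 X`, the
#' decomposed matrix is the evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, and scores are the
#' GLS-centered data projected on R's eigenvectors. All tips (including
#' a grafted fossil) are scored in the single decomposition. Signs
#' follow the same convention as [functional_pca].
#'
#' @param traits Numeric matrix, rows = tips (rownames = tip labels).
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return An object of class `phylo_pca`: `phylogenetic_mean`,
#'   `evolutionary_covariance`, `pc_scores`, `pc_loadings`,
#'   `eigenvalues`, `variance_explained`.
#' @export
phylogenetic_pca <- function(traits, tree) {
  X <- match_tips(traits, tree)
  if (nrow(X) <= ncol(X))
    warning("fewer tips (", nrow(X), ") than descriptors + 1 (",
            ncol(X) + 1, "); pPCA axes will be poorly determined")
  prep <- signal_prep(tree)
  a <- drop(prep$colsum_cinv %*% X) / prep$sum_cinv
  D <- sweep(X, 2, a)
  R <- crossprod(D, prep$Cinv %*% D) / (prep$n - 1)
  e <- eigen_with_signs(R)
  scores <- D %*% e$vectors
  structure(list(
    phylogenetic_mean = a, evolutionary_covariance = R,
    pc_scores = scores, pc_loadings = e$vectors,
    eigenvalues = e$values,
    variance_explained = 100 * e$values / sum(e$values)),
    class = "phylo_pca")
}

#' @export
print.phylo_pca <- function(x, ...) {
  cat("phylo_pca: ", nrow(x$pc_scores), " tips x ",
      ncol(x$pc_scores), " descriptors\n  variance explained (%): ",
      paste(signif(x$variance_explained, 3), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Graft a fossil tip onto a tree
#'
#' Attaches a single tip (e.g. a composite fossil representation) at a
#' given node, by default the root — the stem position of a fossil
#' relative to the sampled crown clade. The default branch length is
#' the mean root-to-tip depth, so an ultrametric tree stays ultrametric.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param label Tip label for the fossil.
#' @param edge_length Branch length of the new terminal edge (default:
#'   mean root-to-tip depth).
#' @param at Node to attach to (default: the root node).
#' @return The augmented tree.
#' @export
add_fossil_tip <- function(tree, label = "CFMR", edge_length = NULL,
                           at = NULL) {
  validate_tree(tree)
  if (label %in% tree$tip.label)
    stop("tip '", label, "' already present in the tree")
  depths <- diag(phylo_covariance(tree))
  if (is.null(edge_length)) edge_length <- mean(depths)
  if (is.null(at)) at <- length(tree$tip.label) + 1L  # root node
  phytools::bind.tip(tree, label, edge.length = edge_length, where = at)
}
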