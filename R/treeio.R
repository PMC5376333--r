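# Phylogeny input, validation, pruning, and phylogenetic covariance matrices.
# Trees are ape "phylo" objects throughout; parsing and pruning delegate to
# ape, validation and the lambda transform are implemented here.

#' Parse a Newick string into a validated phylogeny
#'
#' Reads a single rooted tree in Newick format and validates it for use in
#' phylogenetic regression: tip labels must be unique and nonempty, branch
#' lengths nonnegative, and at least two tips present.  Underscores in labels
#' are preserved verbatim; internal node labels are ignored.
#'
#' @param text Newick string (one tree, terminated by `;`).
#' @param missing_lengths Policy for edges without a branch length:
#'   `"error"` (default) rejects the tree, `"zero"` assigns length 0.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @seealso [read_phylo()], [vcv_matrix()]
#' @export
parse_newick <- function(text, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found in input", call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected a single tree, found ", length(tree), call. = FALSE)
    tree <- tree[[1L]]
  }
  validate_phylo(tree, missing_lengths = missing_lengths)
}

#' Read a phylogeny from a Newick file
#'
#' @param path Path to a file containing exactly one Newick tree.
#' @inheritParams parse_newick
#' @return An object of class `"phylo"`.
#' @export
read_phylo <- function(path, missing_lengths = c("error", "zero")) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               missing_lengths = missing_lengths)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `"phylo"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phylo <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants required by the regression machinery and returns the
#' tree unchanged on success.  Zero-length terminal branches are permitted but
#' flagged with a warning because two tips at identical positions make the
#' phylogenetic covariance matrix singular.
#'
#' @param tree A `"phylo"` object.
#' @inheritParams parse_newick
#' @return The validated tree.
#' @export
validate_phylo <- function(tree, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object", call. = FALSE)
  tips <- tree$tip.label
  if (length(tips) < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  if (anyNA(tips) || any(!nzchar(trimws(tips))))
    stop("empty tip labels are not allowed", call. = FALSE)
  if (anyDuplicated(tips))
    stop("duplicate tip labels: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (missing_lengths == "zero") {
      if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
      tree$edge.length[is.na(tree$edge.length)] <- 0
    } else {
      stop("tree has edges without branch lengths ",
           "(use missing_lengths = \"zero\" to assign 0)", call. = FALSE)
    }
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  term <- tree$edge[, 2] <= length(tips)
  if (any(tree$edge.length[term] == 0))
    warning("zero-length terminal branch(es) present; ",
            "identical tip positions will make the VCV matrix singular",
            call. = FALSE)
  if (!is_ultrametric(tree))
    warning("tree is not ultrametric; the lambda = 0 model then no longer ",
            "reduces to an ordinary (equal-weight) SMA fit", call. = FALSE)
  tree
}

#' Test whether a tree is ultrametric
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @param tol Relative tolerance on root-to-tip depth differences.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  isTRUE(diff(range(d)) <= tol * max(d, tol))
}

#' Prune a phylogeny to a set of taxa
#'
#' Retains exactly the requested tips, suppressing unbranched internal nodes
#' and summing their branch lengths so that path lengths between retained
#' tips are unchanged (the usual tree "trimming" step that drops species
#' absent from the trait database).
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' prune_to_taxa(tr, c("A", "C"))
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(keep) < 2L)
    stop("at least 2 taxa must be retained, got ", length(keep), call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Phylogenetic variance--covariance matrix
#'
#' Entry (i, j) is the total branch length shared by the root-to-tip paths of
#' tips i and j under Brownian motion; the diagonal holds root-to-tip
#' distances.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames and an
#'   attribute `lambda_applied` (`NA` until [lambda_transform()] is applied).
#' @examples
#' vcv_matrix(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
vcv_matrix <- function(tree) {
  C <- ape::vcv(tree)
  attr(C, "lambda_applied") <- NA_real_
  C
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged.  `lambda = 1` keeps the full Brownian-motion covariance;
#' `lambda = 0` removes all phylogenetic correlation.
#'
#' @param C Phylogenetic covariance matrix from [vcv_matrix()].
#' @param lambda Scalar in \[0, 1\].
#' @return The transformed matrix, with attribute `lambda_applied` set.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1], got ",
         format(lambda), call. = FALSE)
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  attr(Cl, "lambda_applied") <- lambda
  Cl
}
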