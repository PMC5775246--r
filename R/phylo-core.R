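#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the input contract
#' the downstream analyses rely on: unique tip labels, branch lengths on
#' every edge, and a rooted topology. Polytomies are retained.
#'
#' @param text A Newick string (mutually exclusive with `file`).
#' @param file Path to a Newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`", call. = FALSE)
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0))
    stop("malformed Newick: unmatched ')' at position ", which(depth < 0)[1],
         call. = FALSE)
  if (length(depth) && depth[length(depth)] != 0)
    stop("malformed Newick: ", depth[length(depth)],
         " unmatched '(' by position ", length(chars), call. = FALSE)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("malformed Newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed Newick: could not parse tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length(s)", call. = FALSE)
  tree
}

#' Cophenetic (patristic) distance matrix
#'
#' Pairwise tip-to-tip path-length distances on the tree, the phylogenetic
#' distances underlying all alpha and beta structure metrics. Rows and
#' columns follow the tree's tip-label order.
#'
#' @param tree A `phylo` object with branch lengths and at least 2 tips.
#' @return A symmetric numeric matrix with zero diagonal, labelled by tip.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 2)
    stop("cophenetic distances need at least 2 tips", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

# Deterministic zero-length resolution of polytomies (order of appearance),
# so that independent contrasts are defined on any input topology.
resolve_polytomies <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  ape::multi2di(tree, random = FALSE)
}

# Felsenstein pruning over a postorder traversal. X is an n_tip x m matrix
# (tip rows in tree tip order); all m columns are processed in one pass,
# which is what makes the trait-shuffle randomization test cheap.
pic_engine <- function(tree, X) {
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- stats::reorder(tree, "postorder")
  e1 <- po$edge[, 1]
  e2 <- po$edge[, 2]
  val <- matrix(0, n + nnode, ncol(X))
  val[seq_len(n), ] <- X
  vl <- numeric(n + nnode)
  vl[e2] <- po$edge.length
  contrasts <- matrix(NA_real_, nnode, ncol(X))
  children <- split(e2, factor(e1, levels = unique(e1)))
  for (p in as.integer(names(children))) {
    ch <- children[[as.character(p)]]
    if (length(ch) != 2)
      stop("tree is not bifurcating; resolve polytomies first", call. = FALSE)
    b1 <- vl[ch[1]]; b2 <- vl[ch[2]]
    contrasts[p - n, ] <- (val[ch[1], ] - val[ch[2], ]) / sqrt(b1 + b2)
    val[p, ] <- if (b1 + b2 == 0) (val[ch[1], ] + val[ch[2], ]) / 2
                else (val[ch[1], ] * b2 + val[ch[2], ] * b1) / (b1 + b2)
    vl[p] <- vl[p] + b1 * b2 / (b1 + b2)
  }
  rownames(contrasts) <- as.character(n + seq_len(nnode))
  contrasts
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts by Felsenstein's pruning algorithm: at each
#' internal node the difference of the two daughter values divided by the
#' square root of the summed branch lengths, with the usual branch-length
#' adjustment for estimated ancestral values. Polytomies are first resolved
#' deterministically with zero-length branches.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named numeric vector; names must cover all tip labels.
#' @return A list with `contrasts` (named by internal node number of the
#'   resolved tree, in postorder) and `node_order`.
#' @export
independent_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("missing trait value for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tree <- resolve_polytomies(tree)
  x <- as.numeric(trait[tree$tip.label])
  if (any(!is.finite(x))) stop("non-finite trait values", call. = FALSE)
  cc <- pic_engine(tree, matrix(x, ncol = 1))
  ord <- rownames(cc)[order(as.integer(rownames(cc)))]
  out <- setNames(cc[, 1], rownames(cc))[ord]
  list(contrasts = out, node_order = ord)
}

# Per-tree clade summary: for every internal node, the sorted descendant
# tip set (as a key) and the node height = distance to its furthest
# descendant tip (age-like on dated trees).
clade_info <- function(tree) {
  n <- ape::Ntip(tree)
  nnode <- tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  po <- stats::reorder(tree, "postorder")
  maxtd <- c(depth[seq_len(n)], rep(-Inf, nnode))
  tipsets <- c(as.list(tree$tip.label), vector("list", nnode))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    maxtd[p] <- max(maxtd[p], maxtd[ch])
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
  }
  ids <- n + seq_len(nnode)
  keys <- vapply(tipsets[ids], function(s) paste(sort(s), collapse = "\r"), "")
  list(keys = keys, heights = maxtd[ids] - depth[ids], node_ids = ids)
}

#' Maximum clade credibility tree with mean node heights
#'
#' Scores every input tree by the product of its clades' credibilities
#' (the frequency of each clade across the whole set) and returns the
#' best-scoring tree, with each internal node height replaced by the mean
#' height of that clade over the trees containing it. Height is measured
#' as the distance from a node to its furthest descendant tip; tips are
#' placed at height zero, so non-ultrametric inputs are flattened (a
#' warning is issued). Ties in the credibility product return the first
#' tree in input order. Clade credibilities are stored as `node.label`.
#'
#' @param trees A `multiPhylo` object or list of `phylo` trees on one tip set.
#' @return A `phylo` object.
#' @export
mcc_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("empty tree set", call. = FALSE)
  tipset <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), tipset))
      stop("trees have mismatched tip sets", call. = FALSE)
  if (!all(vapply(trees, function(t) isTRUE(ape::is.ultrametric(t, tol = 1e-6)), TRUE)))
    warning("non-ultrametric input tree(s); tips are placed at height zero")
  infos <- lapply(trees, clade_info)
  counts <- table(unlist(lapply(infos, `[[`, "keys")))
  n_tree <- length(trees)
  scores <- vapply(infos, function(i) sum(log(as.numeric(counts[i$keys]) / n_tree)),
                   0)
  best <- which.max(scores)
  # mean height of each clade over the trees that contain it
  all_keys <- unlist(lapply(infos, `[[`, "keys"))
  all_h <- unlist(lapply(infos, `[[`, "heights"))
  mean_h <- tapply(all_h, all_keys, mean)
  tree <- trees[[best]]
  info <- infos[[best]]
  n <- ape::Ntip(tree)
  h <- c(rep(0, n), as.numeric(mean_h[info$keys]))
  el <- h[tree$edge[, 1]] - h[tree$edge[, 2]]
  if (any(el < 0)) {
    warning("negative branch length(s) from mean heights clamped to zero")
    el[el < 0] <- 0
  }
  tree$edge.length <- el
  tree$node.label <- as.numeric(counts[info$keys]) / n_tree
  tree
}
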