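#' Read and write Newick species trees
#'
#' Thin wrappers around [ape::read.tree()] and [ape::write.tree()] that fix
#' the conventions used throughout the package: rooted trees with branch
#' lengths in Myr, written with 15 significant digits so that a round trip
#' preserves lengths well below the 1e-9 ultrametricity tolerance.
#'
#' @param text A Newick string (`read_newick`) .
#' @param file Optional path; `read_newick` reads from it when `text` is
#'   missing, `write_newick` writes to it (and returns the string invisibly).
#' @param tree A `phylo` object.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' write_newick(tr)
#' @export
read_newick <- function(text, file = NULL) {
  tr <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("malformed Newick input", call. = FALSE)
  if (is.null(tr$edge.length))
    stop("Newick input has no branch lengths", call. = FALSE)
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 15)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

# max difference among root-to-tip depths, Myr
ultrametric_gap <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  max(d) - min(d)
}

#' Branching times of an ultrametric species tree
#'
#' Ages (Myr before present) of the internal nodes, sorted in decreasing
#' order so the first entry is the crown age. Input must be ultrametric:
#' these ages feed the reconstructed-process birth-death likelihood, which is
#' defined on a dated tree of extant species.
#'
#' @param tree Ultrametric `phylo` with at least 2 tips.
#' @param tol Absolute tolerance (Myr) on tip-depth differences; default 1e-9.
#'   Simulator output is exact to floating-point; the tolerance guards file
#'   round trips.
#' @return Numeric vector of length `Ntip - 1`, decreasing.
#' @examples
#' branching_times(read_newick("((A:1,B:1):1,C:2);"))  # 2 1
#' @export
branching_times <- function(tree, tol = 1e-9) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L)
    stop("branching times are undefined for a single-tip tree", call. = FALSE)
  if (ultrametric_gap(tree) > tol)
    stop("tree is not ultrametric within tolerance ", tol, call. = FALSE)
  sort(unname(ape::branching.times(tree)), decreasing = TRUE)
}

#' Sister species pairs (cherries) of a tree
#'
#' Two tips are sister species when they alone form a monophyletic group,
#' i.e. their common ancestor is a cherry: an internal node whose two
#' children are both tips. Each tip belongs to at most one pair.
#'
#' @param tree A `phylo` with at least 2 tips.
#' @return A 2-column character matrix of tip labels, one row per cherry
#'   (zero rows when the tree has none).
#' @export
sister_pairs <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (nt < 2L) stop("need at least 2 tips", call. = FALSE)
  e <- tree$edge
  tipward <- e[, 2] <= nt
  n_tip_children <- tabulate(e[tipward, 1], nbins = nt + tree$Nnode)
  cherries <- which(n_tip_children == 2L)
  sel <- tipward & e[, 1] %in% cherries
  if (!any(sel))
    return(matrix(character(0), 0, 2,
                  dimnames = list(NULL, c("tip1", "tip2"))))
  o <- order(e[sel, 1])
  m <- matrix(tree$tip.label[e[sel, 2][o]], ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("tip1", "tip2")))
  m
}

#' Cophenetic distance between two tips
#'
#' Sum of branch lengths on the path between tips `a` and `b`; on an
#' ultrametric tree this equals twice the age of their most recent common
#' ancestor, i.e. twice the divergence time. Sister-species "divergence
#' times" reported by this package are full cophenetic path distances, the
#' convention of [ape::cophenetic.phylo()] (not the halved node age).
#'
#' @param tree A `phylo`.
#' @param a,b Tip labels.
#' @return Path distance in Myr.
#' @examples
#' cophenetic_distance(read_newick("((A:1,B:1):1,C:2);"), "A", "C")  # 4
#' @export
cophenetic_distance <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(c(a, b) %in% tree$tip.label))
    stop("unknown tip label(s): ",
         paste(setdiff(c(a, b), tree$tip.label), collapse = ", "),
         call. = FALSE)
  ape::cophenetic.phylo(tree)[a, b]
}

#' Cophenetic distances between all sister pairs of a tree
#'
#' @param tree A `phylo` with at least 2 tips.
#' @return Data frame with columns `tip1`, `tip2`, `distance` (Myr), one row
#'   per cherry.
#' @export
sister_distances <- function(tree) {
  prs <- sister_pairs(tree)
  if (nrow(prs) == 0L)
    return(data.frame(tip1 = character(0), tip2 = character(0),
                      distance = numeric(0)))
  dm <- ape::cophenetic.phylo(tree)
  data.frame(tip1 = prs[, 1], tip2 = prs[, 2],
             distance = dm[cbind(prs[, 1], prs[, 2])])
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch–Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare species richness and sister
#' divergence times between simulation scenarios. Delegates to
#' [stats::t.test()].
#'
#' @param x,y Numeric samples, each of size >= 2; at least one must have
#'   nonzero variance.
#' @return List with `statistic` (t), `df` and `p_value`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
welch_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance; t statistic undefined",
         call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
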