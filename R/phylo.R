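#' Pairwise distances from a core alignment
#'
#' p-distance is differing core columns over total core columns (all
#' columns, monomorphic included, so distances are per-site and branch
#' lengths live on the substitutions-per-site scale); the jc model applies
#' the Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3). Pairs at or above
#' the p = 3/4 saturation point are capped at 5 substitutions/site and
#' flagged in the "saturated" attribute.
#'
#' @param core a [CoreAlignment-class].
#' @param model "p" or "jc".
#' @return symmetric numeric matrix with sample dimnames; attribute
#'   "saturated" is a logical matrix.
#' @export
distanceMatrix <- function(core, model = c("jc", "p")) {
  model <- match.arg(model)
  L <- length(core@positions)
  if (L == 0L) stop("empty core alignment; no distances")
  if (length(core@samples) < 2L) stop("need >= 2 samples")
  diffs <- .cpp_pair_diffs(unname(core@bases[core@samples]),
                           as.integer(core@snpCols))
  p <- diffs / L
  sat <- matrix(FALSE, nrow(p), ncol(p))
  if (model == "jc") {
    sat <- p >= 0.75
    p <- ifelse(sat, 5.0, -0.75 * log(1 - 4 * pmin(p, 0.749999) / 3))
  }
  dimnames(p) <- list(core@samples, core@samples)
  dimnames(sat) <- dimnames(p)
  diag(p) <- 0
  attr(p, "saturated") <- sat
  p
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion. Ties resolve
#' to the smallest (i, j) index pair in the current working order, making
#' the output deterministic; negative branch-length estimates are clamped
#' to zero with a message. Two samples give the trivial two-leaf tree.
#'
#' @param D symmetric distance matrix with sample dimnames.
#' @return an unrooted `phylo` tree (ape).
#' @export
njTree <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  if (n < 2L) stop("need >= 2 samples for a tree")
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    if (x <= 0) 0 else x          # also normalizes negative zero
  }
  if (n == 2L) {
    d <- D[1L, 2L] / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g);", labels[1L], bl(d), labels[2L], bl(d))
    return(ape::read.tree(text = txt))
  }
  frags <- labels
  d <- D
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(r - 1L)) for (j in seq(i + 1L, r)) {
      q <- (r - 2) * d[i, j] - R[i] - R[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    frag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], bl(li), frags[j], bl(lj))
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    frags <- c(frags[keep], frag)
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frags[1], bl(la), frags[2], bl(lb), frags[3], bl(lc))
  if (clamped) message("negative NJ branch estimate(s) clamped to 0")
  ape::read.tree(text = txt)
}

#' Leaf bipartitions of a tree's internal edges
#'
#' Each internal edge is represented by the side of its leaf split that
#' contains the alphabetically smallest leaf, as a sorted
#' comma-joined label string. Trivial (single-leaf) splits are excluded.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split strings.
#' @export
treeBipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))
  # accumulate tips below each node
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  splits <- character(0)
  root <- nt + 1L
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= nt) next                       # trivial split
    side <- sort(desc[[child]])
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (!(anchor %in% side)) side <- sort(setdiff(all_tips, side))
    splits <- c(splits, paste(side, collapse = ","))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Computed as the symmetric difference of the internal-edge bipartition
#' sets.
#'
#' @param a,b `phylo` trees over the same leaves.
#' @return nonnegative integer.
#' @export
rfDistance <- function(a, b) {
  sa <- treeBipartitions(a); sb <- treeBipartitions(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Bootstrap supports by core-column resampling
#'
#' Core alignment columns (full core, monomorphic included) are resampled
#' with replacement; each replicate's NJ tree contributes to the
#' percentage of replicates containing each internal-edge bipartition of
#' the point-estimate tree. Reproducible from the seed.
#'
#' @param core a [CoreAlignment-class].
#' @param nReps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param model distance model, as in [distanceMatrix()].
#' @return the point-estimate `phylo` with node labels set to integer
#'   percentage supports (root label empty).
#' @export
bootstrapSupport <- function(core, nReps = 100L, seed = 42L, model = "jc") {
  stopifnot(nReps >= 1L)
  L <- length(core@positions)
  point <- njTree(distanceMatrix(core, model))
  splits <- treeBipartitions(point)
  if (length(splits) == 0L) {
    point$node.label <- rep("", point$Nnode)
    return(point)
  }
  hits <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  bases <- unname(core@bases[core@samples])
  for (rep in seq_len(nReps)) {
    cols <- sample.int(L, L, replace = TRUE)
    diffs <- .cpp_pair_diffs(bases, as.integer(cols))
    p <- diffs / L
    D <- -0.75 * log(1 - 4 * pmin(p, 0.749999) / 3)
    if (model == "p") D <- p
    dimnames(D) <- list(core@samples, core@samples)
    diag(D) <- 0
    rs <- treeBipartitions(njTree(D))
    present <- splits %in% rs
    hits[present] <- hits[present] + 1
  }
  support <- round(100 * hits / nReps)
  # attach supports as node labels
  tree <- point
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]; c2 <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c2]])
  }
  all_tips <- sort(tree$tip.label); anchor <- all_tips[1L]
  labs <- rep("", tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    node <- nt + nd
    side <- sort(desc[[node]])
    if (length(side) <= 1L || length(side) >= nt - 1L) next
    if (!(anchor %in% side)) side <- sort(setdiff(all_tips, side))
    key <- paste(side, collapse = ",")
    if (key %in% names(support)) labs[nd] <- as.character(support[[key]])
  }
  tree$node.label <- labs
  tree
}

#' Newick output and input
#'
#' Branch lengths are rounded to 6 significant digits on output; supports
#' travel as internal node labels. Reading validates parenthesis balance
#' and rejects duplicate leaf labels.
#'
#' @param tree a `phylo`.
#' @param path file path.
#' @return invisibly the path (writer); a `phylo` (reader).
#' @export
writeNewickFile <- function(tree, path) {
  if (!is.null(tree$edge.length)) tree$edge.length <- signif(tree$edge.length, 6L)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickFile
#' @export
readNewickFile <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  if (lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE))) !=
      lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE))))
    stop("unbalanced parentheses in Newick input")
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree)) stop("failed to parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}
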