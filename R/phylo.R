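# Distance-based tree building, molecular-clock linearization with node
# calibration, and dating of an element insertion relative to a reference
# (e.g. gene-duplication) node.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`), with negative branch
#' lengths clamped to zero and the deficit transferred to the sibling
#' branch so that path lengths are approximately preserved.
#'
#' @param d A symmetric distance matrix (or a `k2p_dist` object, whose `$d`
#'   is used), at least 3 taxa.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "k2p_dist")) d <- d$d
  d <- as.matrix(d)
  if (nrow(d) < 3L) rlang::abort("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (i in neg) {
    deficit <- tr$edge.length[i]
    tr$edge.length[i] <- 0
    parent <- tr$edge[i, 1L]
    sib <- setdiff(which(tr$edge[, 1L] == parent), i)
    if (length(sib) > 0L) {
      tr$edge.length[sib[1L]] <- tr$edge.length[sib[1L]] + deficit
    }
  }
  tr
}

# Clock heights by tip-count-weighted averaging: each internal node's height
# is the mean, over its descendant tips, of the node-to-tip path length.
.clock_heights <- function(tr) {
  nt <- ape::Ntip(tr)
  nn <- tr$Nnode
  h <- numeric(nt + nn)
  num <- numeric(nt + nn)
  den <- numeric(nt + nn)
  wt <- c(rep(1, nt), rep(0, nn))
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    ch <- po$edge[k, 2L]
    if (ch > nt) {
      h[ch] <- num[ch] / den[ch]
      wt[ch] <- den[ch]
    }
    num[p] <- num[p] + wt[ch] * (h[ch] + po$edge.length[k])
    den[p] <- den[p] + wt[ch]
  }
  # The root subdivides one original edge at an arbitrary point (rooting on
  # an outgroup cannot locate it), so its height is the unweighted mean of
  # its child-side path means: invariant to where the edge was split.
  root <- nt + 1L
  root_rows <- which(po$edge[, 1L] == root)
  side_means <- vapply(root_rows, function(k) {
    ch <- po$edge[k, 2L]
    h[ch] + po$edge.length[k]
  }, numeric(1))
  h[root] <- mean(side_means)
  h
}

#' Linearize a tree under a molecular clock and calibrate node ages
#'
#' The tree is rooted on the given outgroup, node heights (substitutions
#' per site) are re-estimated by tip-count-weighted averaging of tip path
#' lengths, and ages are scaled so that the calibration node (the MRCA of
#' `calibration_tips`) has the supplied age. The substitution rate implied
#' by the calibration is `height(calibration node) / calibration_age`.
#'
#' @param tree An unrooted or rooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @param outgroup Tip label (or labels) to root on.
#' @param calibration_tips Two or more tip labels whose MRCA is the
#'   calibration node.
#' @param calibration_age Age of the calibration node in MY.
#' @return An object of class `clock_tree`: list with `tree` (rooted
#'   ultrametric `phylo`, branch lengths in MY), `ages` (per-node, MY),
#'   `heights` (per-node, substitutions/site), `rate`
#'   (substitutions/site/MY) and `calibration`.
#' @export
linearize_and_calibrate <- function(tree, outgroup, calibration_tips,
                                    calibration_age) {
  stopifnot(inherits(tree, "phylo"), calibration_age > 0)
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  nt <- ape::Ntip(tr)
  h <- .clock_heights(tr)
  # enforce monotonicity (a parent can fall below a child after averaging
  # on strongly non-clock trees); the fix keeps ages valid
  po <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1L]
    h[p] <- max(h[p], h[po$edge[k, 2L]])
  }
  cal_node <- ape::getMRCA(tr, calibration_tips)
  if (is.null(cal_node)) rlang::abort("calibration tips not found in tree")
  if (h[cal_node] <= 0) rlang::abort("degenerate calibration: zero height at calibration node")
  rate <- h[cal_node] / calibration_age
  ages <- h / rate
  tr_my <- tr
  tr_my$edge.length <- ages[tr$edge[, 1L]] - ages[tr$edge[, 2L]]
  structure(
    list(tree = tr_my, ages = ages, heights = h, rate = rate,
         calibration = list(node = cal_node, tips = calibration_tips,
                            age = calibration_age)),
    class = "clock_tree"
  )
}

.node_label <- function(clock, node) {
  nt <- ape::Ntip(clock$tree)
  if (node <= nt) clock$tree$tip.label[node] else paste0("node", node)
}

#' @export
print.clock_tree <- function(x, ...) {
  cat(sprintf(
    "<clock_tree> %d tips, rate %.4g subs/site/MY (calibration: %g MY)\n",
    ape::Ntip(x$tree), x$rate, x$calibration$age
  ))
  invisible(x)
}

#' Tidy node ages of a calibrated clock tree
#'
#' @param x A `clock_tree` object.
#' @param ... Unused.
#' @return A tibble with `node`, `label` (tip labels, `nodeN` for internal
#'   nodes), `age` (MY), `height` (substitutions/site) and `is_tip`.
#' @export
#' @exportS3Method generics::tidy
tidy.clock_tree <- function(x, ...) {
  nt <- ape::Ntip(x$tree)
  nodes <- seq_along(x$ages)
  tibble(
    node = nodes,
    label = vapply(nodes, function(n) .node_label(x, n), character(1)),
    age = x$ages,
    height = x$heights,
    is_tip = nodes <= nt
  )
}

#' @export
#' @exportS3Method generics::glance
glance.clock_tree <- function(x, ...) {
  tibble(
    n_tips = ape::Ntip(x$tree),
    rate = x$rate,
    calibration_age = x$calibration$age,
    root_age = max(x$ages)
  )
}

#' Newick export of a calibrated clock tree
#'
#' @param clock A `clock_tree` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_tree <- function(clock, path) {
  ape::write.tree(clock$tree, path)
  invisible(path)
}

#' Date an element insertion on a calibrated tree
#'
#' The element-versus-consensus divergence accrues on a single lineage, so
#' the insertion age point estimate is `d_elem / rate`; the interval is
#' `(d_elem +/- z * se_elem) / rate`, clipped at zero. The insertion is
#' placed on the branch (on the path from the host lineage to the root)
#' whose age interval contains the point estimate, and ordered against a
#' named reference node (typically the gene duplication): `younger` when
#' the whole interval lies below the reference age, `older` when it lies
#' above, otherwise `indistinguishable`.
#'
#' @param d_elem,se_elem Element-versus-consensus K2P distance and its SE.
#' @param clock A `clock_tree` from [linearize_and_calibrate()].
#' @param host_tip Tip label of the lineage carrying the element.
#' @param reference_tips Tip labels whose MRCA is the reference node, or a
#'   single numeric node id.
#' @param z Half-width of the dating interval in SE units.
#' @return An object of class `insertion_dating`; see
#'   [glance.insertion_dating()].
#' @export
date_insertion <- function(d_elem, se_elem, clock, host_tip,
                           reference_tips, z = 2) {
  stopifnot(inherits(clock, "clock_tree"), d_elem >= 0, se_elem >= 0)
  if (clock$rate <= 0) rlang::abort("calibrated rate must be positive")
  ref_node <- if (is.numeric(reference_tips)) {
    as.integer(reference_tips)
  } else if (length(reference_tips) == 1L) {
    which(clock$tree$tip.label == reference_tips)
  } else {
    ape::getMRCA(clock$tree, reference_tips)
  }
  if (length(ref_node) == 0L || is.null(ref_node)) {
    rlang::abort("reference node not found")
  }
  ref_age <- clock$ages[ref_node]
  age_point <- d_elem / clock$rate
  age_low <- max(0, (d_elem - z * se_elem) / clock$rate)
  age_high <- (d_elem + z * se_elem) / clock$rate
  # branch placement along the host lineage's root path
  tip <- which(clock$tree$tip.label == host_tip)
  if (length(tip) != 1L) rlang::abort("`host_tip` not found in tree")
  edge <- clock$tree$edge
  placement <- NA_character_
  node <- tip
  root <- ape::Ntip(clock$tree) + 1L
  while (node != root) {
    parent <- edge[edge[, 2L] == node, 1L]
    if (clock$ages[node] <= age_point && age_point <= clock$ages[parent]) {
      placement <- paste0(.node_label(clock, node), "..", .node_label(clock, parent))
      break
    }
    node <- parent
  }
  verdict <- if (age_high < ref_age) "younger"
  else if (age_low > ref_age) "older"
  else "indistinguishable"
  structure(
    list(
      d_elem = d_elem, se_elem = se_elem, z = z,
      age_point = age_point, age_low = age_low, age_high = age_high,
      branch_placement = placement,
      reference_node = ref_node, reference_age = unname(ref_age),
      verdict_vs_reference = verdict, rate = clock$rate,
      host_tip = host_tip
    ),
    class = "insertion_dating"
  )
}

#' @export
print.insertion_dating <- function(x, ...) {
  cat(sprintf(
    "<insertion_dating> %.2f MY [%.2f, %.2f] on %s; vs reference (%.2f MY): %s\n",
    x$age_point, x$age_low, x$age_high,
    x$branch_placement %||% "?", x$reference_age, x$verdict_vs_reference
  ))
  invisible(x)
}

#' One-row summary of an insertion dating
#'
#' @param x An `insertion_dating` object.
#' @param ... Unused.
#' @return A one-row tibble: distances, ages (MY), branch placement,
#'   reference age and the ordering verdict.
#' @export
#' @exportS3Method generics::glance
glance.insertion_dating <- function(x, ...) {
  tibble(
    d_elem = x$d_elem, se_elem = x$se_elem, z = x$z, rate = x$rate,
    age_point = x$age_point, age_low = x$age_low, age_high = x$age_high,
    branch_placement = x$branch_placement,
    reference_age = x$reference_age,
    verdict = x$verdict_vs_reference
  )
}
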