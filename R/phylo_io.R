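#' Read a phylogeny from Newick or NEXUS
#'
#' Reads a rooted tree with branch lengths and records its height so that
#' downstream results (half-lives, trends) can be converted back to the
#' original time units after scaling to unit height.
#'
#' @param source A file path or a character string containing the tree.
#' @param format One of \code{"auto"}, \code{"newick"}, \code{"nexus"}.
#'   \code{"auto"} picks NEXUS when the content starts with \code{#NEXUS}.
#' @return An object of class \code{c("ou_phylo", "phylo")}: an \pkg{ape}
#'   tree carrying \code{original_height} (the maximum root-to-tip distance
#'   at read time) and a logical \code{scaled} flag.
#' @export
read_tree <- function(source, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  is_path <- length(source) == 1L && !grepl("[(;]", source) && file.exists(source)
  txt <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "\n") else source
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "newick"
  }
  tr <- if (format == "nexus") {
    tf <- tempfile(fileext = ".nex")
    writeLines(txt, tf)
    on.exit(unlink(tf), add = TRUE)
    ape::read.nexus(tf)
  } else {
    tryCatch(ape::read.tree(text = txt),
             error = function(e) stop("tree parse failure: ", conditionMessage(e)))
  }
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr) || !inherits(tr, "phylo")) stop("tree parse failure")
  as_ou_phylo(tr)
}

#' Promote an ape tree to the package's validated tree class
#'
#' @param tr A \code{phylo} object with branch lengths.
#' @param original_height Height in original time units; defaults to the
#'   tree's current maximum root-to-tip distance.
#' @return An \code{ou_phylo} tree.
#' @export
as_ou_phylo <- function(tr, original_height = NULL) {
  stopifnot(inherits(tr, "phylo"))
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("branch lengths must all be present and >= 0")
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  depths <- ape::node.depth.edgelength(tr)
  if (is.null(original_height)) original_height <- max(depths[seq_len(ape::Ntip(tr))])
  tr$original_height <- original_height
  if (is.null(tr$scaled)) tr$scaled <- FALSE
  class(tr) <- unique(c("ou_phylo", class(tr)))
  tr
}

tip_depths <- function(tr) {
  ape::node.depth.edgelength(tr)[seq_len(ape::Ntip(tr))]
}

#' Test ultrametricity against a relative tolerance
#' @param tr A tree.
#' @param tol Relative tolerance on the spread of root-to-tip distances.
#' @return Logical.
#' @export
is_ultrametric_tol <- function(tr, tol = 1e-6) {
  dd <- tip_depths(tr)
  (max(dd) - min(dd)) <= tol * max(dd)
}

#' Scale an ultrametric tree to unit height
#'
#' Divides all branch lengths by the tree height. The pre-scaling height is
#' kept in \code{original_height} so half-lives in tree-height units can be
#' converted back to absolute time (e.g. myr).
#'
#' @param tr An \code{ou_phylo} (or \code{phylo}) tree, ultrametric within
#'   \code{tol}.
#' @param tol Relative ultrametricity tolerance (default \code{1e-6};
#'   published consensus trees carry rounding noise).
#' @return The scaled tree with \code{scaled = TRUE}; after scaling every
#'   root-to-tip distance is 1 within 1e-9.
#' @export
scale_to_unit_height <- function(tr, tol = 1e-6) {
  if (!inherits(tr, "ou_phylo")) tr <- as_ou_phylo(tr)
  if (!is_ultrametric_tol(tr, tol))
    stop("tree is not ultrametric within relative tolerance ", tol)
  if (isTRUE(tr$scaled)) return(tr)
  h <- max(tip_depths(tr))
  if (h <= 0) stop("tree height must be positive")
  tr$edge.length <- tr$edge.length / h
  # snap residual rounding noise so the unit-height invariant holds to 1e-9
  dd <- tip_depths(tr)
  if (max(abs(dd - 1)) > 1e-12) {
    ext <- tr$edge[, 2] <= ape::Ntip(tr)
    tr$edge.length[ext] <- tr$edge.length[ext] + (1 - dd[tr$edge[ext, 2]])
  }
  tr$scaled <- TRUE
  tr
}

#' Paint regimes on every edge from node states
#'
#' Each edge takes the state of its child node, i.e. a shift implied by
#' parent != child is placed at the parent (rootward) end of the edge. This
#' makes a maximum-a-posteriori node-state map fully determine a painting.
#'
#' @param tr A tree.
#' @param node_states Character vector of regime labels for all nodes in ape
#'   node order (tips \code{1..Ntip}, then internals), or named by tip label
#'   for the tip part.
#' @param states Optional declared regime set; defaults to the sorted unique
#'   labels observed.
#' @return A \code{regime_painting}: per-edge named numeric vectors of
#'   segment lengths (names are regimes, ordered parent to child).
#' @export
paint_from_node_states <- function(tr, node_states, states = NULL) {
  nn <- ape::Ntip(tr) + tr$Nnode
  if (length(node_states) != nn)
    stop("need one state per node (", nn, "), got ", length(node_states))
  node_states <- as.character(node_states)
  if (anyNA(node_states)) stop("missing node state")
  if (is.null(states)) states <- sort(unique(node_states))
  if (!all(node_states %in% states))
    stop("unknown regime label: ",
         paste(setdiff(unique(node_states), states), collapse = ", "))
  maps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    seg <- tr$edge.length[e]
    names(seg) <- node_states[tr$edge[e, 2]]
    seg
  })
  new_regime_painting(maps, states, node_states = node_states, tree = tr)
}

new_regime_painting <- function(maps, states, node_states = NULL, tree = NULL) {
  p <- list(maps = maps, states = states, node_states = node_states)
  if (!is.null(tree)) {
    p$edge <- tree$edge
    p$edge.length <- tree$edge.length
    p$tip.label <- tree$tip.label
  }
  class(p) <- "regime_painting"
  p
}

#' Validate a painting against a tree
#' @param p A \code{regime_painting}.
#' @param tr The tree it paints.
#' @param tol Absolute tolerance on segment sums.
#' @return Invisibly \code{TRUE}; errors otherwise.
#' @export
validate_painting <- function(p, tr, tol = 1e-8) {
  stopifnot(inherits(p, "regime_painting"))
  if (length(p$maps) != nrow(tr$edge)) stop("painting does not cover all edges")
  sums <- vapply(p$maps, sum, 0)
  if (any(abs(sums - tr$edge.length) > tol + 1e-9 * pmax(1, tr$edge.length)))
    stop("segment lengths on some edge do not sum to the edge length")
  labs <- unique(unlist(lapply(p$maps, names)))
  if (!all(labs %in% p$states))
    stop("regime labels outside the declared set: ",
         paste(setdiff(labs, p$states), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("regime painting:", length(x$maps), "edges,",
      length(x$states), "regimes (", paste(x$states, collapse = ", "), ")\n")
  invisible(x)
}

edge_path_to_tip <- function(tr, tip_idx) {
  # edge row indices on the root-to-tip path, in root-to-tip order
  parent <- integer(ape::Ntip(tr) + tr$Nnode)
  parent[tr$edge[, 2]] <- seq_len(nrow(tr$edge))  # incoming edge per node
  root <- ape::Ntip(tr) + 1L
  path <- integer(0)
  v <- tip_idx
  while (v != root) {
    e <- parent[v]
    path <- c(e, path)
    v <- tr$edge[e, 1]
  }
  path
}

#' Extract the regime history of one lineage
#'
#' Walks from the root to a tip through the painting and returns contiguous
#' epochs (regime, start, end) measured in time from the root.
#'
#' @param tr A tree.
#' @param p A \code{regime_painting} covering all edges.
#' @param tip A tip label.
#' @return A \code{lineage_history}: data frame with columns \code{regime},
#'   \code{start}, \code{end}, plus attributes \code{tip} and \code{T}.
#' @export
lineage_epochs <- function(tr, p, tip) {
  i <- match(tip, tr$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip)
  path <- edge_path_to_tip(tr, i)
  regs <- character(0); lens <- numeric(0)
  for (e in path) {
    regs <- c(regs, names(p$maps[[e]]))
    lens <- c(lens, unname(p$maps[[e]]))
  }
  # merge consecutive identical regimes
  keep <- c(TRUE, regs[-1] != regs[-length(regs)])
  grp <- cumsum(keep)
  lens <- as.numeric(tapply(lens, grp, sum))
  regs <- regs[keep]
  ends <- cumsum(lens)
  h <- data.frame(regime = regs, start = c(0, ends[-length(ends)]), end = ends,
                  stringsAsFactors = FALSE)
  attr(h, "tip") <- tip
  attr(h, "T") <- ends[length(ends)]
  class(h) <- c("lineage_history", "data.frame")
  h
}

#' All lineage histories of a painted tree
#' @inheritParams lineage_epochs
#' @return Named list of \code{lineage_history}, one per tip.
#' @export
all_lineage_histories <- function(tr, p) {
  out <- lapply(tr$tip.label, function(tp) lineage_epochs(tr, p, tp))
  names(out) <- tr$tip.label
  out
}

#' Shared-time and distance matrices of a tree
#'
#' @param tr A tree (normally scaled to unit height).
#' @return List with \code{s} (time from root to the MRCA of each pair),
#'   \code{d} (patristic distance, \code{d = T_i + T_j - 2 s_ij}) and
#'   \code{depths} (root-to-tip distances), all in tip-label order.
#' @export
phylo_matrices <- function(tr) {
  s <- ape::vcv(tr)
  depths <- diag(s)
  d <- outer(depths, depths, "+") - 2 * s
  list(s = s, d = d, depths = depths)
}

#' Write a painting as a SIMMAP-style annotated Newick string
#'
#' Branches are annotated as \code{:\{state,len:state,len\}} with segments
#' listed rootward first, the convention used by common simmap readers.
#'
#' @param tr The painted tree.
#' @param p A \code{regime_painting}.
#' @param file Optional path; when given the string is written there.
#' @return The annotated Newick string, invisibly when \code{file} is set.
#' @export
write_simmap <- function(tr, p, file = NULL) {
  validate_painting(p, tr)
  ntip <- ape::Ntip(tr)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  lab <- function(v) if (v <= ntip) tr$tip.label[v] else ""
  ann <- function(e) {
    m <- p$maps[[e]]
    paste0("{", paste(sprintf("%s,%.10g", names(m), unname(m)), collapse = ":"), "}")
  }
  rec <- function(v) {
    es <- kids[[as.character(v)]]
    if (is.null(es)) return(lab(v))
    inner <- vapply(es, function(e)
      paste0(rec(tr$edge[e, 2]), ":", ann(e)), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  out <- paste0(rec(ntip + 1L), ";")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Export a single-state-per-edge painting as an edge table
#' @param p A \code{regime_painting}.
#' @return Data frame with columns \code{parent}, \code{child},
#'   \code{regime}, \code{length}; multi-segment edges yield one row per
#'   segment.
#' @export
painting_edge_table <- function(p) {
  rows <- lapply(seq_along(p$maps), function(e) {
    m <- p$maps[[e]]
    data.frame(parent = p$edge[e, 1], child = p$edge[e, 2],
               regime = names(m), length = unname(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Current (tipward) regime of every tip under a painting
#' @param tr A tree.
#' @param p A \code{regime_painting}.
#' @return Named character vector over tips.
#' @export
tip_regimes <- function(tr, p) {
  ntip <- ape::Ntip(tr)
  out <- character(ntip)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) {
      m <- p$maps[[e]]
      out[ch] <- names(m)[length(m)]
    }
  }
  names(out) <- tr$tip.label
  out
}

#' Cross two regime paintings into a combined factor
#'
#' Produces the painting of the interaction factor (levels
#' \code{"a:b"}), refining segments wherever the two component paintings
#' change state at different points along an edge. Only level combinations
#' realized somewhere on the tree appear in the combined state set, so
#' unrealized combinations are never allocated coefficients.
#'
#' @param tr The tree both paintings live on.
#' @param p1,p2 \code{regime_painting} objects.
#' @param sep Separator for combined labels.
#' @return A \code{regime_painting} of the crossed factor.
#' @export
cross_paintings <- function(tr, p1, p2, sep = ":") {
  validate_painting(p1, tr); validate_painting(p2, tr)
  maps <- lapply(seq_len(nrow(tr$edge)), function(e) {
    m1 <- p1$maps[[e]]; m2 <- p2$maps[[e]]
    b1 <- cumsum(unname(m1)); b2 <- cumsum(unname(m2))
    len <- tr$edge.length[e]
    cuts <- sort(unique(c(0, pmin(b1, len), pmin(b2, len), len)))
    cuts <- cuts[!duplicated(signif(cuts, 12))]
    seg_len <- diff(cuts)
    mid <- (cuts[-1] + cuts[-length(cuts)]) / 2
    st1 <- names(m1)[pmin(findInterval(mid, c(0, b1), left.open = TRUE), length(m1))]
    st2 <- names(m2)[pmin(findInterval(mid, c(0, b2), left.open = TRUE), length(m2))]
    out <- seg_len
    names(out) <- paste(st1, st2, sep = sep)
    keep <- out > 0 | length(out) == 1L
    out <- out[keep]
    # merge consecutive equal states
    if (length(out) > 1L) {
      g <- cumsum(c(TRUE, names(out)[-1] != names(out)[-length(out)]))
      merged <- tapply(unname(out), g, sum)
      nm <- names(out)[!duplicated(g)]
      out <- as.numeric(merged); names(out) <- nm
    }
    out
  })
  states <- sort(unique(unlist(lapply(maps, names))))
  node_states <- if (!is.null(p1$node_states) && !is.null(p2$node_states))
    paste(p1$node_states, p2$node_states, sep = sep) else NULL
  new_regime_painting(maps, states, node_states = node_states, tree = tr)
}
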