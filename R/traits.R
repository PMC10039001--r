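#' Discrete character matrix
#'
#' Taxa-by-characters matrix of single-symbol states (`0`-`9`), with `?` for
#' missing/uncertain, plus an optional map giving, per character, the derived
#' ("Neanderthal condition") state.
#'
#' @param states character matrix with taxa as rownames and characters as
#'   colnames.
#' @param derived_state_map optional named character vector
#'   (character -> derived symbol).
#' @return object of class `character_matrix`.
#' @export
character_matrix <- function(states, derived_state_map = NULL) {
  states <- as.matrix(states)
  mode(states) <- "character"
  if (is.null(rownames(states))) stop("states needs taxa as rownames")
  if (is.null(colnames(states)))
    colnames(states) <- paste0("char", seq_len(ncol(states)))
  ok <- states %in% c(as.character(0:9), "?")
  if (!all(ok)) stop("invalid state symbol(s): ",
                     paste(unique(states[!ok]), collapse = ", "))
  if (!is.null(derived_state_map)) {
    bad <- setdiff(names(derived_state_map), colnames(states))
    if (length(bad)) stop("derived_state_map names not in characters: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(states = states, taxa = rownames(states),
                 characters = colnames(states),
                 derived_state_map = derived_state_map),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix> %d taxa x %d characters (%d '?')\n",
              nrow(x$states), ncol(x$states), sum(x$states == "?")))
  invisible(x)
}

#' Majority-rule consensus of several individuals' state vectors
#'
#' Per character, the most frequent non-`?` state; ties and all-missing
#' characters give `?` (conservative coding).
#'
#' @param rows character matrix (individuals x characters) or list of equal
#'   length state vectors.
#' @return character vector of consensus states.
#' @export
majority_state <- function(rows) {
  if (is.list(rows)) rows <- do.call(rbind, rows)
  rows <- as.matrix(rows)
  if (!nrow(rows)) stop("no rows given")
  apply(rows, 2L, function(col) {
    col <- col[col != "?"]
    if (!length(col)) return("?")
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "?" else names(tab)[1]
  })
}

#' Combine two individuals' scores into one taxon row
#'
#' Agreement keeps the state; a `?` defers to the other individual;
#' disagreement gives `?`.
#'
#' @param row_a,row_b equal-length character vectors of states.
#' @return combined character vector.
#' @export
combine_pair <- function(row_a, row_b) {
  stopifnot(length(row_a) == length(row_b))
  out <- ifelse(row_a == row_b, row_a,
                ifelse(row_a == "?", row_b,
                       ifelse(row_b == "?", row_a, "?")))
  stats::setNames(out, names(row_a))
}

#' Count derived-condition characters in a row
#'
#' How many characters show the derived (e.g. Neanderthal) state, out of the
#' full character count (uncertain entries stay in the denominator).
#'
#' @param row character vector of states, one per character.
#' @param derived_state_map named character vector (character -> derived
#'   symbol); names must cover the row.
#' @return list with `k` (derived count), `n` (characters), and `label`
#'   ("k/n").
#' @export
count_derived <- function(row, derived_state_map) {
  n <- length(row)
  if (length(derived_state_map) != n)
    derived_state_map <- derived_state_map[names(row)]
  k <- sum(row == derived_state_map, na.rm = TRUE)
  list(k = k, n = n, label = sprintf("%d/%d", k, n))
}

#' Pairwise character distances
#'
#' Proportion of mismatching characters over the characters scored (non-`?`)
#' in both taxa; 0 with a warning when two taxa share no scored characters.
#'
#' @param matrix a [character_matrix].
#' @return symmetric distance matrix with zero diagonal.
#' @export
character_distance <- function(matrix) {
  st <- matrix$states
  n <- nrow(st)
  if (n < 2L) stop("need at least 2 taxa")
  D <- base::matrix(0, n, n, dimnames = list(rownames(st), rownames(st)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- st[i, ] != "?" & st[j, ] != "?"
    if (!any(comp)) {
      warning("taxa ", rownames(st)[i], " and ", rownames(st)[j],
              " share no scored characters; distance set to 0")
      d <- 0
    } else d <- mean(st[i, comp] != st[j, comp])
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with the Studier-Keppler criterion.
#' Negative branch lengths are clamped to zero with the deficit moved to the
#' sister branch; ties in the joining criterion break on the lexicographically
#' smallest label pair, so the result is deterministic.
#'
#' @param distances symmetric numeric matrix with zero diagonal and taxon
#'   labels as dimnames; n >= 3.
#' @return an unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(distances) {
  D <- as.matrix(distances)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- stats::setNames(labels, labels)   # newick fragment per active node
  key <- stats::setNames(labels, labels)    # lexicographic tie-break key
  active <- labels
  dimnames(D) <- list(labels, labels)
  clamp_pair <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[active[ij[1]]], key[active[ij[2]]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pk)[1L], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    bi <- Dm[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- Dm[i, j] - bi
    b <- clamp_pair(bi, bj)
    new_lab <- paste0("(", i, ",", j, ")")
    frag[new_lab] <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], b[1], frag[j], b[2])
    key[new_lab] <- min(key[i], key[j])
    rest <- setdiff(active, c(i, j))
    newd <- (D[i, rest] + D[j, rest] - D[i, j]) / 2
    D <- rbind(cbind(D, 0), 0)
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_lab
    D[new_lab, rest] <- D[rest, new_lab] <- newd
    active <- c(rest, new_lab)
  }
  a <- active
  d12 <- D[a[1], a[2]]; d13 <- D[a[1], a[3]]; d23 <- D[a[2], a[3]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  bl <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[a[1]], bl[1], frag[a[2]], bl[2], frag[a[3]], bl[3])
  ape::read.tree(text = nwk)
}

# --- Fitch small parsimony -------------------------------------------------

# Encode states as bitmasks; '?' is full ambiguity over the symbols observed
# for that character.
state_masks <- function(states) {
  n <- nrow(states); C <- ncol(states)
  masks <- base::matrix(0L, n, C, dimnames = dimnames(states))
  for (c3 in seq_len(C)) {
    syms <- sort(unique(states[, c3][states[, c3] != "?"]))
    if (!length(syms)) syms <- "0"
    full <- bitwShiftL(1L, length(syms)) - 1L
    m <- match(states[, c3], syms)
    masks[, c3] <- ifelse(is.na(m), full, bitwShiftL(1L, m - 1L))
  }
  masks
}

# Fitch count on an edge list (2 columns of integer node ids; tips are
# 1..n_tip). The tree is rooted on the edge incident to tip 1; every internal
# node then has exactly two children. Returns the per-character change count.
fitch_counts_edges <- function(edges, masks) {
  ntip <- nrow(masks)
  nodes <- unique(as.integer(edges))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  counts <- integer(ncol(masks))
  eval_node <- function(v, parent) {
    if (v <= ntip) return(masks[v, ])
    kids <- setdiff(adj[[as.character(v)]], parent)
    set <- eval_node(kids[1L], v)
    for (k in kids[-1L]) {
      other <- eval_node(k, v)
      inter <- bitwAnd(set, other)
      zero <- inter == 0L
      counts[zero] <<- counts[zero] + 1L
      set <- ifelse(zero, bitwOr(set, other), inter)
    }
    set
  }
  v0 <- adj[["1"]][1L]                      # tip 1's internal neighbour
  set_v <- eval_node(v0, 1L)
  zero <- bitwAnd(set_v, masks[1L, ]) == 0L
  counts[zero] <- counts[zero] + 1L
  counts
}

phylo_to_edges <- function(tree, taxa) {
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) stop("tree tip labels do not match the matrix taxa")
  e <- tree$edge
  ntip <- length(tree$tip.label)
  remap <- function(v) ifelse(v <= ntip, idx[v], v)
  cbind(remap(e[, 1]), remap(e[, 2]))
}

#' Fitch parsimony length of a tree on a character matrix
#'
#' Sum over characters of the minimum number of state changes (Fitch
#' small-parsimony counts); `?` is treated as full ambiguity.
#'
#' @param tree an unrooted binary `ape::phylo` over the matrix taxa (a
#'   rooted tree is unrooted first).
#' @param matrix a [character_matrix].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, matrix) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  if (!setequal(tree$tip.label, matrix$taxa))
    stop("tree tips and matrix taxa differ")
  masks <- state_masks(matrix$states)
  sum(fitch_counts_edges(phylo_to_edges(tree, matrix$taxa), masks))
}

# Enumerate all unrooted binary topologies over n taxa by stepwise edge
# insertion (3 x 5 x ... x (2n-5) trees). Callback receives an edge list with
# tips 1..n and internal ids > n.
enumerate_topologies <- function(n, callback) {
  stopifnot(n >= 3L)
  edges0 <- cbind(n + 1L, 1:3)
  recurse <- function(edges, k, next_internal) {
    if (k > n) { callback(edges); return(invisible()) }
    for (e in seq_len(nrow(edges))) {
      m <- next_internal
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(edges[e, 1], m), c(m, edges[e, 2]), c(m, k))
      recurse(new_edges, k + 1L, next_internal + 1L)
    }
  }
  recurse(edges0, 4L, n + 2L)
}

edges_to_newick <- function(edges, labels) {
  ntip <- length(labels)
  nodes <- unique(as.integer(edges))
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  build <- function(v, parent) {
    if (v <= ntip) return(labels[v])
    kids <- setdiff(adj[[as.character(v)]], parent)
    paste0("(", paste(vapply(kids, build, character(1), parent = v),
                      collapse = ","), ")")
  }
  root <- edges[1L, 1L]
  if (root <= ntip) root <- edges[1L, 2L]
  paste0(build(root, NA_integer_), ";")
}

#' Exhaustive maximum-parsimony search with strict consensus
#'
#' Enumerates every unrooted binary topology (3 x 5 x ... x (2n-5) trees),
#' scores each with Fitch parsimony, and returns all most-parsimonious trees
#' together with their strict consensus (edges absent from any MP tree are
#' collapsed).
#'
#' @param matrix a [character_matrix].
#' @param max_taxa guard on the exhaustive enumeration (default 10).
#' @return list with `score` (minimal length), `trees` (list of
#'   `ape::phylo`), `n_topologies` (number examined) and `strict_consensus`
#'   (an `ape::phylo`, possibly with polytomies).
#' @export
exhaustive_mp <- function(matrix, max_taxa = 10L) {
  n <- length(matrix$taxa)
  if (n > max_taxa)
    stop("exhaustive search limited to ", max_taxa,
         " taxa; heuristic search is out of scope")
  if (n < 4L) stop("need at least 4 taxa for a non-trivial topology")
  masks <- state_masks(matrix$states)
  best <- Inf; best_edges <- list(); n_topo <- 0L
  enumerate_topologies(n, function(edges) {
    n_topo <<- n_topo + 1L
    s <- sum(fitch_counts_edges(edges, masks))
    if (s < best) { best <<- s; best_edges <<- list(edges) }
    else if (s == best) best_edges[[length(best_edges) + 1L]] <<- edges
  })
  trees <- lapply(best_edges, function(e)
    ape::read.tree(text = edges_to_newick(e, matrix$taxa)))
  list(score = as.integer(best), trees = trees, n_topologies = n_topo,
       strict_consensus = strict_consensus(trees))
}

# Splits of an unrooted tree as canonical strings: for each internal edge,
# the sorted tip set on the side not containing the anchor (first taxon).
tree_splits <- function(tree, taxa) {
  anchor <- taxa[1L]
  ntip <- length(tree$tip.label)
  e <- tree$edge
  out <- character(0)
  for (i in seq_len(nrow(e))) {
    child <- e[i, 2L]
    if (child <= ntip) next
    tips <- tree$tip.label[unlist(phangorn_free_descendants(tree, child))]
    side <- if (anchor %in% tips) setdiff(taxa, tips) else tips
    if (length(side) >= 2L && length(side) <= length(taxa) - 2L)
      out <- c(out, paste(sort(side), collapse = "\r"))
  }
  unique(out)
}

# Tip indices below a node (simple recursion; trees here are small).
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k)
    if (k <= ntip) k else phangorn_free_descendants(tree, k)))
}

#' Strict consensus of a set of trees
#'
#' Keeps exactly the splits present in every input tree; all other edges are
#' collapsed into polytomies.
#'
#' @param trees list of `ape::phylo` over identical tip sets.
#' @return an `ape::phylo` (unrooted, possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1L]]$tip.label)
  splits <- Reduce(intersect, lapply(trees, tree_splits, taxa = taxa))
  clusters <- lapply(splits, function(s) strsplit(s, "\r", fixed = TRUE)[[1L]])
  # build a rooted cluster hierarchy (root = all taxa), then print newick
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  node <- function(tips) list(tips = tips, children = list())
  root <- node(taxa)
  insert <- function(tree_node, cl) {
    for (ci in seq_along(tree_node$children)) {
      ch <- tree_node$children[[ci]]
      if (all(cl %in% ch$tips)) {
        tree_node$children[[ci]] <- insert(ch, cl)
        return(tree_node)
      }
    }
    inside <- vapply(tree_node$children, function(ch) all(ch$tips %in% cl),
                     logical(1))
    new_node <- node(cl)
    new_node$children <- tree_node$children[inside]
    tree_node$children <- c(tree_node$children[!inside], list(new_node))
    tree_node
  }
  for (cl in clusters) root <- insert(root, cl)
  to_newick <- function(nd) {
    covered <- unlist(lapply(nd$children, function(ch) ch$tips))
    loose <- setdiff(nd$tips, covered)
    parts <- c(vapply(nd$children, to_newick, character(1)), loose)
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::unroot(ape::read.tree(text = paste0(to_newick(root), ";")))
}

#' Read a character matrix from a NEXUS file
#'
#' Minimal unordered/equal-weight dialect with `MISSING='?'`.
#'
#' @param path NEXUS file path.
#' @param derived_state_map optional derived-state map (see
#'   [character_matrix()]).
#' @return a [character_matrix].
#' @export
read_nexus_matrix <- function(path, derived_state_map = NULL) {
  dat <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(dat, function(x) toupper(x)))
  character_matrix(m, derived_state_map = derived_state_map)
}

#' Write a character matrix to NEXUS
#'
#' @param matrix a [character_matrix].
#' @param path output path.
#' @export
write_nexus_matrix <- function(matrix, path) {
  st <- matrix$states
  pad <- max(nchar(rownames(st))) + 2L
  rows <- sprintf(paste0("  %-", pad, "s%s"), rownames(st),
                  apply(st, 1L, paste, collapse = ""))
  writeLines(c("#NEXUS", "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(st), ncol(st)),
               "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"0123456789\";",
               "  MATRIX", rows, "  ;", "END;"), path)
  invisible(path)
}

#' Write a tree to Newick
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
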