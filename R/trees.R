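#' Parse a rooted Newick string
#'
#' Reads a single rooted, bifurcating Newick expression in which every branch
#' (terminal and internal) carries a length. Branch lengths are interpreted in
#' coalescent units (multiples of 2N generations) throughout the package.
#'
#' @param text A length-one character vector holding one Newick expression,
#'   terminated by a semicolon. Tip labels are restricted to
#'   `[A-Za-z0-9_.-]`.
#' @return An object of class `"phylo"` (see \pkg{ape}).
#' @examples
#' phy <- parse_newick("((A:1,B:1):4,C:5);")
#' root_to_tip_depths(phy)
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("'text' must be a single Newick string", call. = FALSE)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("Newick string must end with ';'", call. = FALSE)
  if (!grepl("(", text, fixed = TRUE)) {
    # single-tip dialect "A:1;"
    m <- regmatches(text, regexec("^([A-Za-z0-9_.-]+):([0-9eE.+-]+);$", text))[[1L]]
    len <- if (length(m) == 3L) suppressWarnings(as.numeric(m[3L])) else NA_real_
    if (is.na(len))
      stop("malformed Newick string: ", text, call. = FALSE)
    phy <- structure(
      list(edge = matrix(c(2L, 1L), 1L, 2L), edge.length = len,
           Nnode = 1L, tip.label = m[2L]),
      class = "phylo", order = "cladewise")
    return(validate_phylo(phy))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("malformed Newick string: ", text, call. = FALSE)
  validate_phylo(phy)
}

## Enforce the package's tree contract: rooted, bifurcating, unique labels,
## every branch with a non-negative length.
validate_phylo <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  nt <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (!all(grepl("^[A-Za-z0-9_.-]+$", phy$tip.label)))
    stop("tip labels must match [A-Za-z0-9_.-]+", call. = FALSE)
  if (is.null(phy$edge.length) ||
      length(phy$edge.length) != nrow(phy$edge) ||
      anyNA(phy$edge.length))
    stop("every branch must carry a length", call. = FALSE)
  if (any(phy$edge.length < 0))
    stop("branch lengths must be non-negative", call. = FALSE)
  if (nt >= 2L) {
    if (!ape::is.rooted(phy))
      stop("tree must be rooted", call. = FALSE)
    if (!ape::is.binary(phy))
      stop("tree must be bifurcating", call. = FALSE)
  }
  phy
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(phy))` reproduces
#' the topology and branch lengths.
#'
#' @param phy A `"phylo"` object.
#' @return A Newick string terminated by a semicolon.
#' @export
write_newick <- function(phy) {
  phy <- validate_phylo(phy)
  if (length(phy$tip.label) == 1L)
    return(paste0(phy$tip.label, ":",
                  format(phy$edge.length, digits = 15, scientific = FALSE), ";"))
  ape::write.tree(phy, digits = 15)
}

#' Root-to-tip path lengths
#'
#' @param phy A `"phylo"` object.
#' @return Named numeric vector: for each tip, the sum of branch lengths on
#'   the path from the root to that tip.
#' @examples
#' root_to_tip_depths(parse_newick("((A:1,B:1):4,C:5);"))  # all 5
#' @export
root_to_tip_depths <- function(phy) {
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  d <- ape::node.depth.edgelength(phy)[seq_len(nt)]
  names(d) <- phy$tip.label
  d
}

#' Is a tree ultrametric?
#'
#' All root-to-tip depths equal to within `tol`.
#' @param phy A `"phylo"` object.
#' @param tol Absolute tolerance.
#' @export
is_ultrametric <- function(phy, tol = 1e-9) {
  d <- root_to_tip_depths(phy)
  max(d) - min(d) <= tol
}

#' Clades of a rooted tree
#'
#' The descendant tip-label set of every internal, non-root node -- one set
#' per internal branch of the tree.
#'
#' @param phy A `"phylo"` object.
#' @return A list of sorted character vectors (empty for trees with fewer
#'   than three tips).
#' @export
clades <- function(phy) {
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  if (nt < 3L) return(list())
  pp <- ape::prop.part(phy)
  ## prop.part lists internal nodes in order nt+1 (root) .. nt+Nnode
  lapply(pp[-1L], function(idx) sort(phy$tip.label[idx]))
}

## locale-independent string ordering for canonical keys
sort_c <- function(x) sort(x, method = "radix")

#' Canonical topology key
#'
#' A label-sorted Newick string without branch lengths. Two rooted trees get
#' the same key if and only if they share a rooted topology; the key does not
#' depend on the order in which children or tips are stored.
#'
#' @param phy A `"phylo"` object.
#' @return A character scalar, e.g. `"((A,B),C)"`.
#' @export
topology_key <- function(phy) {
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  if (nt == 1L) return(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  key <- character(nt + phy$Nnode)
  key[seq_len(nt)] <- phy$tip.label
  parents <- unique(po$edge[, 1L])  # postorder: children complete first
  for (nd in parents) {
    kids <- po$edge[po$edge[, 1L] == nd, 2L]
    key[nd] <- paste0("(", paste(sort_c(key[kids]), collapse = ","), ")")
  }
  key[nt + 1L]
}

#' Fitch parsimony score for a binary character
#'
#' Minimum number of character-state changes needed to explain a binary tip
#' pattern on a rooted tree (any root state allowed).
#'
#' @param phy A `"phylo"` object.
#' @param states Named vector (names = tip labels) of states in `{0, 1}`.
#' @return Integer: the parsimony score.
#' @examples
#' phy <- parse_newick("((((A:1,B:1):4,C:5):4,D:9):4,E:13);")
#' fitch_score(phy, c(A = 1, B = 1, C = 0, D = 0, E = 0))  # 1
#' @export
fitch_score <- function(phy, states) {
  phy <- validate_phylo(phy)
  nt <- length(phy$tip.label)
  if (is.null(names(states)))
    stop("'states' must be named by tip label", call. = FALSE)
  s <- states[phy$tip.label]
  if (anyNA(s) || !all(s %in% c(0, 1)))
    stop("every tip needs a state in {0, 1}", call. = FALSE)
  ## state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  set <- integer(nt + phy$Nnode)
  set[seq_len(nt)] <- ifelse(s == 0, 1L, 2L)
  po <- ape::reorder.phylo(phy, "postorder")
  score <- 0L
  for (nd in unique(po$edge[, 1L])) {
    kids <- po$edge[po$edge[, 1L] == nd, 2L]
    inter <- bitwAnd(set[kids[1L]], set[kids[2L]])
    if (inter > 0L) {
      set[nd] <- inter
    } else {
      set[nd] <- bitwOr(set[kids[1L]], set[kids[2L]])
      score <- score + 1L
    }
  }
  score
}
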