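#' Threshold specification from pooled liabilities
#'
#' The cutoff is one sample standard deviation (denominator n - 1) above the
#' mean of the pooled liability values -- pooled over all species and all
#' replicates of one simulation condition, so conditions with more
#' incomplete lineage sorting (larger liability variances) get higher
#' cutoffs.
#'
#' @param liabilities A `"trait_dataset"` or numeric vector/matrix of
#'   liability values (at least two values).
#' @return An object of class `"threshold_spec"`: `mean`, `sd`, `cutoff`.
#' @examples
#' compute_threshold(c(0, 0, 0, 0, 10))  # cutoff = 2 + sqrt(20)
#' @export
compute_threshold <- function(liabilities) {
  x <- if (inherits(liabilities, "trait_dataset")) liabilities$values
       else liabilities
  x <- as.numeric(x)
  if (length(x) < 2L || anyNA(x))
    stop("need at least two liability values", call. = FALSE)
  m <- mean(x); s <- stats::sd(x)
  structure(list(mean = m, sd = s, cutoff = m + s), class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat("Threshold: mean", format(x$mean, digits = 5), "+ 1 sd",
      format(x$sd, digits = 5), "=> cutoff", format(x$cutoff, digits = 5), "\n")
  invisible(x)
}

#' Classify a binary tip pattern against the species tree
#'
#' A pattern is *uninformative* when fewer than two tips carry '1' or fewer
#' than two carry '0'. Otherwise it is *congruent* when the set of '1' tips
#' is exactly the descendant set of an internal species-tree branch (a single
#' 0 to 1 gain with ancestral state '0'), and *incongruent* otherwise --
#' produced by homoplasy or by hemiplasy on a discordant gene tree.
#'
#' @param tree A `"species_tree"`, `"phylo"`, or Newick string.
#' @param pattern Binary vector (0/1), in the tree's tip order, or a string
#'   such as `"11000"`.
#' @param allow_root_state_one If `TRUE`, patterns whose '0'-set is a clade
#'   (a single loss with ancestral state '1') also count as congruent.
#'   Off by default: the ancestral state is fixed at '0'.
#' @return `"congruent"`, `"incongruent"`, or `"uninformative"`.
#' @examples
#' classify_pattern(tree_5taxon(), "11000")  # congruent
#' classify_pattern(tree_5taxon(), "11010")  # incongruent
#' @export
classify_pattern <- function(tree, pattern, allow_root_state_one = FALSE) {
  st <- as_species_tree(tree)
  tips <- st$phy$tip.label
  if (is.character(pattern) && length(pattern) == 1L)
    pattern <- as.integer(strsplit(pattern, "")[[1L]])
  if (length(pattern) != length(tips))
    stop("pattern length must equal the number of tips", call. = FALSE)
  if (!all(pattern %in% c(0, 1)))
    stop("pattern must be binary", call. = FALSE)
  n1 <- sum(pattern == 1)
  if (n1 < 2L || (length(tips) - n1) < 2L) return("uninformative")
  cl <- clades(st$phy)
  ones <- sort(tips[pattern == 1])
  if (any(vapply(cl, identical, logical(1L), y = ones))) return("congruent")
  if (allow_root_state_one) {
    zeros <- sort(tips[pattern == 0])
    if (any(vapply(cl, identical, logical(1L), y = zeros)))
      return("congruent")
  }
  "incongruent"
}

#' Discretize a liability dataset into threshold-trait patterns
#'
#' Codes each liability value as '1' if strictly above the cutoff and '0'
#' otherwise (values exactly at the cutoff are coded '0'), producing one
#' binary trait pattern per replicate, and classifies every observed pattern
#' against the species tree.
#'
#' @param dataset A `"trait_dataset"` (or replicate x species matrix) of
#'   liabilities.
#' @param spec A `"threshold_spec"`, normally computed from the same
#'   condition's pooled liabilities.
#' @param tree The `"species_tree"` used for pattern classification.
#' @param allow_root_state_one Passed to [classify_pattern()].
#' @return An object of class `"pattern_table"`: `patterns` (per-replicate
#'   strings), and `table` (data frame of pattern, count, n_derived, class).
#' @export
discretize <- function(dataset, spec, tree, allow_root_state_one = FALSE) {
  stopifnot(inherits(spec, "threshold_spec"))
  st <- as_species_tree(tree)
  values <- if (inherits(dataset, "trait_dataset")) dataset$values else dataset
  values <- values[, st$phy$tip.label, drop = FALSE]
  B <- (values > spec$cutoff) + 0L
  patterns <- apply(B, 1L, paste, collapse = "")
  tab <- table(patterns)
  cls <- vapply(names(tab), function(p)
    classify_pattern(st, p, allow_root_state_one), character(1L))
  structure(list(
    patterns = patterns,
    table = data.frame(pattern = names(tab),
                       count = as.integer(tab),
                       n_derived = vapply(strsplit(names(tab), ""),
                                          function(s) sum(s == "1"), 0L),
                       class = unname(cls),
                       row.names = NULL, stringsAsFactors = FALSE),
    cutoff = spec$cutoff),
    class = "pattern_table")
}

#' @export
print.pattern_table <- function(x, ...) {
  cat("Threshold trait patterns (cutoff ", format(x$cutoff, digits = 5),
      "), ", length(x$patterns), " replicates:\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Frequency of incongruent trait patterns
#'
#' Incongruent / (congruent + incongruent), by default restricted to
#' informative patterns in which exactly two species carry the derived state
#' '1' (and the rest '0'). Returns `NA` when no qualifying pattern occurs.
#'
#' @param table A `"pattern_table"` from [discretize()].
#' @param two_one_only Restrict to patterns with exactly two '1's.
#' @return A fraction in `[0, 1]`, or `NA`.
#' @export
incongruence_frequency <- function(table, two_one_only = TRUE) {
  stopifnot(inherits(table, "pattern_table"))
  tab <- table$table
  keep <- tab$class %in% c("congruent", "incongruent")
  if (two_one_only) keep <- keep & tab$n_derived == 2L
  tab <- tab[keep, , drop = FALSE]
  denom <- sum(tab$count)
  if (denom == 0L) return(NA_real_)
  sum(tab$count[tab$class == "incongruent"]) / denom
}
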