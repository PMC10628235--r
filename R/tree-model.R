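# Time-calibrated tree handling: reading ensembles, validation, pruning, and
# the lambda-scaled phylogenetic covariance matrix.

#' Read an ordered ensemble of Newick trees
#'
#' Reads one or more Newick strings from a plain-text file (one
#' semicolon-terminated tree per record; records may share a line or span
#' several). Trees are returned in file order, and iteration index `i` always
#' refers to the same tree, so results can be matched back to a published
#' tree set.
#'
#' @param path Path to a Newick file.
#' @param expected_count Optional integer; if supplied and the file does not
#'   contain exactly this many trees, an error is raised.
#' @param source_label Free-text label stored with the ensemble; defaults to
#'   the file path.
#' @return A `tree_ensemble`: a `multiPhylo` list of validated [ape::read.tree()]
#'   trees with a `source_label` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' ens <- read_newick_ensemble(tf)
#' length(ens)
read_newick_ensemble <- function(path, expected_count = NULL,
                                 source_label = path) {
  if (!file.exists(path)) {
    abort(sprintf("Tree file not found: %s", path))
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  chunks <- strsplit(text, ";", fixed = TRUE)[[1]]
  chunks <- chunks[nzchar(trimws(chunks))]
  if (length(chunks) == 0) {
    abort(sprintf("No Newick records found in %s.", path))
  }
  trees <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    tr <- tryCatch(
      ape::read.tree(text = paste0(trimws(chunks[[i]]), ";")),
      error = function(e) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo")) {
      abort(sprintf("Malformed Newick record at tree index %d in %s.", i, path))
    }
    validate_time_tree(tr, context = sprintf("tree index %d", i))
    trees[[i]] <- tr
  }
  if (!is.null(expected_count) && length(trees) != expected_count) {
    abort(sprintf("Expected %d trees but read %d from %s.",
                  expected_count, length(trees), path))
  }
  structure(trees,
            class = c("tree_ensemble", "multiPhylo"),
            source_label = source_label)
}

#' Validate a time-calibrated tree
#'
#' Checks the invariants the comparative machinery relies on: unique,
#' non-empty tip labels; branch lengths present and non-negative. Zero-length
#' terminal branches and departures from ultrametricity are tolerated but
#' flagged with warnings (they can make the phylogenetic covariance singular
#' at high lambda; the fitting step errors rather than jittering silently).
#'
#' @param tree An [ape::phylo] tree.
#' @param context Optional string naming the tree in error messages.
#' @return The tree, invisibly.
#' @export
validate_time_tree <- function(tree, context = "tree") {
  if (!inherits(tree, "phylo")) {
    abort(sprintf("%s is not a 'phylo' object.", context))
  }
  labs <- tree$tip.label
  if (any(!nzchar(trimws(labs)))) {
    abort(sprintf("%s has empty tip labels.", context))
  }
  dup <- unique(labs[duplicated(normalize_taxon(labs))])
  if (length(dup) > 0) {
    abort(sprintf("%s has duplicate tip labels: %s.",
                  context, paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    abort(sprintf("%s has no branch lengths; a time-calibrated tree is required.",
                  context))
  }
  if (any(tree$edge.length < 0)) {
    abort(sprintf("%s has negative branch lengths.", context))
  }
  term <- tree$edge[, 2] <= ape::Ntip(tree)
  if (any(tree$edge.length[term] == 0)) {
    warn(sprintf("%s has zero-length terminal branches; the phylogenetic covariance may be singular at lambda = 1.",
                 context))
  }
  depths <- node_depths(tree)
  if (diff(range(depths)) > 1e-6 * max(depths, 1e-12)) {
    warn(sprintf("%s is not ultrametric (tip depth spread %.3g); the lambda transform is conventionally applied to ultrametric trees.",
                 context, diff(range(depths))))
  }
  invisible(tree)
}

# Root-to-tip path depths, named by tip label. A root edge (the retained
# basal stem of a pruned tree) counts towards every depth.
node_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d + (tree$root.edge %||% 0)
}

#' Prune a tree to a set of taxa
#'
#' Drops all tips not in `keep`, suppressing the degree-2 internal nodes this
#' creates (their flanking branch lengths are summed), so every retained tip
#' keeps its original root-to-tip depth. Matching uses
#' [normalize_taxon()] (underscore/space equivalence).
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned [ape::phylo] tree.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' prune_to_taxa(tr, c("A", "C"))
prune_to_taxa <- function(tree, keep) {
  keep_norm <- normalize_taxon(keep)
  if (length(keep_norm) < 2) {
    abort("`keep` must contain at least 2 taxa.")
  }
  tip_norm <- normalize_taxon(tree$tip.label)
  idx <- match(keep_norm, tip_norm)
  if (anyNA(idx)) {
    abort(sprintf("Taxa not present in the tree: %s.",
                  paste(keep[is.na(idx)], collapse = ", ")))
  }
  old_depths <- node_depths(tree)
  pruned <- ape::keep.tip(tree, tree$tip.label[idx])
  # keep.tip re-roots at the subset's most recent common ancestor; keep the
  # dropped basal path as a root edge so root-to-tip depths (and the shared
  # history of pairs coalescing at the new root) are preserved.
  lost <- old_depths[pruned$tip.label[1]] -
    (ape::node.depth.edgelength(pruned)[1] + (pruned$root.edge %||% 0))
  if (lost > 1e-12) {
    pruned$root.edge <- (pruned$root.edge %||% 0) + unname(lost)
  }
  pruned
}

#' Lambda-scaled phylogenetic covariance matrix
#'
#' Builds the expected trait covariance among tips under Brownian motion on a
#' time-calibrated tree, with phylogenetic signal attenuated by Pagel's
#' lambda: the diagonal holds each tip's root-to-tip depth (in squared-trait
#' units per Myr of the Brownian rate) and is unchanged by lambda, while each
#' off-diagonal entry is lambda times the shared root-to-common-ancestor path
#' depth of the two tips. `lambda = 1` is pure Brownian covariance;
#' `lambda = 0` removes all phylogenetic correlation.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param lambda Signal parameter in \[0, 1\].
#' @return A symmetric numeric matrix with tip labels as dimnames and a
#'   `"lambda"` attribute.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_vcv(tr, lambda = 1)
phylo_vcv <- function(tree, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].")
  }
  validate_quietly(tree)
  V <- ape::vcv.phylo(tree)
  # A root edge is history shared by every tip: it adds to all path depths
  # and all pairwise shared depths alike.
  V <- V + (tree$root.edge %||% 0)
  off <- row(V) != col(V)
  V[off] <- lambda * V[off]
  attr(V, "lambda") <- lambda
  V
}

# Validation without repeating the ultrametricity/zero-edge warnings each
# time the covariance is rebuilt during a lambda search.
validate_quietly <- function(tree) {
  suppressWarnings(validate_time_tree(tree))
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("Tree ensemble of %d tree(s) [source: %s]\n",
              length(x), attr(x, "source_label") %||% "unknown"))
  ntips <- vapply(x, ape::Ntip, integer(1))
  cat(sprintf("  tips per tree: %d-%d\n", min(ntips), max(ntips)))
  invisible(x)
}
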