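# Synthetic trees and trait data with the statistical structure the
# comparative analyses assume: ultrametric pure-birth trees and
# log10-scale allometries with phylogenetically correlated noise under a
# lambda-distorted Brownian covariance.

#' Simulate an ultrametric pure-birth tree
#'
#' Generates a pure-birth (Yule) topology and rescales it so every
#' root-to-tip path equals `tree_depth` exactly (terminal branches are
#' adjusted to absorb rounding), giving a strictly ultrametric
#' time-calibrated tree. Reproducible from `seed`.
#'
#' @param n_tips Number of tips (at least 3).
#' @param tree_depth Root-to-tip depth in Myr-like time units.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An [ape::phylo] tree with tips `t1 ... tn`.
#' @export
#' @examples
#' tr <- simulate_tree(10, tree_depth = 100, seed = 1)
#' range(ape::node.depth.edgelength(tr)[1:10])
simulate_tree <- function(n_tips, tree_depth = 1, seed = NULL) {
  if (n_tips < 3) abort("`n_tips` must be at least 3.")
  check_positive(tree_depth, "tree_depth")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depths <- node_depths(tree)
  tree$edge.length <- tree$edge.length * (tree_depth / max(depths))
  # Force exact ultrametricity: absorb numerical drift into terminal edges.
  depths <- node_depths(tree)
  term <- match(seq_len(n_tips), tree$edge[, 2])
  adj <- tree$edge.length[term] + (tree_depth - unname(depths))
  if (any(adj < 0)) adj[adj < 0] <- 0
  tree$edge.length[term] <- adj
  tree
}

#' Simulate allometric trait data on a tree
#'
#' Draws a predictor (an evenly spaced grid spanning `predictor_range`
#' assigned to tips in order, or a Brownian trait evolved on the tree) and a
#' response `intercept + slope * predictor + e`, where `e` is multivariate
#' normal with covariance `sigma2 * phylo_vcv(tree, lambda)`. Defaults mirror
#' a log10-scale dinosaur allometry: predictor spanning roughly 1 kg to 16 t
#' of log10 body mass, a shallow positive slope, and Brownian-rate noise
#' accumulating to about +/- 0.15 log10 units over the tree depth. The noise
#' is generated by eigendecomposition ([MASS::mvrnorm()]), a different code
#' path from the Cholesky whitening used by the fitting functions.
#'
#' @param tree An [ape::phylo] tree (at least 3 tips).
#' @param intercept,slope Allometry coefficients on the log10 scale.
#' @param sigma2 Brownian rate of the residual process (squared trait units
#'   per unit tree depth).
#' @param lambda True phylogenetic signal of the noise, in \[0, 1\].
#' @param predictor_model `"fixed_grid"` or `"brownian"`.
#' @param predictor_range Range of the fixed grid (log10 body mass in kg by
#'   default).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `taxon`, `predictor`, `response`.
#' @export
#' @examples
#' tr <- simulate_tree(20, seed = 1)
#' simulate_traits(tr, slope = 0.2, seed = 2)
simulate_traits <- function(tree, intercept = -1, slope = 0.2, sigma2 = 0.02,
                            lambda = 1,
                            predictor_model = c("fixed_grid", "brownian"),
                            predictor_range = c(0, 4.2), seed = NULL) {
  predictor_model <- match.arg(predictor_model)
  n <- ape::Ntip(tree)
  if (n < 3) abort("The tree must have at least 3 tips.")
  if (sigma2 < 0) abort("`sigma2` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)

  x <- if (predictor_model == "fixed_grid") {
    seq(predictor_range[1], predictor_range[2], length.out = n)
  } else {
    as.numeric(MASS::mvrnorm(1, mu = rep(0, n), Sigma = phylo_vcv(tree, 1)))
  }

  e <- if (sigma2 == 0) {
    rep(0, n)
  } else {
    V <- sigma2 * phylo_vcv(tree, lambda)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      abort("Residual covariance is singular; check the tree's branch lengths.")
    }
    as.numeric(MASS::mvrnorm(1, mu = rep(0, n), Sigma = V))
  }

  tibble::tibble(
    taxon = tree$tip.label,
    predictor = x,
    response = intercept + slope * x + e
  )
}

#' Write a self-consistent synthetic fixture set
#'
#' Produces the small, plain-text input files the rest of the package reads:
#'
#' * `endocranial.csv` — the packaged ornithischian endocranial records
#'   (body-mass / endocast-volume intervals with 50% and 60% fills);
#' * `labyrinth.csv` — synthetic labyrinth measurements for a handful of
#'   taxa (plus the study animal's cochlear duct length), in the layout
#'   [read_labyrinth_csv()] expects;
#' * `regression.csv` — a 25-taxon synthetic log10 allometry simulated on
#'   the first ensemble tree (slope 0.2, lambda 1);
#' * `trees.nwk` — a 10-tree ultrametric ensemble over the same 25 taxa;
#' * `manifest.yml` — seeds and per-file descriptions.
#'
#' Two runs with the same seed produce byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed; per-file sub-seeds are derived from it
#'   deterministically and recorded in the manifest.
#' @return Invisibly, a named list of written paths.
#' @export
make_fixture_tables <- function(dir, seed = 1) {
  if (!dir.exists(dir)) {
    ok <- tryCatch({dir.create(dir, recursive = TRUE); TRUE},
                   warning = function(w) FALSE)
    if (!ok || !dir.exists(dir)) {
      abort(sprintf("Cannot create fixture directory %s.", dir))
    }
  }
  paths <- list(
    endocranial = file.path(dir, "endocranial.csv"),
    labyrinth = file.path(dir, "labyrinth.csv"),
    regression = file.path(dir, "regression.csv"),
    trees = file.path(dir, "trees.nwk"),
    manifest = file.path(dir, "manifest.yml")
  )

  readr::write_csv(ornithischian_endocranial_data(), paths$endocranial)

  tree_seeds <- vapply(1:10, function(i) derive_seed(seed, i), integer(1))
  trees <- lapply(tree_seeds, function(s) {
    simulate_tree(25, tree_depth = 100, seed = s)
  })
  writeLines(vapply(trees, ape::write.tree, character(1)), paths$trees)

  traits <- simulate_traits(trees[[1]], intercept = -1, slope = 0.2,
                            sigma2 = 0.0004, lambda = 1,
                            seed = derive_seed(seed, 11))
  readr::write_csv(traits, paths$regression)

  lab_seed <- derive_seed(seed, 12)
  set.seed(lab_seed)
  lab_n <- 8
  skull <- round(exp(runif(lab_n, log(150), log(900))), 1)
  labyrinth <- tibble::tibble(
    taxon = c("Thescelosaurus neglectus", paste0("synthtaxon_", 1:(lab_n - 1))),
    cochlear_duct_length_mm = c(9.95, round(runif(lab_n - 1, 5, 25), 2)),
    basicranial_length_mm = c(NA_real_, round(skull[-1] / 6, 1)),
    asc_height_mm = round(runif(lab_n, 5, 20), 2),
    asc_width_mm = round(runif(lab_n, 4, 18), 2),
    psc_height_mm = round(runif(lab_n, 4, 16), 2),
    psc_width_mm = round(runif(lab_n, 3, 14), 2),
    skull_length_mm = skull,
    lsc_horizontal = TRUE
  )
  readr::write_csv(labyrinth, paths$labyrinth)

  manifest <- list(
    master_seed = as.integer(seed),
    files = list(
      endocranial.csv = "packaged ornithischian endocranial records (intervals, fills, density)",
      labyrinth.csv = "synthetic labyrinth measurements; only the first taxon's cochlear duct length is a published measurement",
      regression.csv = "synthetic 25-taxon log10 allometry, slope 0.2, lambda 1, simulated on tree 1",
      trees.nwk = "10 ultrametric pure-birth trees, 25 tips, depth 100"
    ),
    sub_seeds = list(trees = as.integer(tree_seeds),
                     regression = derive_seed(seed, 11),
                     labyrinth = lab_seed)
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}
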