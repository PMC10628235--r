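# Shared fixtures built in code.

# Three-taxon worked tree: tips A and B share 1 Myr of path, C is separate.
three_taxon_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# Its Brownian covariance at lambda = 1, computed by hand from path depths.
three_taxon_vcv <- function() {
  m <- matrix(c(2, 1, 0,
                1, 2, 0,
                0, 0, 2), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m
}

star_tree <- function(n = 5, depth = 1) {
  txt <- paste0("(", paste0("s", seq_len(n), ":", depth, collapse = ","), ");")
  ape::read.tree(text = txt)
}

write_tree_file <- function(texts) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(texts, tf)
  tf
}
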