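# shared builders for the test suite; all fixtures are constructed in code

barley_catalog_path <- function() {
  system.file("extdata", "barley_pub_catalog.tsv", package = "pubclassr")
}

# protein_record from a compact hit spec: list(U_BOX = c(100, 170), ...)
mk_record <- function(id, length_aa, hits = list()) {
  dom <- if (length(hits)) {
    data.frame(label = rep(names(hits), vapply(hits, function(h) 1L, 1L)),
               start_aa = vapply(hits, `[`, 0, 1),
               end_aa = vapply(hits, `[`, 0, 2),
               stringsAsFactors = FALSE)
  } else NULL
  protein_record(id, length_aa,
                 domains = if (is.null(dom)) data.frame(label = character(),
                                                        start_aa = integer(),
                                                        end_aa = integer())
                           else dom)
}

# alignment with one block of >= `n_diag` columns separating {A,B} from {C,D}
# and only trivial (single-taxon) variation elsewhere
diagnostic_alignment <- function(n_diag = 25, n_const = 20) {
  row <- function(clade_char, private_at, private_char, total) {
    s <- c(rep(clade_char, n_diag), rep("G", n_const))
    s[private_at] <- private_char
    s
  }
  total <- n_diag + n_const
  aa_alignment(list(
    A = row("A", n_diag + 1, "K", total),
    B = row("A", n_diag + 2, "L", total),
    C = row("W", n_diag + 3, "R", total),
    D = row("W", n_diag + 4, "T", total)))
}

# random tree with strictly positive branch lengths; its cophenetic matrix is
# additive by construction
random_additive_dm <- function(n_taxa, seed) {
  tr <- with_seed_local(seed, {
    tr <- ape::rtree(n_taxa, br = NULL)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1.5)
    tr
  })
  tr <- ape::unroot(tr)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# unrooted topology equality via Robinson-Foulds distance
same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
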