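# run expr under a fixed RNG state without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pairwise p-distances from an amino-acid alignment
#'
#' The p-distance between two aligned sequences is the proportion of
#' mismatching residues over the columns compared. Under
#' `"pairwise_deletion"` a column is compared for a pair when both residues
#' are standard (neither gap `-` nor unknown `X`); under
#' `"complete_deletion"` only columns with standard residues in every taxon
#' are used, for all pairs. p-distances lie in \[0, 1\] and need not satisfy
#' the triangle inequality.
#'
#' @param aln An [aa_alignment()].
#' @param gap_mode `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @param model `"pdistance"` (default) or `"poisson"` for the
#'   Poisson-corrected distance `-log(1 - p)`.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pairwise_pdistance <- function(aln,
                               gap_mode = c("pairwise_deletion",
                                            "complete_deletion"),
                               model = c("pdistance", "poisson")) {
  gap_mode <- match.arg(gap_mode)
  model <- match.arg(model)
  m <- toupper(unclass(aln))
  ok <- m != "-" & m != "X"
  if (gap_mode == "complete_deletion") {
    keep <- apply(ok, 2, all)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  labels <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        stop("no comparable columns for pair ", labels[i], " / ", labels[j])
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p = 1 for pair ",
                         labels[i], " / ", labels[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (is.null(rownames(dm))) stop("distance matrix needs taxon labels")
  invisible(dm)
}

fmt_bl <- function(x) sprintf("%.12g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step join the pair (i, j) minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch lengths
#' from the rate-corrected split formula
#' `l_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`. A negative branch length is
#' clamped to zero with the deficit transferred to its sister edge (their sum
#' is preserved). Ties in Q are broken by the lowest (row, column) position in
#' input label order. The result is the unrooted NJ tree with its single
#' trifurcating root; on additive distances the tree's path-length matrix
#' reproduces the input.
#'
#' @param dm Symmetric distance matrix with labelled rows (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  validate_distance_matrix(dm)
  n0 <- nrow(dm)
  if (n0 < 3) stop("neighbor joining needs at least 3 taxa")
  d <- dm
  frag <- rownames(dm)  # newick fragment per active node
  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- paste0("(", frag[i], ":", fmt_bl(li), ",",
                      frag[j], ":", fmt_bl(lj), ")")
    others <- setdiff(seq_len(n), c(i, j))
    du <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- rbind(cbind(d[others, others, drop = FALSE], du),
               c(du, 0))
    frag <- c(frag[others], newfrag)
    dimnames(d) <- list(NULL, NULL)
  }
  # resolve the final three nodes around the trifurcating root
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", frag[1], ":", fmt_bl(max(la, 0)), ",",
                frag[2], ":", fmt_bl(max(lb, 0)), ",",
                frag[3], ":", fmt_bl(max(lc, 0)), ");")
  ape::read.tree(text = txt)
}

# Canonical keys for the non-trivial leaf bipartitions of an unrooted tree.
# Each internal edge is keyed by the tip set on the side not containing the
# reference taxon (the alphabetically first tip of `taxa`).
tree_bipartitions <- function(tree, taxa = sort(tree$tip.label)) {
  ref <- taxa[1]
  n <- ape::Ntip(tree)
  keys <- character()
  nodes <- integer()
  for (node in (n + 1):(n + tree$Nnode)) {
    tips <- tree$tip.label[tips_below(tree, node)]
    if (length(tips) < 2 || length(tips) > length(taxa) - 2) next
    side <- if (ref %in% tips) setdiff(taxa, tips) else tips
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, node)
  }
  list(keys = keys, nodes = nodes)
}

tips_below <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  out <- integer()
  todo <- node
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, kids[kids <= n])
    todo <- c(todo, kids[kids > n])
  }
  out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times (seeded), rebuilds the NJ tree for each
#' replicate, and annotates every internal edge of the full-data tree with the
#' percentage of replicates containing the same leaf bipartition. A replicate
#' in which some pair has no comparable columns is skipped with a warning and
#' the denominator uses the completed replicates. Support is attached as
#' integer internal node labels (0-100), the presentation used for bootstrap
#' values on a reference NJ topology.
#'
#' @param aln An [aa_alignment()].
#' @param n_replicates Number of bootstrap replicates (default 1000, the
#'   conventional setting for NJ gene-family trees).
#' @param seed Integer seed; the same seed reproduces identical support.
#' @param gap_mode Passed to [pairwise_pdistance()].
#' @param model Passed to [pairwise_pdistance()].
#' @return An [ape::phylo] tree; internal `node.label` holds support (empty
#'   at the root trifurcation).
#' @export
bootstrap_support <- function(aln, n_replicates = 1000, seed = 1,
                              gap_mode = c("pairwise_deletion",
                                           "complete_deletion"),
                              model = c("pdistance", "poisson")) {
  gap_mode <- match.arg(gap_mode)
  model <- match.arg(model)
  stopifnot(n_replicates >= 1)
  full <- neighbor_joining(pairwise_pdistance(aln, gap_mode, model))
  taxa <- sort(rownames(aln))
  bp <- tree_bipartitions(full, taxa)
  counts <- stats::setNames(rep(0L, length(bp$keys)), bp$keys)
  ncol_aln <- ncol(aln)
  completed <- 0L
  with_local_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      res <- aa_alignment(unclass(aln)[, cols, drop = FALSE])
      tr <- tryCatch(neighbor_joining(pairwise_pdistance(res, gap_mode, model)),
                     error = function(e) NULL)
      if (is.null(tr)) {
        warning("bootstrap replicate ", rep, " skipped: ",
                "no comparable columns for some pair", call. = FALSE)
        next
      }
      completed <- completed + 1L
      keys <- tree_bipartitions(tr, taxa)$keys
      hit <- bp$keys %in% keys
      counts[hit] <- counts[hit] + 1L
    }
  })
  if (completed == 0L) stop("all bootstrap replicates failed")
  support <- round(100 * counts / completed)
  labels <- rep("", full$Nnode)
  labels[bp$nodes - ape::Ntip(full)] <- as.character(as.integer(support))
  full$node.label <- labels
  attr(full, "n_replicates_completed") <- completed
  full
}
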