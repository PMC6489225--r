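#' Barley PUB class composition
#'
#' The per-(class, subclass) gene counts of the barley U-box family used as
#' the built-in `"barley-table1"` preset of [generate_architectures()]:
#' I: 1, II-a: 19, II-b: 8, III: 1, IV: 11 (6 PKc-only and 5 STK-N-only),
#' V: 21, VI: 3, VII: 2, X: 1 — 67 genes in total.
#'
#' @return Named integer vector keyed by class/subclass.
#' @export
barley_composition <- function() {
  c(I = 1L, IIa = 19L, IIb = 8L, III = 1L, IV_2 = 6L, IV_3 = 5L,
    V = 21L, VI = 3L, VII = 2L, X = 1L)
}

synth_class_keys <- function() {
  c("I", "IIa", "IIb", "III", "IV", "IV_1", "IV_2", "IV_3",
    "V", "VI", "VII", "VIII", "IX", "X")
}

#' Generate synthetic protein domain architectures
#'
#' For every requested (class, subclass) emits a protein whose domain set
#' satisfies exactly that class's rule and no higher-precedence rule, so that
#' [classify_proteome()] recovers the requested composition exactly for any
#' seed (the generator round-trip property). Lengths are drawn uniformly in
#' 350-1100 aa; the U-box hit is ~70 aa wide. Class II-a proteins place the
#' U-box midpoint in (0.35L, 0.6L) with at least two ARM hits C-terminal of
#' it; II-b place it in the N-terminal fifth; Class V proteins carry a
#' degenerate ARM-like hit with probability 0.5, exercising the rule that
#' ARM-like evidence does not promote a protein to Class II.
#'
#' @param composition Named integer vector of counts keyed by class or
#'   subclass (`I`, `IIa`, `IIb`, `III`, `IV`/`IV_1`/`IV_2`/`IV_3`, `V`-`X`),
#'   or the preset string `"barley-table1"` for [barley_composition()].
#'   A bare `IV` generates subgroup `IV_1` (both kinase domains). A subclass
#'   key for a class without subclasses is a usage error.
#' @param seed Integer seed.
#' @param ids Optional character vector of protein ids (length = total
#'   count), assigned in composition order; defaults to `"<key>_<i>"`.
#' @param species Species tag stored on each record.
#' @return Named list of [protein_record()] objects.
#' @examples
#' recs <- generate_architectures("barley-table1", seed = 1)
#' classify_proteome(recs)$class_counts
#' @export
generate_architectures <- function(composition, seed, ids = NULL,
                                   species = "synthetic") {
  if (identical(composition, "barley-table1")) composition <- barley_composition()
  if (is.null(names(composition)) || !all(nzchar(names(composition)))) {
    stop("composition must be a named count vector")
  }
  bad <- setdiff(names(composition), synth_class_keys())
  if (length(bad)) {
    stop("unknown class/subclass key(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(synth_class_keys(), collapse = ", "), ")")
  }
  composition <- composition[composition > 0]
  total <- sum(composition)
  if (total < 1) stop("composition requests no proteins")
  if (!is.null(ids) && length(ids) != total) {
    stop("ids must have length ", total)
  }
  with_local_seed(seed, {
    records <- list()
    k <- 0L
    for (key in names(composition)) {
      for (i in seq_len(composition[[key]])) {
        k <- k + 1L
        id <- if (is.null(ids)) sprintf("%s_%02d", key, i) else ids[k]
        records[[id]] <- synth_architecture(key, id, species)
      }
    }
    records
  })
}

# one architecture satisfying exactly the rule for `key`
synth_architecture <- function(key, id, species) {
  L <- sample(350:1100, 1)
  hit <- function(label, start, end) {
    data.frame(label = label, start_aa = as.integer(round(start)),
               end_aa = as.integer(round(end)), stringsAsFactors = FALSE)
  }
  ubox_at <- function(mid) hit("U_BOX", mid - 35, mid + 34)
  arm_run <- function(from, to, n) {
    # n non-overlapping ~40-aa ARM repeats evenly spread in [from, to]
    at <- seq(from, to - 40, length.out = n)
    do.call(rbind, lapply(at, function(s) hit("ARM", s, s + 39)))
  }
  dom <- switch(key,
    I = rbind(hit("UFD2", 40, min(400, L - 160)), ubox_at(L - 45)),
    IIa = {
      mid <- round(stats::runif(1, 0.37 * L, 0.58 * L))
      rbind(ubox_at(mid), arm_run(mid + 50, L - 5, sample(2:4, 1)))
    },
    IIb = {
      mid <- round(stats::runif(1, 36, 0.19 * L))
      rbind(ubox_at(mid), arm_run(mid + 50, L - 5, sample(2:4, 1)))
    },
    III = rbind(ubox_at(65), hit("CYCLOPHILIN", 0.45 * L, 0.45 * L + 160)),
    IV = ,
    IV_1 = rbind(ubox_at(65), hit("STK_N", 120, 170),
                 hit("PKC", L - 250, L - 50)),
    IV_2 = rbind(ubox_at(65), hit("PKC", L - 250, L - 50)),
    IV_3 = rbind(ubox_at(65), hit("STK_N", L - 250, L - 50)),
    V = {
      d <- ubox_at(round(0.3 * L))
      if (stats::runif(1) < 0.5) {
        d <- rbind(d, hit("ARM_LIKE", 0.6 * L, 0.6 * L + 120))
      }
      d
    },
    VI = rbind(ubox_at(55), hit("WD40", L - 200, L - 60)),
    VII = rbind(ubox_at(65), hit("TPR", 0.5 * L, 0.5 * L + 100)),
    VIII = rbind(ubox_at(65), hit("TPR", 0.35 * L, 0.35 * L + 100),
                 hit("PKC", L - 250, L - 50)),
    IX = rbind(hit("MIF4G", 20, 250), ubox_at(L - 115)),
    X = rbind(hit("DJ1", 20, 200), ubox_at(0.6 * L)))
  protein_record(id, L, domains = dom, species = species)
}

#' Simulate an amino-acid alignment along a tree
#'
#' Evolves sequences from a uniformly random root down a tree with branch
#' lengths: on each edge, every site substitutes with probability
#' `1 - exp(-rate * branch_length)` to a uniformly chosen different residue
#' (a Jukes-Cantor-style model on the 20 amino-acid states, with uniform
#' equilibrium frequencies). This provides ground truth for testing
#' neighbor-joining recovery, not realistic protein sequence content.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param n_columns Alignment length (>= 1).
#' @param rate Substitution rate per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return An [aa_alignment()] over the tree's tips.
#' @export
simulate_alignment <- function(tree, n_columns, rate = 1, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            n_columns >= 1)
  if (rate < 0) stop("rate must be >= 0")
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tr <- stats::reorder(tree, "cladewise")  # parents precede children
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  with_local_seed(seed, {
    seqs <- matrix(NA_integer_, nnode, n_columns)
    root <- ntip + 1L
    seqs[root, ] <- sample.int(20L, n_columns, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      s <- seqs[parent, ]
      p <- 1 - exp(-rate * tr$edge.length[e])
      mut <- which(stats::runif(n_columns) < p)
      if (length(mut)) {
        shift <- sample.int(19L, length(mut), replace = TRUE)
        s[mut] <- (s[mut] - 1L + shift) %% 20L + 1L
      }
      seqs[child, ] <- s
    }
    m <- matrix(alphabet[seqs[seq_len(ntip), , drop = FALSE]], ntip, n_columns)
    rownames(m) <- tr$tip.label
    aa_alignment(m)
  })
}

#' Design of a simulated qPCR experiment
#'
#' @param log2_folds Named numeric vector: planted log2 fold change per gene
#'   (treated vs control). The reference gene is generated with planted fold
#'   0 by construction.
#' @param n_bio Biological replicates per condition (default 3; >= 2 enables
#'   testing).
#' @param n_tech Technical replicates per measurement (default 3, the
#'   technical-triplicate convention).
#' @param noise_sd Gaussian measurement noise, in cycles, added independently
#'   to every Cq value (default 0.2).
#' @param reference_gene Reference gene name (default `"actin"`).
#' @param reference_cq True reference Cq (default 16).
#' @param base_dct_range Range of true control dCt values drawn per gene
#'   (default 1-6 cycles above the reference).
#' @return List of class `cq_design`.
#' @export
cq_design <- function(log2_folds, n_bio = 3, n_tech = 3, noise_sd = 0.2,
                      reference_gene = "actin", reference_cq = 16,
                      base_dct_range = c(1, 6)) {
  stopifnot(is.numeric(log2_folds), !is.null(names(log2_folds)),
            noise_sd >= 0, n_bio >= 1, n_tech >= 1)
  if (reference_gene %in% names(log2_folds)) {
    stop("reference gene cannot carry a planted fold")
  }
  structure(list(log2_folds = log2_folds, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), noise_sd = noise_sd,
                 reference_gene = reference_gene, reference_cq = reference_cq,
                 base_dct_range = base_dct_range),
            class = "cq_design")
}

#' Simulate a Cq table with planted fold changes
#'
#' Each gene receives a true control dCt (drawn once per gene from
#' `base_dct_range`); its treated dCt is the control dCt minus the planted
#' log2 fold, so that the delta-delta-Ct estimate targets the planted fold.
#' Gaussian noise of sd `noise_sd` is added independently to every Cq
#' measurement (gene and reference alike, each technical replicate). With
#' `noise_sd = 0`, [delta_delta_ct()] recovers the planted folds exactly.
#'
#' @param design A [cq_design()].
#' @param seed Integer seed.
#' @return A `cq_table` with the design's reference gene attached.
#' @export
simulate_cq_table <- function(design, seed) {
  stopifnot(inherits(design, "cq_design"))
  with_local_seed(seed, {
    genes <- names(design$log2_folds)
    base_dct <- stats::runif(length(genes), design$base_dct_range[1],
                             design$base_dct_range[2])
    names(base_dct) <- genes
    rows <- list()
    add <- function(gene, cond, bio, true_cq) {
      noise <- stats::rnorm(design$n_tech, 0, design$noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, condition = cond, bio_rep = bio,
        tech_rep = seq_len(design$n_tech), cq = true_cq + noise,
        stringsAsFactors = FALSE)
    }
    for (cond in c("control", "treated")) {
      for (bio in seq_len(design$n_bio)) {
        add(design$reference_gene, cond, bio, design$reference_cq)
        for (g in genes) {
          dct <- if (cond == "control") base_dct[[g]]
                 else base_dct[[g]] - design$log2_folds[[g]]
          add(g, cond, bio, design$reference_cq + dct)
        }
      }
    }
    cq_table(do.call(rbind, rows), reference_gene = design$reference_gene)
  })
}
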