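#' Summarize EST library counts per class
#'
#' Aggregates the four EST-library count columns (abiotic, biotic,
#' generative, vegetative) of a gene catalog per class and per gene, and
#' flags genes with no matching ESTs. Totals are invariant to row order.
#'
#' @param catalog A `pub_catalog` data frame (see [read_gene_catalog()]);
#'   its `class_label` column groups the per-class totals.
#' @return List with `per_class` (one row per class plus a `TOTAL` row),
#'   `per_gene` (gene, class, four counts, total, `no_est` flag).
#' @export
summarize_est_categories <- function(catalog) {
  est_cols <- c("est_abiotic", "est_biotic", "est_generative", "est_vegetative")
  stopifnot(all(est_cols %in% names(catalog)))
  per_gene <- data.frame(name = catalog$name, class_label = catalog$class_label,
                         catalog[est_cols],
                         total = rowSums(catalog[est_cols]),
                         stringsAsFactors = FALSE)
  per_gene$no_est <- per_gene$total == 0
  lab <- if (all(is.na(per_gene$class_label))) rep("all", nrow(per_gene))
         else per_gene$class_label
  agg <- stats::aggregate(per_gene[c(est_cols, "total")], by = list(class_label = lab), sum)
  agg <- agg[order(agg$class_label), , drop = FALSE]
  total_row <- data.frame(class_label = "TOTAL",
                          t(colSums(agg[c(est_cols, "total")])))
  per_class <- rbind(agg, total_row)
  rownames(per_class) <- NULL
  list(per_class = per_class, per_gene = per_gene)
}

#' Assemble a pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param catalog Path to a gene catalog TSV (optional; enables tandem
#'   detection, EST summaries and catalog columns in the report).
#' @param domains Path to a domain annotation file (required).
#' @param domains_format Annotation dialect for [read_domain_annotations()].
#' @param alignment Path to an aligned FASTA (optional; enables the tree
#'   stage).
#' @param cq Path to a Cq CSV (optional; enables expression calls).
#' @param reference_gene Reference gene for the expression stage.
#' @param seed Integer seed, recorded in every output header and used for the
#'   bootstrap.
#' @param bootstrap Bootstrap replicates for the tree stage (default 1000).
#' @param gap_mode Distance gap handling for the tree stage.
#' @param rule_config A [pub_rule_config()].
#' @param up_fold,strong_down_fold Expression thresholds (defaults 2 and 3).
#' @return List of class `pub_run_config`.
#' @export
pub_run_config <- function(out_dir, domains,
                           domains_format = "simple_tsv",
                           catalog = NULL, alignment = NULL, cq = NULL,
                           reference_gene = "actin", seed = 1,
                           bootstrap = 1000,
                           gap_mode = "pairwise_deletion",
                           rule_config = pub_rule_config(),
                           up_fold = 2.0, strong_down_fold = 3.0) {
  cfg <- list(out_dir = out_dir, domains = domains,
              domains_format = domains_format, catalog = catalog,
              alignment = alignment, cq = cq,
              reference_gene = reference_gene, seed = as.integer(seed),
              bootstrap = as.integer(bootstrap), gap_mode = gap_mode,
              rule_config = rule_config, up_fold = up_fold,
              strong_down_fold = strong_down_fold)
  class(cfg) <- "pub_run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' All [pub_run_config()] fields may appear as top-level keys;
#' `rule_config` sub-keys (`und_fraction`, `arm_like_counts_as_arm`,
#' `ubox_point`, `tandem_max_gap_bp`) are forwarded to [pub_rule_config()].
#'
#' @param path YAML file path.
#' @return A `pub_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rc <- do.call(pub_rule_config, if (is.null(y$rule_config)) list() else y$rule_config)
  y$rule_config <- rc
  do.call(pub_run_config, y)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

write_tsv_with_header <- function(d, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full PUB analysis pipeline
#'
#' Orchestrates classification, catalog structure, phylogeny and expression
#' calling and writes `assignments.tsv`, `summary.tsv`, `clusters.tsv`,
#' `tree.nwk`, `calls.tsv` and a joined per-gene `report.tsv` into the
#' configured output directory. Optional stages (tree, expression, catalog)
#' are skipped with a warning when their input is absent; any stage failure
#' aborts the run and removes partial outputs. Every output carries a header
#' comment with the seed and a configuration hash, and a rerun with the same
#' config and seed is byte-identical.
#'
#' @param config A [pub_run_config()] or the path to a YAML config file.
#' @return Invisibly, a list with the classification summary, clusters,
#'   tree, expression calls and the report data frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "pub_run_config"))
  if (!file.exists(config$domains)) {
    stop("classify stage: domain annotation file not found: ", config$domains)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("pubclassr run; seed: %d; config_hash: %s",
                 config$seed, config_hash(config))
  written <- character()
  emit <- function(d, name) {
    p <- file.path(config$out_dir, name)
    write_tsv_with_header(d, p, hdr)
    written <<- c(written, p)
    p
  }
  on_fail <- function(stage, e) {
    unlink(written)
    stop(stage, " stage failed: ", conditionMessage(e), call. = FALSE)
  }

  # classification
  res <- tryCatch({
    records <- read_domain_annotations(config$domains, config$domains_format)
    summ <- classify_proteome(records, config$rule_config)
    emit(summ$assignments, "assignments.tsv")
    emit(data.frame(class = names(summ$class_counts),
                    n = as.integer(summ$class_counts)), "summary.tsv")
    message("classify: ", summ$n_classified, "/", summ$n, " proteins classified")
    summ
  }, error = function(e) on_fail("classify", e))

  # catalog structure
  catalog <- NULL; clusters <- list()
  if (!is.null(config$catalog)) {
    res_cat <- tryCatch({
      catalog <- read_gene_catalog(config$catalog)
      clusters <- find_tandem_clusters(catalog,
                                       config$rule_config$tandem_max_gap_bp)
      cl_df <- if (length(clusters)) {
        do.call(rbind, lapply(seq_along(clusters), function(i) {
          cbind(cluster = i, clusters[[i]])
        }))
      } else {
        data.frame(cluster = integer(), name = character(),
                   chromosome = character(), start_bp = numeric(),
                   end_bp = numeric())
      }
      emit(cl_df, "clusters.tsv")
      message("catalog: ", nrow(catalog), " genes, ", length(clusters),
              " tandem/duplication cluster(s)")
      list(catalog = catalog, clusters = clusters)
    }, error = function(e) on_fail("catalog", e))
    catalog <- res_cat$catalog; clusters <- res_cat$clusters
  } else {
    warning("catalog stage skipped: no catalog configured", call. = FALSE)
  }

  # phylogeny
  tree <- NULL
  if (!is.null(config$alignment) && file.exists(config$alignment)) {
    tree <- tryCatch({
      aln <- read_aligned_fasta(config$alignment)
      tr <- bootstrap_support(aln, n_replicates = config$bootstrap,
                              seed = config$seed, gap_mode = config$gap_mode)
      p <- file.path(config$out_dir, "tree.nwk")
      writeLines(c(paste0("# ", hdr), write_newick(tr)), p)
      written <- c(written, p)
      message("phylo: NJ tree with ", config$bootstrap,
              " bootstrap replicates on ", ape::Ntip(tr), " taxa")
      tr
    }, error = function(e) on_fail("phylo", e))
  } else {
    warning("phylogeny stage skipped: no alignment available", call. = FALSE)
  }

  # expression
  calls <- NULL
  if (!is.null(config$cq) && file.exists(config$cq)) {
    calls <- tryCatch({
      cq <- read_cq_table(config$cq, config$reference_gene)
      er <- analyze_expression(cq)
      sc <- call_stress_response(er, up_fold = config$up_fold,
                                 strong_down_fold = config$strong_down_fold,
                                 assignments = res$assignments)
      emit(sc$calls, "calls.tsv")
      message("expression: ", sum(sc$calls$call == "up"), " up, ",
              sum(sc$calls$call == "down"), " down of ", nrow(sc$calls),
              " genes")
      sc
    }, error = function(e) on_fail("expression", e))
  } else {
    warning("expression stage skipped: no Cq table available", call. = FALSE)
  }

  # joined report
  report <- tryCatch({
    rep <- res$assignments[c("protein", "pub_class", "subclass")]
    cluster_of <- rep(NA_integer_, nrow(rep))
    if (length(clusters)) {
      for (i in seq_along(clusters)) {
        cluster_of[rep$protein %in% clusters[[i]]$name] <- i
      }
    }
    rep$cluster <- cluster_of
    if (!is.null(catalog)) {
      m <- match(rep$protein, catalog$name)
      rep$est_total <- rowSums(catalog[m, c("est_abiotic", "est_biotic",
                                            "est_generative", "est_vegetative")])
    } else {
      rep$est_total <- NA_real_
    }
    if (!is.null(calls)) {
      m <- match(rep$protein, calls$calls$gene)
      rep$fold <- calls$calls$fold[m]
      rep$p_value <- calls$calls$p_value[m]
      rep$call <- calls$calls$call[m]
    } else {
      rep$fold <- NA_real_; rep$p_value <- NA_real_; rep$call <- NA_character_
    }
    emit(rep, "report.tsv")
    rep
  }, error = function(e) on_fail("report", e))

  invisible(list(classification = res, catalog = catalog, clusters = clusters,
                 tree = tree, calls = calls, report = report))
}

#' Generate a synthetic demonstration input bundle
#'
#' Writes a complete, mutually consistent input set into `dir`: the packaged
#' barley gene catalog, domain annotations generated from its class
#' composition (so protein ids match catalog gene names), an alignment
#' simulated on a random tree over the same genes, and a Cq table with
#' planted log2 fold changes for a handful of genes. Useful for end-to-end
#' runs of [run_pipeline()] without external data.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_columns Alignment length (default 300).
#' @return A [pub_run_config()] pointing at the generated files.
#' @export
synth_demo_bundle <- function(dir, seed = 1, n_columns = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  catalog_path <- system.file("extdata", "barley_pub_catalog.tsv",
                              package = "pubclassr")
  catalog <- read_gene_catalog(catalog_path)
  # composition keyed like the generator, ids taken from the catalog
  lab <- catalog$class_label
  key <- ifelse(lab == "IV", NA, lab)  # IV split below
  iv_names <- catalog$name[lab == "IV"]
  comp_order <- c("I", "IIa", "IIb", "III", "IV_2", "IV_3", "V", "VI", "VII", "X")
  ids <- c()
  comp <- c()
  for (k in comp_order) {
    nm <- if (k == "IV_2") iv_names[1:6]
          else if (k == "IV_3") iv_names[7:11]
          else catalog$name[key == k & !is.na(key)]
    if (length(nm)) { comp[k] <- length(nm); ids <- c(ids, nm) }
  }
  records <- generate_architectures(comp, seed = seed, ids = ids, species = "Hv")
  domains_path <- file.path(dir, "domains.tsv")
  write_domain_annotations(records, domains_path)
  tree <- with_local_seed(seed, ape::rtree(length(ids), tip.label = ids))
  aln <- simulate_alignment(tree, n_columns = n_columns, rate = 0.5, seed = seed)
  aln_path <- file.path(dir, "alignment.fasta")
  write_aligned_fasta(aln, aln_path)
  lfc <- stats::setNames(rep(0, length(ids)), ids)
  lfc[seq_len(min(6, length(ids)))] <- c(3, 2, 1.5, -2, -3, 0)[seq_len(min(6, length(ids)))]
  cqt <- simulate_cq_table(cq_design(lfc), seed = seed)
  cq_path <- file.path(dir, "cq.csv")
  write_cq_table(cqt, cq_path, header_comment = paste("seed:", seed))
  pub_run_config(out_dir = file.path(dir, "out"), domains = domains_path,
                 catalog = catalog_path, alignment = aln_path, cq = cq_path,
                 seed = seed)
}
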