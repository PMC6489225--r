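#' Classification rule configuration
#'
#' Tunable parameters of the PUB class rules.
#'
#' @param und_fraction Fraction of the protein length that delimits the
#'   N-terminal quarter used by the Class II-a/II-b split ("one fourth of the
#'   full length"); default 0.25.
#' @param arm_like_counts_as_arm Should a degenerate ARM-like (GKL) region
#'   qualify a protein for Class II? Default `FALSE`: ARM-like proteins fall
#'   to Class V (the re-classification this scheme introduces); `TRUE`
#'   reproduces the superseded grouping for comparison.
#' @param ubox_point Which point of the U-box hit is compared against
#'   `und_fraction * length`: its `"midpoint"` (default; robust to
#'   annotation-tool boundary jitter) or its `"start"`.
#' @param tandem_max_gap_bp Maximum intergenic gap (bp) for two neighbouring
#'   genes to be chained into a tandem/duplication cluster; default 100000.
#' @return A list of class `pub_rule_config`.
#' @export
pub_rule_config <- function(und_fraction = 0.25,
                            arm_like_counts_as_arm = FALSE,
                            ubox_point = c("midpoint", "start"),
                            tandem_max_gap_bp = 100000) {
  stopifnot(und_fraction > 0, und_fraction < 1, tandem_max_gap_bp >= 1)
  structure(list(und_fraction = und_fraction,
                 arm_like_counts_as_arm = isTRUE(arm_like_counts_as_arm),
                 ubox_point = match.arg(ubox_point),
                 tandem_max_gap_bp = as.integer(tandem_max_gap_bp)),
            class = "pub_rule_config")
}

#' Classify one U-box protein by its domain architecture
#'
#' Assigns one of the ten PUB classes (I-X) or `UNCLASSIFIED` from the
#' controlled-vocabulary domain hits of a [protein_record()]. A protein with
#' no U-box hit is `UNCLASSIFIED`. Otherwise the first matching rule in a
#' fixed precedence order wins, rarer and more specific domains first:
#'
#' * `I`    — UFD2 domain present (UFD2 + U-box architecture)
#' * `III`  — cyclophilin (peptidyl-prolyl isomerase) domain
#' * `VIII` — TPR together with a kinase domain (PKc or STK-N)
#' * `IV`   — kinase domain (PKc and/or STK-N), sub-grouped by
#'   [subclassify_class_iv()]
#' * `VII`  — TPR
#' * `VI`   — WD40
#' * `IX`   — MIF4G
#' * `X`    — DJ-1
#' * `II`   — ARM and/or HEAT repeats (ARM-like only if
#'   `config$arm_like_counts_as_arm`), sub-grouped by
#'   [subclassify_class_ii()]
#' * `V`    — a U-box and no other qualifying domain; by default this absorbs
#'   proteins whose only extra evidence is a degenerate ARM-like region.
#'
#' Every rule consulted is appended to a machine-readable rationale trace so
#' multi-domain conflicts can be audited.
#'
#' @param record A [protein_record()].
#' @param config A [pub_rule_config()].
#' @return List of class `pub_assignment` with elements `protein`,
#'   `pub_class`, `subclass` (non-`NA` only for classes II and IV), and
#'   `rationale` (character vector of rule identifiers that fired).
#' @export
classify_protein <- function(record, config = pub_rule_config()) {
  stopifnot(inherits(record, "protein_record"),
            inherits(config, "pub_rule_config"))
  rationale <- character()
  note <- function(x) rationale <<- c(rationale, x)
  kinase <- has_domain(record, c("PKC", "STK_N"))
  arm_evidence <- c("ARM", "HEAT",
                    if (config$arm_like_counts_as_arm) "ARM_LIKE")

  if (!has_domain(record, "U_BOX")) {
    note("no_ubox")
    cls <- "UNCLASSIFIED"; sub <- NA_character_
  } else if (has_domain(record, "UFD2")) {
    note("ufd2->I"); cls <- "I"; sub <- NA_character_
  } else if (has_domain(record, "CYCLOPHILIN")) {
    note("cyclophilin->III"); cls <- "III"; sub <- NA_character_
  } else if (has_domain(record, "TPR") && kinase) {
    note("tpr+kinase->VIII"); cls <- "VIII"; sub <- NA_character_
  } else if (kinase) {
    note("kinase->IV"); cls <- "IV"
    sub <- subclassify_class_iv(record)
    note(paste0("kinase_set->", sub))
  } else if (has_domain(record, "TPR")) {
    note("tpr->VII"); cls <- "VII"; sub <- NA_character_
  } else if (has_domain(record, "WD40")) {
    note("wd40->VI"); cls <- "VI"; sub <- NA_character_
  } else if (has_domain(record, "MIF4G")) {
    note("mif4g->IX"); cls <- "IX"; sub <- NA_character_
  } else if (has_domain(record, "DJ1")) {
    note("dj1->X"); cls <- "X"; sub <- NA_character_
  } else if (has_domain(record, arm_evidence)) {
    note(if (has_domain(record, c("ARM", "HEAT"))) "arm_heat->II"
         else "arm_like_as_arm->II")
    cls <- "II"
    s <- subclassify_class_ii(record, config)
    sub <- s$subclass
    rationale <- c(rationale, s$rationale)
  } else {
    if (has_domain(record, "ARM_LIKE")) note("arm_like_not_arm")
    note("ubox_only->V")
    cls <- "V"; sub <- NA_character_
  }
  structure(list(protein = record$id, pub_class = cls, subclass = sub,
                 rationale = rationale),
            class = "pub_assignment")
}

#' Split Class II into II-a and II-b by U-box position
#'
#' Class II-a proteins carry the U-box near the centre, leaving an N-terminal
#' region (the UND) before it; Class II-b proteins carry the U-box close to
#' the N-terminus. The rule compares a reference point of the most N-terminal
#' U-box hit (midpoint by default) against `und_fraction * length`: at or
#' below the boundary is II-b, above it II-a. The boundary itself is II-b
#' (inclusive `<=`, a documented tie rule).
#'
#' @inheritParams classify_protein
#' @return List with `subclass` (`"IIa"` or `"IIb"`) and a `rationale` trace.
#' @export
subclassify_class_ii <- function(record, config = pub_rule_config()) {
  hits <- record$domains[record$domains$label == "U_BOX", , drop = FALSE]
  if (nrow(hits) == 0) stop("protein ", record$id, " has no U-box hit")
  rationale <- character()
  if (nrow(hits) > 1) rationale <- "multiple_ubox_use_most_nterminal"
  h <- hits[which.min(hits$start_aa), ]
  p <- if (config$ubox_point == "midpoint") (h$start_aa + h$end_aa) / 2
       else h$start_aa
  boundary <- config$und_fraction * record$length_aa
  sub <- if (p <= boundary) "IIb" else "IIa"
  rationale <- c(rationale,
                 sprintf("ubox_%s=%.1f_%s_%.3fL->%s", config$ubox_point, p,
                         if (p <= boundary) "le" else "gt",
                         config$und_fraction, sub))
  list(subclass = sub, rationale = rationale)
}

#' Split Class IV into kinase-domain subgroups
#'
#' Subgroup `IV_1` carries both kinase domains (PKc and STK-N), `IV_2` only
#' the catalytic PKc domain, `IV_3` only the N-terminal STK-N domain. The
#' three cases are exhaustive for a Class IV protein.
#'
#' @param record A [protein_record()] that classifies to Class IV.
#' @return `"IV_1"`, `"IV_2"` or `"IV_3"`.
#' @export
subclassify_class_iv <- function(record) {
  pkc <- has_domain(record, "PKC")
  stk <- has_domain(record, "STK_N")
  if (!pkc && !stk) stop("protein ", record$id, " has no kinase domain")
  if (pkc && stk) "IV_1" else if (pkc) "IV_2" else "IV_3"
}

#' Classify a set of proteins and tabulate class composition
#'
#' @param records Named list of [protein_record()] objects (unique ids).
#' @param config A [pub_rule_config()].
#' @return List of class `pub_class_summary`: `assignments` (data frame with
#'   columns `protein`, `pub_class`, `subclass`, `rationale`), `class_counts`
#'   (named integer vector over I-X; `UNCLASSIFIED` listed separately), and
#'   `subclass_counts` over IIa/IIb/IV_1/IV_2/IV_3.
#' @export
classify_proteome <- function(records, config = pub_rule_config()) {
  stopifnot(length(records) >= 1)
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate protein id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  asn <- lapply(records, classify_protein, config = config)
  df <- data.frame(
    protein = ids,
    pub_class = vapply(asn, `[[`, "", "pub_class"),
    subclass = vapply(asn, `[[`, "", "subclass"),
    rationale = vapply(asn, function(a) paste(a$rationale, collapse = ";"), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  classes <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X")
  class_counts <- vapply(classes, function(k) sum(df$pub_class == k), 0L)
  class_counts <- c(class_counts,
                    UNCLASSIFIED = sum(df$pub_class == "UNCLASSIFIED"))
  subs <- c("IIa", "IIb", "IV_1", "IV_2", "IV_3")
  subclass_counts <- vapply(subs, function(k) sum(df$subclass == k, na.rm = TRUE), 0L)
  structure(list(assignments = df, class_counts = class_counts,
                 subclass_counts = subclass_counts,
                 n = nrow(df), n_classified = sum(df$pub_class != "UNCLASSIFIED")),
            class = "pub_class_summary")
}

#' @export
print.pub_class_summary <- function(x, ...) {
  cat("PUB classification:", x$n_classified, "of", x$n, "proteins classified\n")
  print(x$class_counts[x$class_counts > 0 | names(x$class_counts) == "UNCLASSIFIED"])
  if (any(x$subclass_counts > 0)) {
    cat("subclasses:\n")
    print(x$subclass_counts[x$subclass_counts > 0])
  }
  invisible(x)
}

#' Find tandemly arranged / clustered gene groups
#'
#' Within each chromosome, genes are sorted by start coordinate and chained
#' whenever the gap between one gene's end and the next gene's start is at
#' most `max_gap_bp`; maximal chains of two or more genes are reported.
#' `chrUn` is treated as an ordinary chromosome. The result is invariant to
#' input row order and the clusters are disjoint.
#'
#' @param catalog A `pub_catalog` data frame (see [read_gene_catalog()]).
#' @param max_gap_bp Maximum gap in bp (default 100000).
#' @return List of clusters; each a data frame with columns `name`,
#'   `chromosome`, `start_bp`, `end_bp`.
#' @examples
#' path <- system.file("extdata", "barley_pub_catalog.tsv", package = "pubclassr")
#' find_tandem_clusters(read_gene_catalog(path))  # HvPUB11/12 and HvPUB58/59
#' @export
find_tandem_clusters <- function(catalog, max_gap_bp = 100000) {
  stopifnot(all(c("name", "chromosome", "start_bp", "end_bp") %in% names(catalog)))
  out <- list()
  for (chr in sort(unique(catalog$chromosome))) {
    d <- catalog[catalog$chromosome == chr, , drop = FALSE]
    d <- d[order(d$start_bp, d$end_bp, d$name), , drop = FALSE]
    if (nrow(d) < 2) next
    gap <- d$start_bp[-1] - d$end_bp[-nrow(d)]
    brk <- c(0, cumsum(gap > max_gap_bp))
    for (g in split(seq_len(nrow(d)), brk)) {
      if (length(g) >= 2) {
        cl <- d[g, c("name", "chromosome", "start_bp", "end_bp"), drop = FALSE]
        rownames(cl) <- NULL
        out[[length(out) + 1L]] <- cl
      }
    }
  }
  out
}
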