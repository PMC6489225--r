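#' Construct a protein record with located domain hits
#'
#' A `protein_record` holds a protein id, its length in residues, an optional
#' species tag, and an ordered table of domain hits on the controlled
#' vocabulary. Hits are sorted by start coordinate and overlapping hits of the
#' same label are merged into one hit spanning their union. Coordinates are
#' 1-based inclusive.
#'
#' @param id Protein identifier.
#' @param length_aa Protein length in residues (>= 1).
#' @param domains Data frame with columns `label`, `start_aa`, `end_aa` and
#'   optionally `source_accession`, `score`. May have zero rows.
#' @param species Optional species tag (e.g. "Hv", "At", "Os").
#' @param merge_overlaps Merge overlapping same-label hits (default `TRUE`).
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, length_aa, domains = empty_domain_table(),
                           species = NA_character_, merge_overlaps = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  length_aa <- as.integer(length_aa)
  stopifnot(length(length_aa) == 1L, !is.na(length_aa), length_aa >= 1L)
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  if (nrow(domains) > 0) {
    req <- c("label", "start_aa", "end_aa")
    if (!all(req %in% names(domains))) {
      stop("domain table must have columns label, start_aa, end_aa")
    }
    domains$start_aa <- as.integer(domains$start_aa)
    domains$end_aa <- as.integer(domains$end_aa)
    bad <- domains$start_aa < 1L | domains$start_aa > domains$end_aa
    if (any(bad)) {
      stop("protein ", id, ": invalid domain coordinates (need 1 <= start <= end)")
    }
    if (any(domains$end_aa > length_aa)) {
      stop("protein ", id, ": domain hit extends beyond protein length ",
           length_aa)
    }
    if (!all(domains$label %in% pub_domain_labels())) {
      stop("protein ", id, ": domain labels outside the controlled vocabulary")
    }
    if (is.null(domains$source_accession)) domains$source_accession <- NA_character_
    if (is.null(domains$score)) domains$score <- NA_real_
    domains <- domains[order(domains$start_aa, domains$end_aa), , drop = FALSE]
    if (merge_overlaps) domains <- merge_same_label_overlaps(domains)
    rownames(domains) <- NULL
  } else {
    domains <- empty_domain_table()
  }
  structure(list(id = id, species = species, length_aa = length_aa,
                 domains = domains),
            class = "protein_record")
}

empty_domain_table <- function() {
  data.frame(label = character(), start_aa = integer(), end_aa = integer(),
             source_accession = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

# Union of overlapping (or touching) intervals, per label.
merge_same_label_overlaps <- function(domains) {
  out <- lapply(split(domains, domains$label), function(d) {
    d <- d[order(d$start_aa, d$end_aa), , drop = FALSE]
    keep <- d[1, , drop = FALSE]
    if (nrow(d) > 1) {
      for (k in 2:nrow(d)) {
        last <- nrow(keep)
        if (d$start_aa[k] <= keep$end_aa[last]) {
          keep$end_aa[last] <- max(keep$end_aa[last], d$end_aa[k])
        } else {
          keep <- rbind(keep, d[k, , drop = FALSE])
        }
      }
    }
    keep
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start_aa, out$end_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.protein_record <- function(x, ...) {
  cat("protein_record", x$id, paste0("(", x$length_aa, " aa"),
      if (!is.na(x$species)) paste0(", ", x$species), ")\n", sep = " ")
  if (nrow(x$domains)) {
    cat(paste0("  ", x$domains$label, " [", x$domains$start_aa, ",",
               x$domains$end_aa, "]", collapse = "\n"), "\n")
  } else {
    cat("  (no domain hits)\n")
  }
  invisible(x)
}

has_domain <- function(record, labels) {
  any(record$domains$label %in% labels)
}

first_hit <- function(record, label) {
  d <- record$domains[record$domains$label == label, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  d[which.min(d$start_aa), , drop = FALSE]
}
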