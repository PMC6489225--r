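#' Controlled vocabulary of PUB domain labels
#'
#' The classifier reasons over a small controlled vocabulary of domain labels
#' rather than raw annotation-tool accessions. `pub_domain_labels()` returns
#' the vocabulary; [normalize_domain_label()] maps accessions and free-text
#' names onto it.
#'
#' @return Character vector of recognised labels.
#' @export
pub_domain_labels <- function() {
  c("U_BOX", "UFD2", "ARM", "HEAT", "ARM_LIKE", "CYCLOPHILIN",
    "PKC", "STK_N", "WD40", "TPR", "MIF4G", "DJ1", "OTHER")
}

#' Default accession/name to domain-label mapping
#'
#' Seeds the Pfam accessions commonly reported for the domains that define the
#' ten PUB classes, plus case-insensitive free-text aliases. Users can extend
#' or override the mapping via the `vocab` argument of
#' [normalize_domain_label()] and [read_domain_annotations()].
#'
#' @return Named character vector: names are raw tokens (upper-cased), values
#'   are controlled labels.
#' @export
default_domain_vocab <- function() {
  c(
    # Pfam accessions
    PF04564 = "U_BOX",
    PF10408 = "UFD2",
    PF00514 = "ARM",
    PF02985 = "HEAT",
    PF13646 = "HEAT",
    PF00160 = "CYCLOPHILIN",
    PF00069 = "PKC",
    PF00400 = "WD40",
    PF00515 = "TPR",
    PF13176 = "TPR",
    PF02854 = "MIF4G",
    PF01965 = "DJ1",
    # free-text aliases (matched upper-cased, punctuation collapsed)
    `U-BOX` = "U_BOX", UBOX = "U_BOX", U_BOX = "U_BOX",
    UFD2 = "UFD2",
    ARM = "ARM", ARMADILLO = "ARM",
    HEAT = "HEAT",
    `ARM-LIKE` = "ARM_LIKE", ARM_LIKE = "ARM_LIKE", GKL = "ARM_LIKE",
    CYCLOPHILIN = "CYCLOPHILIN", `PPIASE` = "CYCLOPHILIN",
    PKC = "PKC", `S_TKC` = "PKC", KINASE = "PKC",
    `STK-N` = "STK_N", STK_N = "STK_N",
    WD40 = "WD40", `WD-40` = "WD40",
    TPR = "TPR", TRP = "TPR",
    MIF4G = "MIF4G",
    `DJ-1` = "DJ1", DJ1 = "DJ1", THIJ = "DJ1"
  )
}

#' Normalize a raw domain accession or name to the controlled vocabulary
#'
#' Lookup is case-insensitive; Pfam accessions are matched with or without a
#' version suffix (`PF04564.12` matches `PF04564`). Unmapped input maps to
#' `"OTHER"` with a warning, so normalization is a total function.
#'
#' @param raw Character vector of accessions or names.
#' @param vocab Named character mapping raw tokens to labels; defaults to
#'   [default_domain_vocab()]. User entries are matched before the defaults.
#' @param warn Warn on unmapped tokens (default `TRUE`).
#' @return Character vector of labels from [pub_domain_labels()].
#' @examples
#' normalize_domain_label(c("PF04564", "u-box", "PF00514"))
#' @export
normalize_domain_label <- function(raw, vocab = default_domain_vocab(),
                                   warn = TRUE) {
  stopifnot(is.character(raw))
  map <- vocab
  if (!identical(names(map), names(default_domain_vocab())) ||
      !identical(unname(map), unname(default_domain_vocab()))) {
    # user overrides take precedence over the shipped defaults
    defaults <- default_domain_vocab()
    map <- c(vocab, defaults[!toupper(names(defaults)) %in% toupper(names(vocab))])
  }
  names(map) <- toupper(names(map))
  key <- toupper(trimws(raw))
  key <- sub("^(PF\\d{5})\\.\\d+$", "\\1", key)  # strip Pfam version suffix
  out <- unname(map[key])
  miss <- is.na(out)
  if (any(miss)) {
    if (warn) {
      warning("unmapped domain label(s) set to OTHER: ",
              paste(unique(raw[miss]), collapse = ", "), call. = FALSE)
    }
    out[miss] <- "OTHER"
  }
  out
}
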