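#' Read a gene catalog in the family-table dialect
#'
#' Parses a tab-separated gene catalog with columns `class`, `name`,
#' `gene_id`, `locus`, and four EST-library count columns (`est_abiotic`,
#' `est_biotic`, `est_generative`, `est_vegetative`). Locus strings of the
#' form `"chr5H:102370756-102,375,777"` are split into chromosome, start and
#' end; both ASCII hyphen and en-dash separators and digit-grouping commas are
#' accepted. Blank EST cells are read as 0. Genomic coordinates are 1-based
#' inclusive.
#'
#' @param path Path to the catalog file.
#' @param dialect Catalog dialect; only `"table1_tsv"` is defined.
#' @return A data frame of class `pub_catalog` with columns `name`, `gene_id`,
#'   `chromosome`, `start_bp`, `end_bp`, `class_label`, `est_abiotic`,
#'   `est_biotic`, `est_generative`, `est_vegetative`.
#' @examples
#' path <- system.file("extdata", "barley_pub_catalog.tsv", package = "pubclassr")
#' cat67 <- read_gene_catalog(path)
#' nrow(cat67)  # 67
#' @export
read_gene_catalog <- function(path, dialect = "table1_tsv") {
  dialect <- match.arg(dialect, "table1_tsv")
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character", encoding = "UTF-8",
                           blank.lines.skip = TRUE)
  req <- c("name", "gene_id", "locus")
  if (!all(req %in% names(raw))) {
    stop("catalog is missing required column(s): ",
         paste(setdiff(req, names(raw)), collapse = ", "))
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicate gene name(s) in catalog: ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "))
  }
  loc <- parse_locus(raw$locus, raw$name)
  est_cols <- c("est_abiotic", "est_biotic", "est_generative", "est_vegetative")
  est <- lapply(est_cols, function(col) {
    v <- if (col %in% names(raw)) raw[[col]] else rep("", nrow(raw))
    v[is.na(v) | !nzchar(trimws(v))] <- "0"
    n <- suppressWarnings(as.integer(gsub(",", "", v)))
    if (anyNA(n) || any(n < 0)) stop("non-numeric or negative EST count in ", col)
    n
  })
  names(est) <- est_cols
  out <- data.frame(name = raw$name, gene_id = raw$gene_id,
                    chromosome = loc$chromosome, start_bp = loc$start_bp,
                    end_bp = loc$end_bp,
                    class_label = if ("class" %in% names(raw)) raw$class
                                  else NA_character_,
                    est, stringsAsFactors = FALSE)
  class(out) <- c("pub_catalog", "data.frame")
  out
}

# "chrNH:A-B" with optional digit commas; hyphen or en-dash. 1-based inclusive.
parse_locus <- function(locus, names) {
  locus <- gsub(",", "", trimws(locus))
  m <- regmatches(locus, regexec("^([^:]+):([0-9]+)[–-]([0-9]+)$", locus))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed locus string for row(s): ",
         paste(names[bad], collapse = ", "))
  }
  start <- as.numeric(vapply(m, `[`, "", 3))
  end <- as.numeric(vapply(m, `[`, "", 4))
  if (any(start > end)) {
    stop("locus start > end for row(s): ", paste(names[start > end], collapse = ", "))
  }
  list(chromosome = vapply(m, `[`, "", 2), start_bp = start, end_bp = end)
}

#' Write a gene catalog in the family-table dialect
#'
#' Inverse of [read_gene_catalog()]: reading the written file reproduces all
#' fields exactly. Loci are written as `chrom:start-end` without digit
#' grouping; zero EST counts are written as blanks (the convention of printed
#' family tables).
#'
#' @param catalog A `pub_catalog` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  est_cols <- c("est_abiotic", "est_biotic", "est_generative", "est_vegetative")
  est <- lapply(catalog[est_cols], function(v) ifelse(v == 0, "", as.character(v)))
  out <- data.frame(class = catalog$class_label, name = catalog$name,
                    gene_id = catalog$gene_id,
                    locus = sprintf("%s:%.0f-%.0f", catalog$chromosome,
                                    catalog$start_bp, catalog$end_bp),
                    est, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-protein domain annotations
#'
#' Supports three dialects: `simple_tsv` (five whitespace- or tab-separated
#' columns: protein, protein length, domain accession/name, start, end; no
#' header), `interproscan_tsv` (the 14-column InterProScan TSV; protein id,
#' sequence length, signature accession, and match start/stop are taken from
#' columns 1, 3, 5, 7 and 8), and `hmmscan_domtblout` (HMMER3
#' `hmmscan --domtblout`; the alignment coordinates, `ali from`/`ali to`, are
#' used, not the envelope). Residue coordinates are 1-based inclusive.
#'
#' Raw labels are normalized with [normalize_domain_label()]; hits are grouped
#' by protein, sorted by start, and overlapping same-label hits are merged.
#'
#' @param path Path to the annotation file.
#' @param format One of `"simple_tsv"`, `"interproscan_tsv"`,
#'   `"hmmscan_domtblout"`.
#' @param vocab Label mapping passed to [normalize_domain_label()].
#' @param species Optional species tag stored on every record.
#' @return Named list of [protein_record()] objects.
#' @export
read_domain_annotations <- function(path,
                                    format = c("simple_tsv", "interproscan_tsv",
                                               "hmmscan_domtblout"),
                                    vocab = default_domain_vocab(),
                                    species = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  hits <- switch(format,
    simple_tsv = {
      d <- utils::read.table(path, stringsAsFactors = FALSE,
                             col.names = c("protein", "length", "raw_label",
                                           "start", "end"))
      d
    },
    interproscan_tsv = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      f <- strsplit(lines, "\t", fixed = TRUE)
      if (any(vapply(f, length, 0L) < 8L)) {
        stop("interproscan_tsv line with fewer than 8 columns")
      }
      data.frame(protein = vapply(f, `[`, "", 1),
                 length = as.integer(vapply(f, `[`, "", 3)),
                 raw_label = vapply(f, `[`, "", 5),
                 start = as.integer(vapply(f, `[`, "", 7)),
                 end = as.integer(vapply(f, `[`, "", 8)),
                 stringsAsFactors = FALSE)
    },
    hmmscan_domtblout = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      f <- strsplit(trimws(lines), "[[:space:]]+")
      if (any(vapply(f, length, 0L) < 22L)) {
        stop("hmmscan domtblout line with fewer than 22 columns")
      }
      acc <- vapply(f, `[`, "", 2)
      nm <- vapply(f, `[`, "", 1)
      data.frame(protein = vapply(f, `[`, "", 4),
                 length = as.integer(vapply(f, `[`, "", 6)),
                 raw_label = ifelse(acc == "-", nm, acc),
                 start = as.integer(vapply(f, `[`, "", 18)),  # ali from
                 end = as.integer(vapply(f, `[`, "", 19)),    # ali to
                 score = as.numeric(vapply(f, `[`, "", 14)),
                 stringsAsFactors = FALSE)
    })
  hits$label <- normalize_domain_label(hits$raw_label, vocab = vocab)
  if (is.null(hits$score)) hits$score <- NA_real_
  by_prot <- split(hits, hits$protein)
  # preserve first-appearance order
  by_prot <- by_prot[unique(hits$protein)]
  records <- lapply(by_prot, function(h) {
    len <- unique(h$length)
    if (length(len) != 1L) {
      stop("inconsistent protein length for ", h$protein[1])
    }
    protein_record(h$protein[1], len,
                   domains = data.frame(label = h$label, start_aa = h$start,
                                        end_aa = h$end,
                                        source_accession = h$raw_label,
                                        score = h$score,
                                        stringsAsFactors = FALSE),
                   species = species)
  })
  names(records) <- names(by_prot)
  records
}

#' Write protein records as a simple five-column annotation table
#'
#' @param records Named list of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_annotations <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$domains) == 0) return(NULL)
    data.frame(protein = r$id, length = r$length_aa, label = r$domains$label,
               start = r$domains$start_aa, end = r$domains$end_aa,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an aligned amino-acid FASTA file
#'
#' All sequences must have equal length (a ragged file is a validation error)
#' and unique labels. Residues are upper-cased; `-` is the gap character and
#' `X` the unknown residue.
#'
#' @param path Path to an aligned FASTA file.
#' @return Character matrix of class `aa_alignment`, rows = taxa.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", set.attributes = FALSE)
  aa_alignment(lapply(seqs, function(s) toupper(as.character(s))),
               ids = names(seqs))
}

#' Construct an alignment object
#'
#' @param rows List of equal-length character vectors (one per taxon), or a
#'   character matrix.
#' @param ids Taxon labels (required when `rows` has no names).
#' @return Character matrix of class `aa_alignment`.
#' @export
aa_alignment <- function(rows, ids = names(rows)) {
  if (is.matrix(rows)) {
    m <- rows
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, rows)
    rownames(m) <- ids
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("alignment taxa must have unique labels")
  }
  if (nrow(m) < 2L) stop("alignment needs at least 2 taxa")
  class(m) <- c("aa_alignment", class(m))
  m
}

#' Write an alignment as FASTA
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(aln, path) {
  seqinr::write.fasta(lapply(seq_len(nrow(aln)), function(i) unname(aln[i, ])),
                      names = rownames(aln), file.out = path)
  invisible(path)
}

#' Serialize a phylogenetic tree as newick text
#'
#' Emits branch lengths and, when present, integer bootstrap support values as
#' internal node labels. A single-leaf tree degenerates to `"label;"`.
#'
#' @param tree An [ape::phylo] tree, or a single taxon label.
#' @param path Optional output path; when `NULL` the newick string is returned.
#' @return Newick text (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    txt <- paste0(tree, ";")
  } else if (inherits(tree, "phylo") && ape::Ntip(tree) == 1L) {
    txt <- paste0(tree$tip.label, ";")
  } else {
    txt <- ape::write.tree(tree)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a quantification-cycle (Cq) table
#'
#' The CSV must have columns `gene`, `condition`, `bio_rep`, `tech_rep`, `cq`;
#' `condition` must be `control` or `treated`. When `reference_gene` is given
#' it must be present in every (condition, biological replicate) cell.
#'
#' @param path Path to a CSV file.
#' @param reference_gene Optional reference (housekeeping) gene name, stored
#'   as an attribute and used as the default by [delta_delta_ct()].
#' @return Data frame of class `cq_table`.
#' @export
read_cq_table <- function(path, reference_gene = NULL) {
  if (!file.exists(path)) stop("Cq file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  cq_table(d, reference_gene = reference_gene)
}

#' Validate a data frame as a Cq table
#' @param d Data frame with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `cq`.
#' @inheritParams read_cq_table
#' @return Data frame of class `cq_table`.
#' @export
cq_table <- function(d, reference_gene = NULL) {
  req <- c("gene", "condition", "bio_rep", "tech_rep", "cq")
  if (!all(req %in% names(d))) {
    stop("Cq table is missing required column(s): ",
         paste(setdiff(req, names(d)), collapse = ", "))
  }
  if (!all(d$condition %in% c("control", "treated"))) {
    stop("condition must be 'control' or 'treated'")
  }
  if (any(d$cq < 0)) stop("Cq values must be >= 0")
  if (!is.null(reference_gene)) {
    cells <- unique(d[, c("condition", "bio_rep")])
    ref <- d[d$gene == reference_gene, c("condition", "bio_rep")]
    ok <- interaction(cells$condition, cells$bio_rep) %in%
      interaction(ref$condition, ref$bio_rep)
    if (!all(ok)) {
      stop("reference gene '", reference_gene,
           "' missing from some (condition, bio_rep) cells")
    }
  }
  attr(d, "reference_gene") <- reference_gene
  class(d) <- c("cq_table", "data.frame")
  d
}

#' Write a Cq table as CSV
#' @param cq A `cq_table`.
#' @param path Output path.
#' @param header_comment Optional `#`-prefixed comment line(s) for provenance.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(as.data.frame(cq), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
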