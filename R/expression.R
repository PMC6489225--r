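#' Relative expression of one gene by the delta-delta-Ct method
#'
#' Technical replicates of each (gene, condition, biological replicate) cell
#' are averaged first; biological replicates are the unit of inference.
#' Per cell, `dCt = Cq(gene) - Cq(reference)`; per treated biological
#' replicate, `ddCt = dCt(treated) - mean(dCt(control))`; relative expression
#' is `2^(-ddCt)` with the control condition at 1. Adding a constant to every
#' Cq value leaves all folds unchanged, and the reference gene itself always
#' yields fold 1 exactly.
#'
#' @param cq A `cq_table` (see [read_cq_table()]).
#' @param gene Gene to quantify.
#' @param reference Reference (housekeeping) gene; defaults to the table's
#'   `reference_gene` attribute.
#' @return List of class `ddct_result`: `gene`, `fold_per_bio` (one fold per
#'   treated biological replicate), `fold` (their mean), `log2_fold`
#'   (`log2(fold)`), `control_dct` and `treated_dct` (per biological
#'   replicate), `n_bio`, and per-condition `dct_sd` (standard deviation of
#'   the technical-replicate Cq differences, the error-bar scale).
#' @export
delta_delta_ct <- function(cq, gene, reference = attr(cq, "reference_gene")) {
  if (is.null(reference)) stop("no reference gene given or stored on the table")
  d <- as.data.frame(cq)
  if (!gene %in% d$gene) stop("gene not in Cq table: ", gene)
  if (!reference %in% d$gene) stop("reference gene not in Cq table: ", reference)
  cell_mean <- function(g, cond) {
    x <- d[d$gene == g & d$condition == cond, , drop = FALSE]
    if (nrow(x) == 0) return(NULL)
    tapply(x$cq, x$bio_rep, mean)
  }
  dct_for <- function(cond) {
    g <- cell_mean(gene, cond); r <- cell_mean(reference, cond)
    if (is.null(g) || is.null(r)) {
      stop("gene ", gene, " or reference missing in condition '", cond, "'")
    }
    common <- intersect(names(g), names(r))
    if (length(common) < length(g)) {
      stop("reference gene missing for some biological replicate of '", cond, "'")
    }
    as.numeric(g[common] - r[common])
  }
  control_dct <- dct_for("control")
  treated_dct <- dct_for("treated")
  ddct <- treated_dct - mean(control_dct)
  fold_per_bio <- 2^(-ddct)
  fold <- mean(fold_per_bio)
  n_bio <- length(treated_dct)
  if (n_bio < 2) {
    warning("fewer than 2 biological replicates; significance testing disabled",
            call. = FALSE)
  }
  tech_sd <- function(cond) {
    x <- d[d$gene == gene & d$condition == cond, , drop = FALSE]
    mean(tapply(x$cq, x$bio_rep, stats::sd), na.rm = TRUE)
  }
  structure(list(gene = gene, fold_per_bio = unname(fold_per_bio),
                 fold = fold, log2_fold = log2(fold),
                 control_dct = unname(control_dct),
                 treated_dct = unname(treated_dct), n_bio = n_bio,
                 dct_sd = c(control = unname(tech_sd("control")),
                            treated = unname(tech_sd("treated")))),
            class = "ddct_result")
}

#' Two-sample Student's t-test on delta-Ct values
#'
#' Two-sided test of treated vs control dCt values across biological
#' replicates, with pooled variance by default (classic Student; set
#' `welch = TRUE` for the Welch form). Significance stars follow the usual
#' qPCR convention: `*` for p < 0.05, `**` for p < 0.01. Degenerate inputs
#' with zero variance in both groups give p = 1 when the means are equal and
#' p = 0 (flagged `degenerate`) when they differ.
#'
#' @param control_dcts,treated_dcts Numeric vectors, length >= 2 each.
#' @param welch Use the Welch (unequal-variance) test instead of the
#'   pooled-variance test.
#' @return List with `p_value`, `stars`, `t`, `df`, `degenerate`.
#' @export
test_differential <- function(control_dcts, treated_dcts, welch = FALSE) {
  stopifnot(length(control_dcts) >= 2, length(treated_dcts) >= 2)
  degenerate <- FALSE
  if (stats::sd(control_dcts) == 0 && stats::sd(treated_dcts) == 0) {
    if (mean(control_dcts) == mean(treated_dcts)) {
      res <- list(p_value = 1, t = 0,
                  df = length(control_dcts) + length(treated_dcts) - 2)
    } else {
      res <- list(p_value = 0, t = Inf,
                  df = length(control_dcts) + length(treated_dcts) - 2)
      degenerate <- TRUE
    }
  } else {
    tt <- stats::t.test(treated_dcts, control_dcts, var.equal = !welch)
    res <- list(p_value = unname(tt$p.value), t = unname(tt$statistic),
                df = unname(tt$parameter))
  }
  stars <- if (res$p_value < 0.01) "**" else if (res$p_value < 0.05) "*" else ""
  c(res, list(stars = stars, degenerate = degenerate))
}

#' Quantify and test every gene in a Cq table
#'
#' Runs [delta_delta_ct()] and [test_differential()] for each non-reference
#' gene and assembles a per-gene results table.
#'
#' @inheritParams delta_delta_ct
#' @param genes Genes to analyze; defaults to all non-reference genes.
#' @param welch Passed to [test_differential()].
#' @param adjust_method Optional multiple-testing correction reported in an
#'   extra `p_adj` column (e.g. `"BH"`); `"none"` (default) matches per-gene
#'   starring without correction.
#' @return Data frame of class `expression_results` with columns `gene`,
#'   `fold`, `log2_fold`, `p_value`, `stars`, `n_bio` (and `p_adj` when
#'   adjustment is requested).
#' @export
analyze_expression <- function(cq, reference = attr(cq, "reference_gene"),
                               genes = NULL, welch = FALSE,
                               adjust_method = "none") {
  d <- as.data.frame(cq)
  if (is.null(genes)) genes <- setdiff(unique(d$gene), reference)
  rows <- lapply(genes, function(g) {
    r <- delta_delta_ct(cq, g, reference)
    if (r$n_bio >= 2 && length(r$control_dct) >= 2) {
      tt <- test_differential(r$control_dct, r$treated_dct)
      p <- tt$p_value; stars <- tt$stars
    } else {
      p <- NA_real_; stars <- ""
    }
    data.frame(gene = g, fold = r$fold, log2_fold = r$log2_fold, p_value = p,
               stars = stars, n_bio = r$n_bio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!identical(adjust_method, "none")) {
    out$p_adj <- stats::p.adjust(out$p_value, method = adjust_method)
  }
  class(out) <- c("expression_results", "data.frame")
  out
}

#' Call stress-responsive genes from expression results
#'
#' A gene is called `up` when its fold change is at least `up_fold`
#' (inclusive: "at least two-fold induced") and, when
#' `require_significance`, its p-value is below `alpha`. It is called `down`
#' (strong suppression) when its fold change is at most `1/strong_down_fold`
#' (more than `strong_down_fold`-fold suppressed); the suppression call is a
#' pure fold threshold. All other genes are `none`.
#'
#' @param results An `expression_results` data frame (see
#'   [analyze_expression()]).
#' @param up_fold Induction threshold (default 2).
#' @param strong_down_fold Suppression threshold (default 3; call at fold
#'   <= 1/3).
#' @param require_significance Gate up-calls on `p_value < alpha`.
#' @param alpha Significance level for the gate (default 0.05).
#' @param assignments Optional classification table (columns `protein`,
#'   `pub_class`) used to tabulate calls per PUB class.
#' @return List of class `stress_calls`: `calls` (the results table with a
#'   `call` column) and `summary` (counts of up/down/none, per class when
#'   `assignments` is given).
#' @export
call_stress_response <- function(results, up_fold = 2.0, strong_down_fold = 3.0,
                                 require_significance = TRUE, alpha = 0.05,
                                 assignments = NULL) {
  stopifnot(nrow(results) >= 1)
  sig <- if (require_significance) {
    !is.na(results$p_value) & results$p_value < alpha
  } else rep(TRUE, nrow(results))
  call <- rep("none", nrow(results))
  call[results$fold >= up_fold & sig] <- "up"
  call[results$fold <= 1 / strong_down_fold] <- "down"
  out <- results
  out$call <- call
  if (!is.null(assignments)) {
    cls <- assignments$pub_class[match(out$gene, assignments$protein)]
    out$pub_class <- cls
    summary <- as.data.frame(table(pub_class = cls, call = call),
                             stringsAsFactors = FALSE)
  } else {
    summary <- as.data.frame(table(call = call), stringsAsFactors = FALSE)
  }
  structure(list(calls = out, summary = summary), class = "stress_calls")
}
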