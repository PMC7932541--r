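## Rank GO Biological Process terms by enrichment of SRE/NF-Y-positive
## genes.  The headline statistic is the cross-product odds ratio on the
## table [[positives_in, positives_out], [total_in, total_out]] — i.e. the
## ratio of positive-gene proportions in and out of the term — with the
## exact-conditional confidence interval and two-sided Fisher p computed on
## the same table.  The conventional positive/negative odds ratio is also
## reported in its own column.

#' Read gene -> GO annotations
#'
#' Two-column TSV `gene_id`, `go_id` (header optional); an optional third
#' column restricts rows to the Biological Process aspect (`P`,
#' `biological_process`, or `BP`).  Term names can come from a second
#' two-column TSV `go_id`, `name`.
#'
#' @param path annotation TSV.
#' @param names_path optional term-name TSV.
#' @return list of class `go_annotations`: `gene2terms` (named list of
#'   character vectors), `term2genes` (inverse), `term_names` (named
#'   character).
#' @export
read_go_annotations <- function(path, names_path = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#")
  if (nrow(tab) > 0L &&
      grepl("gene", tab[1, 1], ignore.case = TRUE)) tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2L) stop("annotation file needs columns gene_id, go_id: ", path)
  if (ncol(tab) >= 3L) {
    bp <- tab[[3]] %in% c("P", "BP", "biological_process")
    tab <- tab[bp, , drop = FALSE]
  }
  term_names <- character(0)
  if (!is.null(names_path)) {
    nm <- read.table(names_path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, quote = "", comment.char = "#")
    term_names <- setNames(as.character(nm[[2]]), as.character(nm[[1]]))
  }
  go_annotations(setNames(as.character(tab[[2]]), as.character(tab[[1]])),
                 term_names)
}

#' Build a `go_annotations` object from a gene/term pairing
#'
#' @param pairs named character vector: names are gene ids, values GO term
#'   ids (one pair per element).
#' @param term_names optional named character vector of term names.
#' @return list of class `go_annotations`.
#' @export
go_annotations <- function(pairs, term_names = character(0)) {
  genes <- names(pairs)
  gene2terms <- lapply(split(unname(pairs), genes), unique)
  term2genes <- lapply(split(genes, unname(pairs)), unique)
  structure(list(gene2terms = gene2terms, term2genes = term2genes,
                 term_names = term_names),
            class = "go_annotations")
}

#' Build the gene universe with binary positivity
#'
#' The universe is the set of genes that have at least one Biological
#' Process annotation AND a scanned promoter; each universe gene is flagged
#' positive or negative from the promoter call.  Every enrichment row
#' partitions this same universe.
#'
#' @param gene_calls data.frame with `gene_id` and logical `call`
#'   (from [scan_promoters()]).
#' @param annotations a `go_annotations` object.
#' @return data.frame `gene_id`, `positive`.
#' @export
build_universe <- function(gene_calls, annotations) {
  stopifnot(is.data.frame(gene_calls),
            all(c("gene_id", "call") %in% names(gene_calls)))
  keep <- gene_calls$gene_id %in% names(annotations$gene2terms)
  if (!any(keep)) stop("no scanned gene has a GO Biological Process annotation")
  data.frame(gene_id = gene_calls$gene_id[keep],
             positive = as.logical(gene_calls$call[keep]),
             stringsAsFactors = FALSE)
}

#' 2x2 counts of a term against the universe
#'
#' @param term_genes character vector of the term's gene ids.
#' @param universe data.frame from [build_universe()].
#' @return list `pos_in`, `n_in`, `pos_out`, `n_out`
#'   (`n_in + n_out == nrow(universe)`).
#' @export
contingency_counts <- function(term_genes, universe) {
  inside <- universe$gene_id %in% term_genes
  if (!any(inside)) stop("term has no gene in the universe")
  list(pos_in = sum(universe$positive[inside]), n_in = sum(inside),
       pos_out = sum(universe$positive[!inside]), n_out = sum(!inside))
}

#' Enrichment odds ratio, confidence interval and Fisher p-value
#'
#' The statistic lives on the totals table
#' `[[pos_in, pos_out], [n_in, n_out]]`.  The reported `odds_ratio` is the
#' exact-conditional maximum-likelihood estimate from the Fisher test on
#' that table (what epidemiology-style odds-ratio functions report), with
#' its 95% exact-conditional confidence interval and two-sided exact
#' p-value.  `sample_odds_ratio` is the plain cross-product
#' `(pos_in * n_out) / (pos_out * n_in)` — numerically the ratio of the
#' in-group and out-group positive proportions; for counts of this shape
#' the two estimates agree to two decimals.  A zero cell gets a 0.5
#' continuity correction in the cross-product and is flagged.
#'
#' @param pos_in,n_in positive and total gene counts inside the term.
#' @param pos_out,n_out the same outside the term.
#' @param conf_level confidence level (0.95).
#' @return list `odds_ratio`, `sample_odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `corrected`.
#' @export
enrichment_statistic <- function(pos_in, n_in, pos_out, n_out,
                                 conf_level = 0.95) {
  stopifnot(pos_in >= 0, pos_out >= 0, n_in > 0, n_out > 0,
            pos_in <= n_in, pos_out <= n_out)
  tab <- matrix(c(pos_in, n_in, pos_out, n_out), nrow = 2)
  corrected <- any(tab == 0)
  est_tab <- if (corrected) tab + 0.5 else tab
  or <- (est_tab[1, 1] * est_tab[2, 2]) / (est_tab[1, 2] * est_tab[2, 1])
  ft <- fisher.test(tab, conf.level = conf_level)
  list(odds_ratio = unname(ft$estimate), sample_odds_ratio = or,
       ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
       p_value = ft$p.value, corrected = corrected)
}

conventional_or <- function(pos_in, n_in, pos_out, n_out) {
  tab <- matrix(c(pos_in, n_in - pos_in, pos_out, n_out - pos_out), nrow = 2)
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Rank all BP terms by enrichment
#'
#' One row per term with at least `min_term_size` universe genes, sorted by
#' descending odds ratio; ties broken by smaller p-value, then term id.  No
#' multiple-testing correction is applied by default (set `adjust = "BH"`
#' for Benjamini-Hochberg in an extra column).
#'
#' @param universe data.frame from [build_universe()].
#' @param annotations a `go_annotations` object.
#' @param min_term_size minimum universe genes per term (default 10).
#' @param adjust `"none"` or `"BH"`.
#' @return data.frame with `go_id`, `go_name`, `odds_ratio`,
#'   `sample_odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `pos_in`, `n_in`, `pos_out`, `n_out`,
#'   `in_ratio`, `out_ratio`, `conventional_or` (and `p_adjust` if
#'   requested).
#' @export
enrich_all <- function(universe, annotations, min_term_size = 10L,
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (term in names(annotations$term2genes)) {
    genes <- annotations$term2genes[[term]]
    n_in <- sum(universe$gene_id %in% genes)
    if (n_in < min_term_size || n_in == nrow(universe)) next
    ct <- contingency_counts(genes, universe)
    st <- enrichment_statistic(ct$pos_in, ct$n_in, ct$pos_out, ct$n_out)
    rows[[term]] <- data.frame(
      go_id = term,
      go_name = unname(annotations$term_names[term] %|NA|% term),
      odds_ratio = st$odds_ratio, sample_odds_ratio = st$sample_odds_ratio,
      ci_low = st$ci_low, ci_high = st$ci_high,
      p_value = st$p_value,
      pos_in = ct$pos_in, n_in = ct$n_in,
      pos_out = ct$pos_out, n_out = ct$n_out,
      in_ratio = ct$pos_in / ct$n_in, out_ratio = ct$pos_out / ct$n_out,
      conventional_or = conventional_or(ct$pos_in, ct$n_in, ct$pos_out,
                                        ct$n_out),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no term passes min_term_size = ", min_term_size)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$odds_ratio, out$p_value, out$go_id), , drop = FALSE]
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
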