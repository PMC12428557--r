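#' Read a GMT-style annotation file
#'
#' One term per line: term id, description, then member gene ids,
#' tab-separated.
#'
#' @param path GMT file.
#' @return Tibble with `term`, `description` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(term = vapply(parts, `[`, character(1), 1),
         description = vapply(parts, `[`, character(1), 2),
         genes = lapply(parts, function(p) unique(p[-(1:2)])))
}

#' Fisher's exact over-representation analysis
#'
#' For each term with gene set of size K in a universe of N genes, tests
#' whether the study set (size n, k hits in the term) is over-represented:
#' one-sided hypergeometric upper-tail p for observing >= k hits,
#' Benjamini-Hochberg FDR across tested terms, and fold enrichment
#' (k/n)/(K/N). Results are sorted by decreasing fold enrichment.
#'
#' @param study Character vector of study gene ids. Genes outside the
#'   universe are dropped with a warning.
#' @param annotation Tibble from [read_gmt()] (or with `term` and `genes`
#'   columns).
#' @param universe Background gene ids; defaults to the union of all genes
#'   in the annotation.
#' @return An `ora_result` tibble: `term`, `description`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p`, `fdr`.
#' @export
fisher_ora <- function(study, annotation, universe = NULL) {
  if (length(study) == 0) abort("empty study gene set")
  if (is.null(universe)) universe <- unique(unlist(annotation$genes))
  study <- unique(study)
  outside <- setdiff(study, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d study gene(s) outside the universe dropped: %s",
                 length(outside),
                 paste(utils::head(outside, 5), collapse = ", ")))
    study <- intersect(study, universe)
  }
  if (length(study) == 0) abort("no study genes left inside the universe")
  N <- length(universe)
  n <- length(study)
  res <- lapply(seq_len(nrow(annotation)), function(i) {
    genes <- intersect(annotation$genes[[i]], universe)
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(study, genes))
    tibble(term = annotation$term[i],
           description = if ("description" %in% names(annotation))
             annotation$description[i] else NA_character_,
           k = k, n = n, K = K, N = N,
           fold_enrichment = (k / n) / (K / N),
           p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- bind_rows(res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- arrange(out, dplyr::desc(.data$fold_enrichment), .data$p)
  class(out) <- c("ora_result", class(out))
  out
}

#' @export
glance.ora_result <- function(x, alpha = 0.05, ...) {
  tibble(n_terms = nrow(x), n_sig_fdr = sum(x$fdr <= alpha),
         study_size = if (nrow(x)) x$n[1] else NA_integer_,
         universe_size = if (nrow(x)) x$N[1] else NA_integer_)
}

#' Plot over-representation results
#'
#' @param object An `ora_result`.
#' @param top Number of terms to show (by fold enrichment).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ora_result <- function(object, top = 15, ...) {
  d <- utils::head(object, top)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fold_enrichment, y = .data$term,
                                  size = .data$k,
                                  colour = -log10(.data$fdr))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "# genes",
                  colour = "-log10 FDR") +
    ggplot2::theme_minimal()
}
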