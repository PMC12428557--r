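fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- as.character(seqs[[nm]])
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

write_gtf <- function(events, cds, path) {
  lines <- character(0)
  add <- function(chrom, src, type, start0, end, strand, frame, attrs) {
    c(lines, paste(chrom, src, type, start0 + 1, end, ".", strand,
                   frame, attrs, sep = "\t"))
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     ev$gene_id, ev$gene_id)
    exons <- switch(ev$event_class,
      SE = list(c(ev$upstream_start, ev$upstream_end),
                c(ev$exon_start, ev$exon_end),
                c(ev$downstream_start, ev$downstream_end)),
      MXE = list(c(ev$upstream_start, ev$upstream_end),
                 c(ev$exon_start, ev$exon_end),
                 c(ev$exon2_start, ev$exon2_end),
                 c(ev$downstream_start, ev$downstream_end)),
      RI = list(c(ev$upstream_start, ev$upstream_end),
                c(ev$downstream_start, ev$downstream_end)),
      list(c(ev$exon_start, ev$exon_end),
           c(ev$flanking_start, ev$flanking_end)))
    for (ex in exons) {
      lines <- add(ev$chrom, "splicedown_sim", "exon", ex[1], ex[2],
                   ev$strand, ".", attrs)
    }
  }
  if (!is.null(cds)) {
    for (i in seq_len(nrow(cds))) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                       sub("\\.t1$", "", cds$transcript_id[i]),
                       cds$transcript_id[i])
      lines <- add(cds$chrom[i], "splicedown_sim", "CDS", cds$start[i],
                   cds$end[i], cds$strand[i], cds$phase[i], attrs)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

join_counts <- function(lst) {
  vapply(lst, paste, character(1), collapse = ",")
}

write_rmats_table <- function(events, cls, path) {
  ev <- events[events$event_class == cls, , drop = FALSE]
  cmap <- rmats_coord_map[[cls]]
  out <- data.frame(ID = sub("^[A-Z35]+_", "", ev$event_id),
                    GeneID = ev$gene_id, geneSymbol = ev$gene_symbol,
                    chr = ev$chrom, strand = ev$strand,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in names(cmap)) {
    # write canonical rMATS headers ("1stExonStart_0base", not the
    # R-mangled names used on read)
    out[[sub("^X", "", cmap[[nm]])]] <- ev[[nm]]
  }
  out[["IJC_SAMPLE_1"]] <- join_counts(ev$inc_counts_trt)
  out[["SJC_SAMPLE_1"]] <- join_counts(ev$skip_counts_trt)
  out[["IJC_SAMPLE_2"]] <- join_counts(ev$inc_counts_ctl)
  out[["SJC_SAMPLE_2"]] <- join_counts(ev$skip_counts_ctl)
  out[["IncFormLen"]] <- ev$inc_len
  out[["SkipFormLen"]] <- ev$skip_len
  out[["PValue"]] <- fmt_num(ev$pvalue)
  out[["FDR"]] <- fmt_num(ev$fdr)
  out[["IncLevel1"]] <- vapply(ev$psi_trt, function(x) {
    if (is.null(x)) "NA" else paste(fmt_num(x, 4), collapse = ",")
  }, character(1))
  out[["IncLevel2"]] <- vapply(ev$psi_ctl, function(x) {
    if (is.null(x)) "NA" else paste(fmt_num(x, 4), collapse = ",")
  }, character(1))
  out[["IncLevelDifference"]] <- fmt_num(ev$delta_psi, 4)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, per-class `<CLASS>.MATS.JC.txt`
#' tables, `mirna.fa`, `mirna_expression.tsv`, `motifs.tsv`,
#' `ppi_edges.tsv`, `ppi_nodes.tsv`, `degs.tsv`, `annotation.gmt` and
#' `truth.json`. Deterministic: the same bundle writes byte-identical files.
#'
#' @param bundle A `synthetic_bundle` from [simulate_dataset()].
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(as.list(as.character(bundle$genome)), p("genome.fa"))
  write_gtf(bundle$events, bundle$cds, p("annotation.gtf"))
  for (cls in unique(bundle$events$event_class)) {
    write_rmats_table(bundle$events, cls, p(paste0(cls, ".MATS.JC.txt")))
  }
  write_fasta(setNames(as.list(bundle$mirnas$sequence), bundle$mirnas$mirna_id),
              p("mirna.fa"))
  utils::write.table(bundle$expression, p("mirna_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  motif_rows <- tidyr::unnest(
    tibble(rbp = bundle$motifs$rbp, pattern = bundle$motifs$patterns),
    "pattern")
  utils::write.table(motif_rows, p("motifs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$network_edges, p("ppi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$network_nodes, p("ppi_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$degs, p("degs.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gmt <- vapply(seq_len(nrow(bundle$annotation_map)), function(i) {
    paste(c(bundle$annotation_map$term[i],
            bundle$annotation_map$description[i],
            bundle$annotation_map$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, p("annotation.gmt"))
  truth <- bundle$truth
  writeLines(jsonlite::toJSON(truth, dataframe = "rows", digits = 10,
                              pretty = TRUE), p("truth.json"))
  invisible(out_dir)
}

#' Load a dataset bundle from a directory
#'
#' Reads the files written by [write_bundle()] (or equivalently formatted
#' user data) back into the in-memory bundle consumed by
#' [run_splicing_pipeline()]. Missing optional files yield `NULL` slots.
#'
#' @param dir Directory of input files.
#' @return A bundle list.
#' @export
load_bundle_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- function(f) {
    if (!file.exists(p(f))) abort(sprintf("missing input file: %s", p(f)))
    p(f)
  }
  opt_tsv <- function(f) {
    if (file.exists(p(f))) {
      as_tibble(utils::read.delim(p(f), stringsAsFactors = FALSE))
    } else NULL
  }
  motifs <- NULL
  if (file.exists(p("motifs.tsv"))) motifs <- read_motifs(p("motifs.tsv"))
  expr <- opt_tsv("mirna_expression.tsv")
  bundle <- list(
    genome = read_genome(need("genome.fa")),
    events = read_rmats_dir(dir),
    cds = if (file.exists(p("annotation.gtf")))
      tryCatch(read_cds_gtf(p("annotation.gtf")), error = function(e) NULL)
    else NULL,
    mirnas = if (file.exists(p("mirna.fa"))) read_mirna_fasta(p("mirna.fa"))
    else NULL,
    expression = expr,
    motifs = motifs,
    network_nodes = opt_tsv("ppi_nodes.tsv"),
    network_edges = opt_tsv("ppi_edges.tsv"),
    degs = opt_tsv("degs.tsv"),
    annotation_map = if (file.exists(p("annotation.gmt")))
      read_gmt(p("annotation.gmt")) else NULL,
    truth = if (file.exists(p("truth.json")))
      jsonlite::fromJSON(p("truth.json")) else NULL,
    config = NULL)
  bundle
}

write_stamped_tsv <- function(x, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance, con)
  listcols <- vapply(x, is.list, logical(1))
  x <- x[, !listcols, drop = FALSE]
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
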