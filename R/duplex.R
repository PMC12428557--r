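PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
WC_TYPES <- c("AU", "UA", "CG", "GC")

flip_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))

#' Read a duplex energy model from a parameter file
#'
#' The plain-text table carries nearest-neighbour helix stacks (one entry per
#' symmetry class, expanded on load), bulge and interior-loop initiation
#' penalties by size, the interior asymmetry term, the duplex initiation
#' penalty and the loop-size caps.
#'
#' @param path Parameter TSV; defaults to the table shipped with the package.
#' @return An energy model list consumed by [duplex_mfe()].
#' @export
read_energy_model <- function(path = system.file("extdata", "rna_duplex_params.tsv",
                                                 package = "splicedown")) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  get1 <- function(section, key) {
    as.numeric(tab$value[tab$section == section & tab$key == key])
  }
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  st <- tab[tab$section == "stack", ]
  for (i in seq_len(nrow(st))) {
    kk <- strsplit(st$key[i], "|", fixed = TRUE)[[1]]
    v <- as.numeric(st$value[i])
    stack[kk[1], kk[2]] <- v
    stack[flip_pair(kk[2]), flip_pair(kk[1])] <- v
  }
  if (anyNA(stack)) abort("incomplete stack table in energy parameter file")
  bu <- tab[tab$section == "bulge", ]
  bulge <- as.numeric(bu$value)[order(as.integer(bu$key))]
  io <- tab[tab$section == "interior", ]
  interior <- as.numeric(io$value)[order(as.integer(io$key))]
  model <- list(
    stack = stack,
    bulge = bulge,
    interior = interior,
    interior_asym = get1("asym", "coef"),
    interior_asym_max = get1("asym", "max"),
    duplex_init = get1("init", "duplex"),
    max_bulge = as.integer(get1("cap", "bulge")),
    max_interior = as.integer(get1("cap", "interior"))
  )
  stopifnot(all(model$bulge >= 0), all(model$interior >= 0),
            model$max_bulge >= 1, model$max_interior >= 1)
  class(model) <- "energy_model"
  model
}

model_cache <- new.env(parent = emptyenv())

#' Default duplex energy model
#'
#' @return The packaged nearest-neighbour model (cached after first read).
#' @export
default_energy_model <- function() {
  if (is.null(model_cache$default)) model_cache$default <- read_energy_model()
  model_cache$default
}

rna_codes <- function(x) {
  x <- chartr("tT", "uU", x)
  v <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "U")) - 1L
  v[is.na(v)] <- -1L  # N and friends: unpairable
  v
}

pair_type_chr <- function(a, b) {
  p <- paste0(a, b)
  ifelse(p %in% PAIR_TYPES, p, NA_character_)
}

#' Minimum-free-energy miRNA-target duplex
#'
#' Intermolecular-only duplex dynamic programming: the miRNA (5'->3') is
#' hybridised antiparallel against the target with helix stacks, single-strand
#' bulges and interior loops bounded by the model's size caps; G-U wobbles are
#' allowed in helices. Returns the global-minimum-energy alignment. A target
#' shorter than `min_target_len`, or a best energy >= 0, yields a no-hit
#' result with `mfe = 0` and an empty pairing.
#'
#' @param mirna miRNA sequence, 5'->3' RNA (DNA accepted, T read as U).
#' @param target Target sequence in transcript orientation (DNA or RNA).
#' @param model Energy model (see [default_energy_model()]).
#' @param mirna_id,event_id Optional identifiers carried into the result.
#' @param min_target_len Minimum target length for a scan (default 8).
#' @return A `duplex_hit` object: `mfe` (kcal/mol), `pairing` tibble
#'   (`mi_pos`, `tg_pos`, `type`), `pairing_map` (per miRNA position one of
#'   `"WC"`, `"wobble"`, `"unpaired"`), `target_window` (1-based paired span).
#' @export
duplex_mfe <- function(mirna, target, model = default_energy_model(),
                       mirna_id = NA_character_, event_id = NA_character_,
                       min_target_len = 8) {
  mi <- rna_codes(mirna)
  tg <- rna_codes(target)
  if (length(tg) < min_target_len) {
    res <- list(mfe = 0, mi_pos = integer(0), tg_pos = integer(0))
  } else {
    res <- .duplex_dp(mi, tg, unclass(model))
  }
  mi_chr <- strsplit(chartr("tT", "uU", toupper(mirna)), "")[[1]]
  tg_chr <- strsplit(chartr("tT", "uU", toupper(target)), "")[[1]]
  type <- pair_type_chr(mi_chr[res$mi_pos], tg_chr[res$tg_pos])
  map <- rep("unpaired", length(mi_chr))
  map[res$mi_pos] <- if_else(type %in% WC_TYPES, "WC", "wobble")
  hit <- list(
    mirna_id = mirna_id, event_id = event_id,
    mirna = paste(mi_chr, collapse = ""), target = paste(tg_chr, collapse = ""),
    mfe = res$mfe,
    pairing = tibble(mi_pos = as.integer(res$mi_pos),
                     tg_pos = as.integer(res$tg_pos), type = type),
    pairing_map = map,
    target_window = if (length(res$tg_pos)) range(res$tg_pos) else c(NA_integer_, NA_integer_)
  )
  class(hit) <- "duplex_hit"
  hit
}

#' Recompute a duplex energy from its pairing
#'
#' Sums the initiation, stack and loop terms over a reported pairing; used
#' to assert self-consistency of [duplex_mfe()] results.
#'
#' @param hit A `duplex_hit`.
#' @param model Energy model.
#' @return Energy in kcal/mol (0 for an empty pairing).
#' @export
duplex_energy <- function(hit, model = default_energy_model()) {
  pr <- hit$pairing
  if (nrow(pr) == 0) return(0)
  e <- model$duplex_init
  for (k in seq_len(nrow(pr))[-1]) {
    g1 <- pr$mi_pos[k] - pr$mi_pos[k - 1] - 1
    g2 <- pr$tg_pos[k - 1] - pr$tg_pos[k] - 1
    if (g1 == 0 && g2 == 0) {
      e <- e + model$stack[pr$type[k - 1], pr$type[k]]
    } else if (g1 == 0 || g2 == 0) {
      e <- e + model$bulge[max(g1, g2)]
    } else {
      e <- e + model$interior[g1 + g2 - 1] +
        min(model$interior_asym_max, model$interior_asym * abs(g1 - g2))
    }
  }
  e
}

#' @export
print.duplex_hit <- function(x, ...) {
  cat(sprintf("<duplex_hit> %s vs %s  mfe = %.2f kcal/mol, %d pairs\n",
              x$mirna_id %||% "miRNA", x$event_id %||% "target",
              x$mfe, nrow(x$pairing)))
  invisible(x)
}

#' @export
tidy.duplex_hit <- function(x, ...) {
  tibble(mi_pos = seq_along(x$pairing_map),
         mi_base = strsplit(x$mirna, "")[[1]],
         status = x$pairing_map,
         tg_pos = x$pairing$tg_pos[match(seq_along(x$pairing_map), x$pairing$mi_pos)])
}

#' @export
glance.duplex_hit <- function(x, ...) {
  tibble(mirna_id = x$mirna_id, event_id = x$event_id, mfe = x$mfe,
         n_pairs = nrow(x$pairing),
         seed_class = classify_seed(x),
         target_start = x$target_window[1], target_end = x$target_window[2])
}

#' Filter hybridizations on minimum free energy
#'
#' @param hits Hybridization tibble with an `mfe` column.
#' @param threshold Retain rows with `mfe <= threshold` (default -30
#'   kcal/mol, boundary inclusive).
#' @return Filtered tibble.
#' @export
filter_by_mfe <- function(hits, threshold = -30) {
  hits[!is.na(hits$mfe) & hits$mfe <= threshold, , drop = FALSE]
}

#' Classify a duplex into seed-pairing site classes
#'
#' Seed = miRNA positions 2-7, post-seed = positions 13-16. `Strong`: all
#' seed and all post-seed positions Watson-Crick paired; `Canonical`: all
#' seed WC but not all post-seed; `Compensatory`: at least one seed position
#' not WC while all post-seed positions are WC; anything else is
#' `Unclassified` (excluded downstream). G-U wobbles count as non-WC here
#' even though the energy model pairs them.
#'
#' @param hit A `duplex_hit`, or a character pairing map (values `"WC"`,
#'   `"wobble"`, `"unpaired"` per miRNA position).
#' @return One of `"Strong"`, `"Canonical"`, `"Compensatory"`,
#'   `"Unclassified"`.
#' @export
classify_seed <- function(hit) {
  map <- if (inherits(hit, "duplex_hit")) hit$pairing_map else hit
  if (length(map) < 16) {
    warn("miRNA shorter than 16 nt cannot be seed-classified")
    return("Unclassified")
  }
  seed_wc <- all(map[2:7] == "WC")
  post_wc <- all(map[13:16] == "WC")
  if (seed_wc && post_wc) return("Strong")
  if (seed_wc) return("Canonical")
  if (post_wc) return("Compensatory")
  "Unclassified"
}

#' Annotate the A1 adenosine of a duplex
#'
#' TRUE iff the target nucleotide opposite miRNA position 1 - the base
#' immediately 3' (target orientation) of the base opposite position 2 - is
#' adenosine. Annotation only, never a filter. When the duplex sits at the
#' target boundary the result is `FALSE` with attribute `edge = TRUE`.
#'
#' @param hit A `duplex_hit`.
#' @param target Target sequence (defaults to the one stored in the hit).
#' @return Logical scalar with attribute `edge`.
#' @export
annotate_a1 <- function(hit, target = hit$target) {
  tg_chr <- strsplit(chartr("tT", "uU", toupper(target)), "")[[1]]
  pr <- hit$pairing
  out <- FALSE
  edge <- FALSE
  if (nrow(pr) > 0) {
    p <- min(pr$mi_pos)
    jp <- pr$tg_pos[pr$mi_pos == p]
    j1 <- jp + (p - 1)  # antiparallel: position 1 faces the 3'-most target base
    if (j1 > length(tg_chr)) {
      edge <- TRUE
    } else {
      out <- tg_chr[j1] == "A"
    }
  }
  attr(out, "edge") <- edge
  out
}

#' Retain miRNAs in the high-expression range of a tissue
#'
#' The universe is the set of miRNAs with positive expression; the threshold
#' is the `q`-th percentile of their values (linear interpolation between
#' order statistics) and ids at or above it are retained.
#'
#' @param expr Tibble with `mirna_id` and `expression` columns.
#' @param q Percentile, default 85.
#' @return Character vector of retained miRNA ids.
#' @export
percentile_filter <- function(expr, q = 85) {
  uni <- expr[!is.na(expr$expression) & expr$expression > 0, , drop = FALSE]
  if (nrow(uni) == 0) {
    warn("no miRNA with positive expression; empty high-expression set")
    return(character(0))
  }
  thr <- unname(quantile(uni$expression, probs = q / 100, type = 7))
  uni$mirna_id[uni$expression >= thr]
}

#' Read a miRNA FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @return Tibble with `mirna_id` (first header word) and `sequence`
#'   (RNA, 5'->3').
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(mirna_id = sub("\\s.*$", "", names(x)),
         sequence = chartr("tT", "uU", toupper(as.character(x))))
}

#' miRNA-DASE hybridization cascade
#'
#' For every (miRNA, DASE-region) pair: predict the single best duplex, gate
#' on minimum free energy, classify seed pairing (dropping `Unclassified`),
#' then keep only miRNAs in the tissue high-expression range. Pairs whose
#' region is shorter than the miRNA are skipped. Per-stage pair counts are
#' attached as the `stage_counts` attribute (retrievable with `glance()`).
#'
#' @param dases Filtered event tibble (the DASEs of interest).
#' @param genome Genome object or named character vector.
#' @param mirnas Tibble with `mirna_id`, `sequence` (see [read_mirna_fasta()]).
#' @param expr Expression tibble for [percentile_filter()], or `NULL` to skip
#'   the expression stage.
#' @param model Energy model.
#' @param mfe_max mfe cutoff (default -30, inclusive).
#' @param expression_percentile Percentile for the expression stage.
#' @return Hybridization tibble: `event_class`, `gene_symbol`, `event_id`,
#'   `mirna_id`, `delta_psi`, `mfe`, `seed_class`, `a1`, `target_start`,
#'   `target_end`; class `hybridization_table`.
#' @export
predict_hybridizations <- function(dases, genome, mirnas, expr = NULL,
                                   model = default_energy_model(),
                                   mfe_max = -30, expression_percentile = 85) {
  regions <- dase_region(dases)
  seqs <- extract_region_seq(genome, regions)
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(dases))) {
    for (k in seq_len(nrow(mirnas))) {
      if (nchar(seqs[i]) < nchar(mirnas$sequence[k])) {
        n_skipped <- n_skipped + 1L
        next
      }
      hit <- duplex_mfe(mirnas$sequence[k], seqs[i], model,
                        mirna_id = mirnas$mirna_id[k],
                        event_id = dases$event_id[i])
      a1 <- annotate_a1(hit)
      rows[[length(rows) + 1L]] <- tibble(
        event_class = dases$event_class[i],
        gene_symbol = dases$gene_symbol[i],
        event_id = dases$event_id[i],
        mirna_id = mirnas$mirna_id[k],
        delta_psi = dases$delta_psi[i],
        mfe = hit$mfe,
        seed_class = classify_seed(hit),
        a1 = as.logical(a1),
        target_start = hit$target_window[1],
        target_end = hit$target_window[2]
      )
    }
  }
  all_hits <- if (length(rows)) bind_rows(rows) else tibble(
    event_class = character(), gene_symbol = character(),
    event_id = character(), mirna_id = character(), delta_psi = numeric(),
    mfe = numeric(), seed_class = character(), a1 = logical(),
    target_start = integer(), target_end = integer())
  stage1 <- filter_by_mfe(all_hits, mfe_max)
  stage2 <- stage1[stage1$seed_class != "Unclassified", , drop = FALSE]
  if (!is.null(expr)) {
    keep_ids <- percentile_filter(expr, expression_percentile)
    stage3 <- stage2[stage2$mirna_id %in% keep_ids, , drop = FALSE]
  } else {
    stage3 <- stage2
  }
  out <- arrange(stage3, .data$event_class, .data$gene_symbol, .data$mirna_id)
  attr(out, "stage_counts") <- c(
    scanned = nrow(all_hits), skipped_short = n_skipped,
    pass_mfe = nrow(stage1), classified = nrow(stage2),
    expressed = nrow(stage3))
  class(out) <- c("hybridization_table", class(out))
  out
}

#' @export
glance.hybridization_table <- function(x, ...) {
  sc <- attr(x, "stage_counts")
  tibble(scanned = sc[["scanned"]], pass_mfe = sc[["pass_mfe"]],
         classified = sc[["classified"]], expressed = sc[["expressed"]],
         n_mirnas = length(unique(x$mirna_id)),
         n_events = length(unique(x$event_id)))
}
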