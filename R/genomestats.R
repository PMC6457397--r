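#' Build an annotation set from a feature table
#'
#' The internal annotation container: a validated list of `genes`,
#' `transcripts` and `exons` tibbles, coordinates 1-based inclusive (GFF3
#' convention). Exons within a transcript must be non-overlapping; they are
#' stored sorted by start.
#'
#' @param features Tibble with columns `seqid`, `type`
#'   (`gene`/`mRNA`/`exon`, optionally `CDS`), `start`, `end`, `strand`,
#'   `id`, `parent`.
#' @return An object of class `annotation_set`.
#' @export
as_annotation_set <- function(features) {
  need <- c("seqid", "type", "start", "end", "strand", "id", "parent")
  if (!all(need %in% names(features))) {
    stop("feature table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  genes <- features[features$type == "gene", ]
  tx <- features[features$type %in% c("mRNA", "transcript"), ]
  exons <- features[features$type == "exon", ]
  cds <- features[features$type == "CDS", ]
  if (anyDuplicated(genes$id) || anyDuplicated(tx$id)) {
    stop("gene and transcript ids must be unique", call. = FALSE)
  }
  orphan <- setdiff(tx$parent, genes$id)
  if (length(orphan)) {
    stop("transcripts with unknown parent gene: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  exons <- exons |>
    dplyr::arrange(.data$parent, .data$start) |>
    dplyr::rename(transcript_id = "parent")
  bad <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(overlap = any(.data$start[-1] <=
                                     .data$end[-dplyr::n()] &
                                     dplyr::n() > 1)) |>
    dplyr::filter(.data$overlap)
  if (nrow(bad)) {
    stop("overlapping exons within transcript(s): ",
         paste(utils::head(bad$transcript_id, 5), collapse = ", "),
         call. = FALSE)
  }
  tx <- tx |> dplyr::rename(gene_id = "parent")
  structure(list(
    genes = tibble::as_tibble(genes[, c("seqid", "start", "end", "strand",
                                        "id")]),
    transcripts = tibble::as_tibble(tx[, c("seqid", "start", "end",
                                           "strand", "id", "gene_id")]),
    exons = tibble::as_tibble(exons[, c("seqid", "start", "end", "strand",
                                        "id", "transcript_id")]),
    cds = if (nrow(cds)) {
      tibble::as_tibble(
        dplyr::rename(cds, transcript_id = "parent")[
          , c("seqid", "start", "end", "strand", "id", "transcript_id")])
    } else {
      NULL
    }), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons on",
      length(unique(x$genes$seqid)), "scaffold(s)\n")
  invisible(x)
}

#' Read a GFF3 annotation
#'
#' Ingests `gene`/`mRNA`/`exon` (and `CDS`) features with `ID`/`Parent`
#' attributes into an [as_annotation_set()] container.
#'
#' @param file Path to a GFF3 file.
#' @return An `annotation_set`.
#' @export
read_annotation <- function(file) {
  g <- rtracklayer::readGFF(file,
                            filter = list(type = c("gene", "mRNA",
                                                   "transcript", "exon",
                                                   "CDS")))
  parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, "")
  feats <- tibble::tibble(
    seqid = as.character(g$seqid), type = as.character(g$type),
    start = as.integer(g$start), end = as.integer(g$end),
    strand = as.character(g$strand),
    id = ifelse(is.na(g$ID) & g$type == "exon",
                paste0(parent, ".e", seq_along(g$ID)), as.character(g$ID)),
    parent = parent)
  as_annotation_set(feats)
}

#' Write an annotation set as GFF3
#'
#' @param annotation An `annotation_set`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(annotation, file) {
  rows <- c("##gff-version 3")
  fmt <- function(df, type, attr) {
    sprintf("%s\tnemacomp\t%s\t%d\t%d\t.\t%s\t.\t%s",
            df$seqid, type, df$start, df$end, df$strand, attr)
  }
  g <- annotation$genes
  rows <- c(rows, fmt(g, "gene", paste0("ID=", g$id)))
  tx <- annotation$transcripts
  rows <- c(rows, fmt(tx, "mRNA", paste0("ID=", tx$id, ";Parent=",
                                         tx$gene_id)))
  ex <- annotation$exons
  rows <- c(rows, fmt(ex, "exon", paste0("ID=", ex$id, ";Parent=",
                                         ex$transcript_id)))
  writeLines(rows, file)
  invisible(file)
}

#' Select the longest isoform of every gene
#'
#' The transcript with the maximal summed exon length; ties break to the
#' lexicographically smallest transcript id, so the selection is stable
#' under input order.
#'
#' @param annotation An `annotation_set`.
#' @return Tibble `gene_id`, `transcript_id`, `exon_span`.
#' @export
longest_isoform <- function(annotation) {
  no_tx <- setdiff(annotation$genes$id, annotation$transcripts$gene_id)
  if (length(no_tx)) {
    stop("gene(s) without transcripts: ",
         paste(utils::head(no_tx, 5), collapse = ", "), call. = FALSE)
  }
  spans <- annotation$exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(exon_span = sum(.data$end - .data$start + 1L))
  annotation$transcripts |>
    dplyr::select(gene_id = "gene_id", transcript_id = "id") |>
    dplyr::left_join(spans, by = "transcript_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$exon_span), .data$transcript_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Per-gene structure statistics on the longest isoform
#'
#' `intron_count = exons - 1`; `intron_span` is the summed gap between
#' consecutive exons (`next_start - prev_end - 1`). When `utr = "exclude"`
#' and CDS features are annotated, CDS ranges replace exons (for data sets
#' where UTRs are annotated in only some species).
#'
#' @param annotation An `annotation_set`.
#' @param selection Output of [longest_isoform()]; computed if missing.
#' @param utr `"include"` (default; exon ranges as annotated) or
#'   `"exclude"` (use CDS ranges when present).
#' @return Tibble `gene_id`, `transcript_id`, `intron_count`, `intron_span`,
#'   `exon_span`, `extent` (genomic transcript extent).
#' @export
gene_structure_stats <- function(annotation,
                                 selection = longest_isoform(annotation),
                                 utr = c("include", "exclude")) {
  utr <- match.arg(utr)
  parts <- if (utr == "exclude" && !is.null(annotation$cds)) {
    annotation$cds
  } else {
    annotation$exons
  }
  parts <- parts[parts$transcript_id %in% selection$transcript_id, ]
  parts |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(
      intron_count = dplyr::n() - 1L,
      intron_span = if (dplyr::n() > 1) {
        sum(.data$start[-1] - .data$end[-dplyr::n()] - 1L)
      } else 0L,
      exon_span = sum(.data$end - .data$start + 1L),
      extent = max(.data$end) - min(.data$start) + 1L) |>
    dplyr::left_join(
      selection[, c("gene_id", "transcript_id")], by = "transcript_id") |>
    dplyr::select("gene_id", "transcript_id", "intron_count", "intron_span",
                  "exon_span", "extent")
}

#' Intergenic distances between adjacent genes
#'
#' Gene spans come from the selected (longest) isoform; genes are sorted by
#' start within each scaffold, strand ignored. The distance is
#' `next_start - prev_end - 1`, floored at 0 for overlapping genes;
#' scaffold-terminal flanks are excluded. The species mean is `NA` when no
#' adjacent pair exists.
#'
#' @inheritParams gene_structure_stats
#' @return A list: `pairs` (tibble `seqid`, `gene_a`, `gene_b`, `distance`)
#'   and `mean_distance`.
#' @export
intergenic_distances <- function(annotation,
                                 selection = longest_isoform(annotation)) {
  tx <- annotation$transcripts[
    annotation$transcripts$id %in% selection$transcript_id, ]
  spans <- tx |>
    dplyr::select(seqid = "seqid", gene_id = "gene_id", start = "start",
                  end = "end") |>
    dplyr::arrange(.data$seqid, .data$start, .data$gene_id)
  pairs <- spans |>
    dplyr::group_by(.data$seqid) |>
    dplyr::mutate(next_start = dplyr::lead(.data$start),
                  next_gene = dplyr::lead(.data$gene_id)) |>
    dplyr::filter(!is.na(.data$next_start)) |>
    dplyr::transmute(gene_a = .data$gene_id, gene_b = .data$next_gene,
                     distance = pmax(0L, .data$next_start -
                                       .data$end - 1L)) |>
    dplyr::ungroup()
  list(pairs = pairs,
       mean_distance = if (nrow(pairs)) mean(pairs$distance) else NA_real_)
}

#' Per-species gene-structure summary
#'
#' Means of intron count, intron span and exon span over all genes, plus
#' gene count and mean intergenic distance.
#'
#' @inheritParams gene_structure_stats
#' @return One-row tibble.
#' @export
species_structure_summary <- function(annotation,
                                      utr = c("include", "exclude")) {
  utr <- match.arg(utr)
  sel <- longest_isoform(annotation)
  gs <- gene_structure_stats(annotation, sel, utr = utr)
  ig <- intergenic_distances(annotation, sel)
  tibble::tibble(
    gene_count = nrow(gs),
    mean_intron_count = mean(gs$intron_count),
    mean_intron_span = mean(gs$intron_span),
    mean_exon_span = mean(gs$exon_span),
    mean_intergenic = ig$mean_distance)
}

#' Assembly span, scaffold count, N50 and N fraction
#'
#' N50 is the largest length L such that scaffolds of length >= L jointly
#' cover at least half the span (computed by descending sort and first
#' cumulative crossing of span/2). `n_fraction` is the percentage of bases
#' that are `N`/`n`.
#'
#' @param assembly A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return Tibble `span`, `scaffold_count`, `n50`, `n_fraction`.
#' @examples
#' sq <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTA",
#'                                  c = "ACGT", d = "ACG"))
#' assembly_metrics(sq) # N50 = 5
#' @export
assembly_metrics <- function(assembly) {
  if (is.character(assembly)) {
    assembly <- Biostrings::readDNAStringSet(assembly)
  }
  if (length(assembly) == 0L) stop("empty assembly", call. = FALSE)
  len <- sort(Biostrings::width(assembly), decreasing = TRUE)
  span <- sum(len)
  n50 <- len[which(cumsum(len) >= span / 2)[1]]
  freq <- Biostrings::alphabetFrequency(assembly, collapse = TRUE)
  n_bases <- sum(freq[c("N")])
  tibble::tibble(span = span, scaffold_count = length(len), n50 = n50,
                 n_fraction = 100 * n_bases / span)
}

#' Orthologue-pair log2 ratios of intron span and intron count
#'
#' For one-to-one orthologue pairs between species A and B, computes
#' `log2(span_A / span_B)` and `log2(count_A / count_B)` per pair — the
#' quantities histogrammed when comparing gene compaction between a small
#' and a reference genome. Pairs in which either side has value 0 for a
#' quantity yield `NA` for that ratio and are counted in the `dropped`
#' attribute.
#'
#' @param stats_a,stats_b [gene_structure_stats()] tibbles for the two
#'   species.
#' @param pairs Tibble `gene_a`, `gene_b` mapping genes of A to genes of B.
#' @return Tibble `gene_a`, `gene_b`, `log2_span_ratio`,
#'   `log2_count_ratio`, with attribute `dropped` (named counts).
#' @export
ortholog_log2_ratios <- function(stats_a, stats_b, pairs) {
  bad_a <- setdiff(pairs$gene_a, stats_a$gene_id)
  bad_b <- setdiff(pairs$gene_b, stats_b$gene_id)
  if (length(bad_a) || length(bad_b)) {
    stop("pairs reference unknown genes: ",
         paste(utils::head(c(bad_a, bad_b), 5), collapse = ", "),
         call. = FALSE)
  }
  a <- stats_a[match(pairs$gene_a, stats_a$gene_id), ]
  b <- stats_b[match(pairs$gene_b, stats_b$gene_id), ]
  span_ok <- a$intron_span > 0 & b$intron_span > 0
  count_ok <- a$intron_count > 0 & b$intron_count > 0
  out <- tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    # computed as a difference of logs so that swapping the species
    # negates every value exactly, not just to rounding
    log2_span_ratio = ifelse(span_ok,
                             log2(a$intron_span) - log2(b$intron_span),
                             NA_real_),
    log2_count_ratio = ifelse(count_ok,
                              log2(a$intron_count) - log2(b$intron_count),
                              NA_real_))
  attr(out, "dropped") <- c(span = sum(!span_ok), count = sum(!count_ok))
  out
}

#' Histogram of orthologue log2 ratios
#'
#' @param ratios Output of [ortholog_log2_ratios()].
#' @param quantity `"span"` or `"count"`.
#' @return A ggplot object.
#' @export
plot_log2_ratios <- function(ratios, quantity = c("span", "count")) {
  quantity <- match.arg(quantity)
  col <- paste0("log2_", quantity, "_ratio")
  ggplot2::ggplot(ratios[!is.na(ratios[[col]]), ],
                  ggplot2::aes(.data[[col]])) +
    ggplot2::geom_histogram(bins = 40, fill = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = bquote(log[2] ~ "ratio of intron" ~ .(quantity)),
                  y = "genes")
}
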