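#' Load gene models from a GTF annotation
#'
#' Reads CDS features from a GTF file and assembles per-gene transcript
#' models. GTF coordinates are 1-based inclusive; internally all exon
#' intervals are stored 0-based half-open, which removes off-by-one ambiguity
#' from downstream interval arithmetic. Overlapping CDS segments within a
#' transcript are merged so each transcript's exons are disjoint.
#'
#' Features without a usable gene symbol (`gene_name`, falling back to
#' `gene_id`) or without a `transcript_id` are skipped; the number skipped is
#' recorded in the `n_skipped` attribute of the result.
#'
#' @param path Path to a GTF file (tab-separated, 9 columns; `CDS` features
#'   are used, everything else is ignored).
#' @return A tibble of class `gene_models` with columns `gene`, `transcript`,
#'   `chrom`, `start`, `end` (0-based half-open), one row per coding exon.
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  n_data <- check_gtf_columns(path)
  if (n_data == 0L) {
    return(structure(normalize_exons(data.frame()),
                     class = c("gene_models", class(tibble::tibble())),
                     n_skipped = 0L))
  }
  gr <- suppressWarnings(rtracklayer::import(path, format = "gtf"))
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  gene <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else
    rep(NA_character_, length(gr))
  if ("gene_id" %in% names(mc)) {
    gene <- ifelse(is.na(gene) | gene == "", as.character(mc$gene_id), gene)
  }
  tx <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else
    rep(NA_character_, length(gr))
  gene <- trimws(gene)
  bad <- is.na(gene) | gene == "" | is.na(tx) | tx == ""
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    message(n_skipped, " CDS feature(s) lacked gene or transcript attributes; skipped")
  }
  gr <- gr[!bad]; gene <- gene[!bad]; tx <- tx[!bad]
  ex <- tibble::tibble(
    gene = gene,
    transcript = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  ex <- normalize_exons(ex)
  structure(ex, class = c("gene_models", class(tibble::tibble())),
            n_skipped = n_skipped)
}

# Reject malformed GTF early, naming the first offending line (rtracklayer's
# own errors do not carry line numbers).
check_gtf_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^(#|\\s*$)", lines))
  if (!length(data_idx)) return(0L)
  nf <- lengths(strsplit(lines[data_idx], "\t", fixed = TRUE))
  bad <- data_idx[nf < 8L]
  if (length(bad)) {
    stop("malformed GTF: line ", bad[1], " has fewer than 8 tab-separated fields")
  }
  length(data_idx)
}

# Merge overlapping CDS intervals within each transcript and sort.
normalize_exons <- function(ex) {
  if (!nrow(ex)) {
    return(tibble::tibble(gene = character(), transcript = character(),
                          chrom = character(), start = integer(), end = integer()))
  }
  stopifnot(all(ex$end > ex$start))
  key <- paste(ex$gene, ex$transcript, ex$chrom, sep = "\r")
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  red <- IRanges::reduce(S4Vectors::split(ir, factor(key, levels = unique(key))))
  n_per <- S4Vectors::elementNROWS(red)
  flat <- unlist(red, use.names = FALSE)
  parts <- strsplit(rep(names(red), n_per), "\r", fixed = TRUE)
  res <- tibble::tibble(
    gene = vapply(parts, `[[`, character(1), 1L),
    transcript = vapply(parts, `[[`, character(1), 2L),
    chrom = vapply(parts, `[[`, character(1), 3L),
    start = IRanges::start(flat) - 1L,
    end = IRanges::end(flat))
  dplyr::arrange(res, .data$gene, .data$transcript, .data$chrom, .data$start)
}

#' Coding length of each transcript
#'
#' @param models A `gene_models` tibble.
#' @return Tibble with `gene`, `transcript`, `coding_length`.
#' @export
transcript_lengths <- function(models) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(models), .data$gene, .data$transcript),
    coding_length = sum(.data$end - .data$start), .groups = "drop")
}

#' Representative (longest) transcript per gene
#'
#' Picks the transcript with the greatest coding length for each gene. Ties
#' are broken by the lexicographically smallest transcript id so footprints
#' are reproducible.
#'
#' @param models A `gene_models` tibble.
#' @param genes Optional character vector restricting the genes considered.
#' @return Tibble with one row per gene: `gene`, `transcript`,
#'   `coding_length`.
#' @export
longest_transcript <- function(models, genes = NULL) {
  tl <- transcript_lengths(models)
  if (!is.null(genes)) tl <- tl[tl$gene %in% genes, , drop = FALSE]
  tl <- dplyr::arrange(tl, .data$gene, dplyr::desc(.data$coding_length),
                       .data$transcript)
  dplyr::slice_head(dplyr::group_by(tl, .data$gene), n = 1L) |> dplyr::ungroup()
}

#' Define a gene panel
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols; whitespace is trimmed,
#'   duplicates are dropped with a warning, matching is case-sensitive.
#' @return A `panel_definition` list with `name` and `genes`.
#' @export
panel_definition <- function(name, genes) {
  genes <- trimws(as.character(genes))
  genes <- genes[genes != ""]
  if (!length(genes)) stop("panel '", name, "' has no genes")
  if (anyDuplicated(genes)) {
    warning("panel '", name, "': ", sum(duplicated(genes)),
            " duplicate gene symbol(s) dropped")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "panel_definition")
}

#' Read a panel gene list from a plain-text file
#'
#' One gene symbol per line; `#` starts a comment; blank lines are ignored.
#'
#' @param path File path.
#' @param name Panel name; defaults to the file name without extension.
#' @return A `panel_definition`.
#' @export
read_panel_genes <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  panel_definition(name, lines[trimws(lines) != ""])
}

new_footprint <- function(panel_name, selected, intervals, missing_genes,
                          n_genes = length(selected)) {
  total_bases <- sum(GenomicRanges::width(intervals))
  structure(list(
    panel_name = panel_name,
    selected_transcripts = selected,
    intervals = intervals,
    total_bases = as.double(total_bases),
    total_mb = total_bases / 1e6,
    missing_genes = missing_genes,
    n_genes = n_genes
  ), class = "panel_footprint")
}

#' Coding footprint of a gene panel
#'
#' For each panel gene present in the annotation, the coding exons of its
#' longest transcript are collected; intervals are merged per chromosome so
#' that bases shared between genes count once toward the footprint. Panel
#' genes absent from the annotation are reported in `missing_genes` (a
#' warning, unless the entire panel is missing, which is an error).
#'
#' @param panel A `panel_definition`.
#' @param models A `gene_models` tibble.
#' @return A `panel_footprint` with merged intervals (`GRanges`),
#'   `total_bases`, `total_mb`, per-gene `selected_transcripts`, and
#'   `missing_genes`.
#' @export
panel_footprint <- function(panel, models) {
  stopifnot(inherits(panel, "panel_definition"))
  present <- intersect(panel$genes, unique(models$gene))
  missing <- setdiff(panel$genes, present)
  if (!length(present)) {
    stop("empty footprint: no gene of panel '", panel$name,
         "' is present in the annotation")
  }
  if (length(missing)) {
    warning("panel '", panel$name, "': ", length(missing),
            " gene(s) absent from annotation")
  }
  sel <- longest_transcript(models, genes = present)
  ex <- dplyr::inner_join(tibble::as_tibble(models), sel[, c("gene", "transcript")],
                          by = c("gene", "transcript"))
  gr <- GenomicRanges::reduce(exons_to_granges(ex))
  new_footprint(panel$name, setNames(sel$transcript, sel$gene), gr, missing)
}

#' Coding footprint of the whole exome
#'
#' The union of all coding exons of all transcripts of all genes, merged.
#' Note the asymmetry with [panel_footprint()], which uses only the longest
#' transcript per gene: the exome denominator covers every annotated coding
#' base.
#'
#' @param models A `gene_models` tibble.
#' @param name Footprint label, default `"WES"`.
#' @return A `panel_footprint`.
#' @export
exome_footprint <- function(models, name = "WES") {
  if (!nrow(models)) stop("no gene models supplied")
  gr <- GenomicRanges::reduce(exons_to_granges(tibble::as_tibble(models)))
  new_footprint(name, setNames(character(0), character(0)), gr, character(0),
                n_genes = length(unique(models$gene)))
}

exons_to_granges <- function(ex) {
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end))
}

#' @export
print.panel_footprint <- function(x, ...) {
  cat("panel footprint '", x$panel_name, "': ",
      format(x$total_bases, big.mark = ","), " bases (",
      sprintf("%.3f", x$total_mb), " Mb), ",
      x$n_genes, " gene(s), ",
      length(x$missing_genes), " missing\n", sep = "")
  invisible(x)
}

#' Tabulate footprints
#'
#' @param footprints A list of `panel_footprint` objects.
#' @return Tibble with columns `panel`, `n_genes`, `n_missing`,
#'   `total_bases`, `total_mb`.
#' @export
footprint_report <- function(footprints) {
  dplyr::bind_rows(lapply(footprints, function(fp) tibble::tibble(
    panel = fp$panel_name,
    n_genes = fp$n_genes,
    n_missing = length(fp$missing_genes),
    total_bases = fp$total_bases,
    total_mb = fp$total_mb)))
}
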