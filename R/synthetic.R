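#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the simulator: the gene universe (log-normal coding
#' lengths), the cohort (per-tumor mutation rates spanning orders of
#' magnitude, as somatic burden does across tumor types), panels drawn from
#' a shared "cancer gene" pool so they overlap partially like real assays,
#' the consequence model, and the survival model whose hazard depends on
#' log-TMB.
#'
#' @param seed Integer seed; every simulation function derives its stream
#'   from it, so identical configs give byte-identical outputs.
#' @param n_genes Number of genes in the synthetic exome.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters for
#'   per-gene coding length in bases; the defaults give a mean of ~1.5 kb.
#' @param n_samples Number of tumors.
#' @param tumor_types Data frame with `name`, `weight`, `rate_min`,
#'   `rate_max`: per-type log-uniform bounds (variants per Mb) for the
#'   per-tumor mutation rate.
#' @param count_bounds Optional length-2 vector: draw per-tumor total exome
#'   variant counts log-uniformly between these bounds instead of using
#'   rates (counts are then spread over genes in proportion to their coding
#'   footprint).
#' @param panels Named list: each element is either a gene count (genes are
#'   drawn from the shared pool) or an explicit character vector of genes.
#' @param panel_pool_size Size of the shared gene pool panels are drawn
#'   from; overlap between panels arises from drawing from this common pool.
#' @param panel_rate_multiplier Named numeric: relative mutation rate of the
#'   genes of the named panel (1 = exome-average rate).
#' @param consequence_model `"genetic_code"` (draw a uniform sense codon,
#'   position and alternate base; classify with the standard code, so the
#'   synonymous fraction emerges from the code's redundancy) or
#'   `"fixed_fraction"` (synonymous with probability `syn_fraction`).
#' @param syn_fraction Synonymous probability for the `fixed_fraction`
#'   model; the default is the code-determined constant 134/549.
#' @param indel_fraction Probability that a variant is an indel.
#' @param h0 Baseline hazard per day.
#' @param beta_logtmb Log-hazard increment per unit `log(TMB + 1)`.
#' @param censoring_rate Expected fraction of censored subjects.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       gene_length_meanlog = log(1500) - 0.6^2 / 2,
                       gene_length_sdlog = 0.6,
                       n_samples = 100L,
                       tumor_types = data.frame(
                         name = c("typeA", "typeB", "typeC"),
                         weight = c(0.4, 0.35, 0.25),
                         rate_min = c(0.5, 1, 2),
                         rate_max = c(20, 50, 100)),
                       count_bounds = NULL,
                       panels = list(panelA = 300L),
                       panel_pool_size = 1000L,
                       panel_rate_multiplier = NULL,
                       consequence_model = c("genetic_code", "fixed_fraction"),
                       syn_fraction = 134 / 549,
                       indel_fraction = 0.1,
                       h0 = 5e-4,
                       beta_logtmb = 0.35,
                       censoring_rate = 0.3) {
  consequence_model <- match.arg(consequence_model)
  stopifnot(is.numeric(seed), length(seed) == 1, n_genes >= 1, n_samples >= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            syn_fraction >= 0, syn_fraction <= 1,
            censoring_rate >= 0, censoring_rate < 1, h0 > 0,
            all(tumor_types$rate_min > 0),
            all(tumor_types$rate_max >= tumor_types$rate_min),
            all(tumor_types$weight > 0))
  if (!is.null(count_bounds)) {
    stopifnot(length(count_bounds) == 2, all(count_bounds >= 1),
              count_bounds[2] >= count_bounds[1])
  }
  sizes <- vapply(panels, function(p) if (is.numeric(p)) as.integer(p) else length(p),
                  integer(1))
  if (any(sizes > n_genes)) stop("panel larger than the gene universe")
  pool <- min(panel_pool_size, n_genes)
  if (any(sizes > pool)) stop("panel larger than the panel gene pool")
  if (!is.null(panel_rate_multiplier)) {
    stopifnot(!is.null(names(panel_rate_multiplier)),
              all(names(panel_rate_multiplier) %in% names(panels)),
              all(panel_rate_multiplier > 0))
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_meanlog = gene_length_meanlog,
                 gene_length_sdlog = gene_length_sdlog,
                 n_samples = as.integer(n_samples),
                 tumor_types = tumor_types, count_bounds = count_bounds,
                 panels = panels, panel_pool_size = as.integer(pool),
                 panel_rate_multiplier = panel_rate_multiplier,
                 consequence_model = consequence_model,
                 syn_fraction = syn_fraction,
                 indel_fraction = indel_fraction,
                 h0 = h0, beta_logtmb = beta_logtmb,
                 censoring_rate = censoring_rate),
            class = "sim_config")
}

# Partition total length L into k exon chunks of >= min_len each.
split_exons <- function(L, k, min_len = 10L) {
  k <- max(1L, min(k, L %/% min_len))
  if (k == 1L) return(L)
  free <- L - k * min_len
  cutpts <- sort(sample.int(free + 1L, k - 1L, replace = TRUE) - 1L)
  parts <- diff(c(0L, cutpts, free))
  as.integer(parts + min_len)
}

#' Simulate a synthetic exome and panel definitions
#'
#' Generates `n_genes` genes laid out over 22 synthetic chromosomes, each
#' with 1-3 transcripts; the first transcript carries the full coding
#' footprint (1-20 exons) and the others are strict sub-selections of its
#' exons, so the longest transcript is unique. Panels are drawn without
#' replacement from a shared pool of genes.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_genome`: `models` (a `gene_models` tibble),
#'   `panels` (list of `panel_definition`), `gene_pool` (the shared panel
#'   pool), `config`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  lens <- pmax(150L, pmin(100000L,
    as.integer(round(rlnorm(ng, cfg$gene_length_meanlog, cfg$gene_length_sdlog)))))
  n_exons <- sample.int(20L, ng, replace = TRUE)
  n_tx <- sample.int(3L, ng, replace = TRUE)
  chrom_of <- paste0("chr", (seq_len(ng) - 1L) %% 22L + 1L)
  offset <- integer(22L); names(offset) <- paste0("chr", 1:22)
  acc_gene <- vector("list", ng); acc_tx <- vector("list", ng)
  acc_start <- vector("list", ng); acc_end <- vector("list", ng)
  acc_chrom <- character(ng)
  for (i in seq_len(ng)) {
    ex_len <- split_exons(lens[i], n_exons[i])
    k <- length(ex_len)
    introns <- if (k > 1) sample(100:2000, k - 1, replace = TRUE) else integer(0)
    chrom <- chrom_of[i]
    gstart <- offset[[chrom]]
    starts <- as.integer(gstart + cumsum(c(0L, ex_len[-k] + introns)))
    ends <- as.integer(starts + ex_len)
    offset[[chrom]] <- ends[k] + sample(1000:5000, 1)
    tx <- rep(paste0(genes[i], ".t1"), k)
    st <- starts; en <- ends
    if (n_tx[i] > 1 && k > 1) {
      for (t in 2:n_tx[i]) {
        keep <- sort(sample.int(k, sample.int(k - 1L, 1L)))
        tx <- c(tx, rep(paste0(genes[i], ".t", t), length(keep)))
        st <- c(st, starts[keep]); en <- c(en, ends[keep])
      }
    }
    acc_gene[[i]] <- rep(genes[i], length(tx))
    acc_tx[[i]] <- tx
    acc_start[[i]] <- st; acc_end[[i]] <- en
    acc_chrom[i] <- chrom
  }
  n_per <- lengths(acc_tx)
  models <- tibble::tibble(
    gene = unlist(acc_gene), transcript = unlist(acc_tx),
    chrom = rep(acc_chrom, n_per),
    start = unlist(acc_start), end = unlist(acc_end))
  models <- structure(models, class = c("gene_models", class(tibble::tibble())),
                      n_skipped = 0L)
  # Clinical panels target long, heavily studied genes, so their footprints
  # run larger than a uniform gene draw would give; a length-weighted draw
  # of the shared pool reproduces realistic panel sizes.
  pool <- sample(genes, cfg$panel_pool_size, prob = lens)
  panels <- lapply(names(cfg$panels), function(nm) {
    p <- cfg$panels[[nm]]
    if (is.numeric(p)) panel_definition(nm, sample(pool, as.integer(p)))
    else panel_definition(nm, p)
  })
  names(panels) <- names(cfg$panels)
  structure(list(models = models, panels = panels, gene_pool = pool,
                 config = cfg), class = "sim_genome")
}

#' Write a simulated genome to disk
#'
#' Emits a GTF of CDS features (1-based inclusive coordinates) and one
#' plain-text gene list per panel.
#'
#' @param genome A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `gtf` path and `panel` paths.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "sim_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- tibble::as_tibble(genome$models)
  gtf <- file.path(dir, "annotation.gtf")
  lines <- sprintf(
    '%s\tpanelTMB_sim\tCDS\t%d\t%d\t.\t+\t0\tgene_id "%s"; gene_name "%s"; transcript_id "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$gene, ex$gene, ex$transcript)
  writeLines(lines, gtf)
  panel_paths <- vapply(genome$panels, function(p) {
    path <- file.path(dir, paste0("panel_", p$name, ".txt"))
    writeLines(c(paste0("# panel ", p$name), p$genes), path)
    path
  }, character(1))
  invisible(list(gtf = gtf, panels = panel_paths))
}

# Per-gene union coding footprint with cumulative offsets, for uniform
# placement of variants over coding positions. Assumes (as the simulated
# genome guarantees) that a gene's exons lie on one chromosome.
gene_union_table <- function(models) {
  ex <- tibble::as_tibble(models)
  gkey <- factor(ex$gene, levels = sort(unique(ex$gene)))
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  red <- IRanges::reduce(S4Vectors::split(ir, gkey))
  n_per <- S4Vectors::elementNROWS(red)
  flat <- unlist(red, use.names = FALSE)
  gene <- rep(names(red), n_per)
  w <- IRanges::width(flat)
  cs <- cumsum(as.numeric(w))
  base <- cs - w
  first <- base[match(unique(gene), gene)]
  cum0 <- base - rep(first, n_per)
  chrom_by_gene <- ex$chrom[match(names(red), ex$gene)]
  tibble::tibble(gene = gene, chrom = rep(chrom_by_gene, n_per),
                 start = IRanges::start(flat) - 1L, end = IRanges::end(flat),
                 cum0 = cum0, width = as.integer(w))
}

sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

draw_snv_consequences <- function(n, model, syn_fraction) {
  bases <- c("A", "C", "G", "T")
  if (model == "genetic_code") {
    codons <- sample(sense_codons(), n, replace = TRUE)
    pos <- sample(0:2, n, replace = TRUE)
    ref <- substr(codons, pos + 1L, pos + 1L)
    # uniform over the 3 bases different from the reference base
    shift <- sample.int(3L, n, replace = TRUE)
    refi <- match(ref, bases)
    alt <- bases[((refi - 1L + shift) %% 4L) + 1L]
    csq <- classify_consequence(codons, pos, alt)
  } else {
    ref <- sample(bases, n, replace = TRUE)
    shift <- sample.int(3L, n, replace = TRUE)
    alt <- bases[((match(ref, bases) - 1L + shift) %% 4L) + 1L]
    csq <- ifelse(runif(n) < syn_fraction, "synonymous", "missense")
  }
  list(ref = ref, alt = alt, consequence = csq)
}

#' Simulate a somatic variant cohort
#'
#' For each tumor: draw a tumor type, then a per-Mb mutation rate
#' (log-uniform within the type's bounds, so cohort burdens span orders of
#' magnitude), then place `Poisson(rate x gene footprint x multiplier)`
#' variants per gene uniformly over that gene's coding positions. If
#' `count_bounds` is set, the per-tumor total count is drawn log-uniformly
#' and spread over genes in proportion to footprint instead. SNVs get their
#' alleles and consequence from the configured consequence model; indels are
#' frameshift with probability 2/3, in-frame otherwise.
#'
#' @param cfg A [sim_config()].
#' @param genome A [simulate_genome()] result.
#' @return List of class `sim_cohort`: `variants` (cohort variant tibble),
#'   `samples` (tibble `sample_id`, `tumor_type`, `true_rate`), `config`.
#' @export
simulate_cohort <- function(cfg, genome) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genome, "sim_genome"))
  set.seed(cfg$seed + 1L)
  ns <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(ns))
  tt <- cfg$tumor_types
  type_idx <- sample.int(nrow(tt), ns, replace = TRUE,
                         prob = tt$weight / sum(tt$weight))
  rate <- exp(runif(ns, log(tt$rate_min[type_idx]), log(tt$rate_max[type_idx])))

  ut <- gene_union_table(genome$models)
  glen_m <- rowsum(as.numeric(ut$width), ut$gene)
  glen <- setNames(as.numeric(glen_m), rownames(glen_m))
  gene_ids <- names(glen)
  mult <- rep(1, length(glen)); names(mult) <- gene_ids
  if (!is.null(cfg$panel_rate_multiplier)) {
    for (nm in names(cfg$panel_rate_multiplier)) {
      pg <- genome$panels[[nm]]$genes
      mult[pg] <- cfg$panel_rate_multiplier[[nm]]
    }
  }
  w <- glen * mult  # effective per-gene mutational weight

  if (!is.null(cfg$count_bounds)) {
    tot <- round(exp(runif(ns, log(cfg$count_bounds[1]), log(cfg$count_bounds[2]))))
    counts <- vapply(tot, function(N) {
      as.integer(rmultinom(1, N, prob = w))
    }, integer(length(w)))  # genes x samples
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = length(w))
  } else {
    lam <- outer(w / 1e6, rate)  # genes x samples
    counts <- matrix(rpois(length(lam), lam), nrow = length(w))
  }
  nz <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    variants <- tibble::tibble(sample_id = character(), chrom = character(),
                               pos = integer(), ref = character(),
                               alt = character(), variant_class = character(),
                               consequence = character(), gene = character())
  } else {
    reps <- counts[nz]
    vg <- rep(nz[, 1], reps)   # gene index per variant
    vs <- rep(nz[, 2], reps)   # sample index per variant
    n_var <- length(vg)
    # uniform coding offset within each gene, mapped to genomic coordinates
    # through a global concatenated-footprint coordinate (exon rows in `ut`
    # are sorted by gene, matching the order of `glen`).
    off <- floor(runif(n_var) * glen[vg])
    g_base <- setNames(cumsum(glen) - glen, gene_ids)
    cum_global <- g_base[ut$gene] + ut$cum0
    o_global <- g_base[vg] + off
    ei <- findInterval(o_global, cum_global)
    pos <- as.integer(ut$start[ei] + (o_global - cum_global[ei]) + 1)
    chrom <- ut$chrom[ei]
    is_indel <- runif(n_var) < cfg$indel_fraction
    n_snv <- sum(!is_indel)
    ref <- character(n_var); alt <- character(n_var)
    csq <- character(n_var); vclass <- character(n_var)
    if (n_snv > 0) {
      snv <- draw_snv_consequences(n_snv, cfg$consequence_model, cfg$syn_fraction)
      ref[!is_indel] <- snv$ref; alt[!is_indel] <- snv$alt
      csq[!is_indel] <- snv$consequence; vclass[!is_indel] <- "SNV"
    }
    n_ind <- sum(is_indel)
    if (n_ind > 0) {
      bases <- c("A", "C", "G", "T")
      anchor <- sample(bases, n_ind, replace = TRUE)
      frameshift <- runif(n_ind) < 2 / 3
      ins <- runif(n_ind) < 0.5
      extra_len <- ifelse(frameshift, sample(c(1L, 2L), n_ind, replace = TRUE), 3L)
      extra <- vapply(extra_len, function(k)
        paste(sample(bases, k, replace = TRUE), collapse = ""), character(1))
      ref[is_indel] <- ifelse(ins, anchor, paste0(anchor, extra))
      alt[is_indel] <- ifelse(ins, paste0(anchor, extra), anchor)
      vclass[is_indel] <- ifelse(ins, "insertion", "deletion")
      csq[is_indel] <- ifelse(frameshift, "frameshift", "inframe_indel")
    }
    variants <- tibble::tibble(
      sample_id = sample_ids[vs], chrom = chrom, pos = pos,
      ref = ref, alt = alt, variant_class = vclass,
      consequence = csq, gene = gene_ids[vg])
    variants <- dplyr::arrange(variants, .data$sample_id, .data$chrom, .data$pos)
  }
  samples <- tibble::tibble(sample_id = sample_ids,
                            tumor_type = tt$name[type_idx],
                            true_rate = if (is.null(cfg$count_bounds)) rate else NA_real_)
  structure(list(variants = variants, samples = samples, config = cfg),
            class = "sim_cohort")
}

#' Write a simulated cohort as one annotated VCF per sample
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of VCF paths (one per sample, including
#'   samples with zero variants, whose files are header-only).
#' @export
write_cohort_vcfs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=panelTMB_simulate_cohort",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="Consequence class">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  v <- cohort$variants
  ids <- cohort$samples$sample_id
  lines_all <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;CSQ_CLASS=%s",
                       v$chrom, v$pos, v$ref, v$alt, v$gene, v$consequence)
  by_sample <- split(lines_all, factor(v$sample_id, levels = ids))
  paths <- vapply(ids, function(sid) {
    path <- file.path(dir, paste0(sid, ".vcf"))
    writeLines(c(header, by_sample[[sid]]), path)
    path
  }, character(1))
  invisible(paths)
}

# Exponential censoring rate c such that the expected censored fraction over
# subjects with hazards `haz` equals `target`.
solve_censoring_rate <- function(haz, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + haz)) - target
  exp(uniroot(f, lower = log(min(haz)) - 20, upper = log(max(haz)) + 20)$root)
}

#' Simulate overall survival given per-sample TMB
#'
#' Event times are exponential with per-subject hazard
#' `h0 * exp(beta_logtmb * log(tmb + 1))`; censoring times are independent
#' exponential with the rate solved numerically so the expected censored
#' fraction matches `censoring_rate`. Times are rounded up to whole days,
#' which produces realistic ties.
#'
#' @param cfg A [sim_config()].
#' @param tmb_by_sample Tibble with `sample_id` and `tmb` for every sample.
#' @param tumor_type Optional character vector (same order) of tumor types;
#'   defaults to `"all"`.
#' @return Clinical tibble: `sample_id`, `tumor_type`, `os_days`, `event`.
#' @export
simulate_survival <- function(cfg, tmb_by_sample, tumor_type = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- tibble::as_tibble(tmb_by_sample)[, c("sample_id", "tmb")]
  stopifnot(!anyNA(d$tmb))
  set.seed(cfg$seed + 2L)
  n <- nrow(d)
  haz <- cfg$h0 * exp(cfg$beta_logtmb * log1p(d$tmb))
  t_event <- rexp(n, haz)
  crate <- solve_censoring_rate(haz, cfg$censoring_rate)
  t_cens <- if (crate > 0) rexp(n, crate) else rep(Inf, n)
  os <- pmax(1, ceiling(pmin(t_event, t_cens)))
  tibble::tibble(sample_id = d$sample_id,
                 tumor_type = if (is.null(tumor_type)) "all" else tumor_type,
                 os_days = as.numeric(os),
                 event = as.integer(t_event <= t_cens))
}

#' Write a clinical table as TSV
#'
#' @param clinical Tibble with `sample_id`, `tumor_type`, `os_days`, `event`.
#' @param path Output file.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' @param path TSV with header `sample_id`, `tumor_type`, `os_days`, `event`.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("sample_id", "tumor_type", "os_days", "event")
  if (!all(need %in% names(df))) {
    stop("clinical TSV must have columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(df$event %in% c(0, 1)), all(df$os_days >= 0))
  tibble::as_tibble(df)[, need]
}
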