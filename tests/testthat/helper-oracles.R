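# Independent oracles used across tests. These deliberately avoid the code
# paths (and the lookup tables) of the package itself.

# Standard genetic code, hard-coded (independent of Biostrings).
oracle_codon_table <- function() {
  c(TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
}

oracle_classify <- function(codon, pos0, alt) {
  tab <- oracle_codon_table()
  mutated <- codon
  substr(mutated, pos0 + 1, pos0 + 1) <- alt
  if (tab[[mutated]] == "*") return("nonsense")
  if (tab[[mutated]] == tab[[codon]]) return("synonymous")
  "missense"
}

# All (sense codon, position, alternate base) single-substitution cases.
oracle_all_substitutions <- function() {
  tab <- oracle_codon_table()
  sense <- names(tab)[tab != "*"]
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (cod in sense) for (p in 0:2) {
    for (b in setdiff(bases, substr(cod, p + 1, p + 1))) {
      rows[[length(rows) + 1]] <- data.frame(
        codon = cod, pos = p, alt = b,
        expected = oracle_classify(cod, p, b), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Numeric orthogonal-distance minimizer for the errors-in-variables line:
# profile out the intercept, then minimize over the slope.
deming_oracle <- function(x, y, lambda = 1) {
  cx <- x - mean(x); cy <- y - mean(y)
  loss <- function(b) sum((cy - b * cx)^2) / (1 + b^2 / lambda)
  # coarse grid to bracket the global minimum, then golden-section refine
  grid <- seq(-20, 20, by = 0.01)
  b0 <- grid[which.min(vapply(grid, loss, numeric(1)))]
  opt <- optimize(loss, interval = c(b0 - 0.02, b0 + 0.02), tol = 1e-12)
  slope <- opt$minimum
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Hand product-limit estimator: S(t) at each distinct event time.
km_oracle <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(0)
  for (t in ev_times) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out <- c(out, s)
  }
  data.frame(time = ev_times, survival = out)
}

# Write a GTF file from an exon table with 1-based inclusive coordinates.
gtf_file <- function(df, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttest\tCDS\t%d\t%d\t.\t+\t0\tgene_id "%s"; gene_name "%s"; transcript_id "%s";',
    df$chrom, df$start1, df$end1, df$gene, df$gene, df$tx)
  writeLines(lines, path)
  path
}

# A small deterministic annotation: gene A (one transcript, two exons),
# gene B (two transcripts), gene C overlapping A's second exon.
tiny_models <- function() {
  df <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1"),
    start1 = c(11, 31, 101, 101, 36, 1001),
    end1 = c(20, 40, 200, 150, 45, 1100),
    gene = c("A", "A", "B", "B", "C", "C"),
    tx = c("A.t1", "A.t1", "B.t1", "B.t2", "C.t1", "C.t2"))
  suppressMessages(load_gene_models(gtf_file(df)))
}

# Hand-built quartile assignment for driving the Cox stage directly.
make_qa <- function(sample_id, quartile, stratum = "all", tmb = NULL) {
  structure(list(
    mode = "pan_cohort",
    cuts = tibble::tibble(stratum = unique(stratum), c25 = NA_real_,
                          c50 = NA_real_, c75 = NA_real_),
    groups = tibble::tibble(
      sample_id = sample_id, stratum = stratum,
      tmb = if (is.null(tmb)) NA_real_ else tmb,
      quartile = factor(quartile, levels = paste0("Q", 1:4))),
    quantile_type = 7L), class = "quartile_assignment")
}

# Variant tibble builder with sensible defaults.
make_variants <- function(pos, sample_id = "S1", chrom = "chr1",
                          ref = "A", alt = "T", variant_class = "SNV",
                          consequence = "missense", gene = "A") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, variant_class = variant_class,
                 consequence = consequence, gene = gene)
}
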