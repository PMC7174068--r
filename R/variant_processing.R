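CODING_CONSEQUENCES <- c("synonymous", "missense", "nonsense", "frameshift",
                         "inframe_indel", "splice")
VARIANT_CLASSES <- c("SNV", "insertion", "deletion")

# Class from allele lengths: equal lengths -> SNV (multi-nucleotide
# substitutions are lumped with SNVs), longer alt -> insertion, longer
# ref -> deletion.
variant_class_from_alleles <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  dplyr::case_when(la == lr ~ "SNV", la > lr ~ "insertion", TRUE ~ "deletion")
}

as_variant_records <- function(df) {
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
            "consequence", "gene")
  stopifnot(all(need %in% names(df)))
  stopifnot(all(df$pos >= 1), all(df$ref != df$alt))
  tibble::as_tibble(df)[, need]
}

#' Read somatic variants from an annotated VCF
#'
#' Parses a VCF 4.x file (one file per tumor sample) into a flat variant
#' table. Multi-allelic records are split into one row per alternate allele.
#' Records whose FILTER is neither `PASS` nor `.` are dropped and counted in
#' the `n_filtered` attribute. Gene symbol and consequence class are read
#' from INFO keys (annotation dialects vary, so the keys are configurable);
#' rows missing them get `consequence = "unknown"` and an empty gene.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param gene_key,csq_key INFO keys carrying the gene symbol and the
#'   consequence class (defaults `GENE` and `CSQ_CLASS`).
#' @return Tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_class`, `consequence`, `gene`; attribute `n_filtered` counts
#'   non-PASS records dropped.
#' @export
read_variants <- function(path, sample_id = NULL, gene_key = "GENE",
                          csq_key = "CSQ_CLASS") {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = as.integer(length(fix) > 0),
                                       dimnames = list(NULL, names(fix)))
  if (!nrow(fix)) {
    return(structure(as_variant_records(tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), variant_class = character(),
      consequence = character(), gene = character())), n_filtered = 0L))
  }
  filt <- fix[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  n_filtered <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  info <- fix[idx, "INFO"]
  gene <- info_field(info, gene_key)
  csq <- info_field(info, csq_key)
  df <- tibble::tibble(
    sample_id = sample_id,
    chrom = unname(fix[idx, "CHROM"]),
    pos = as.integer(fix[idx, "POS"]),
    ref = unname(fix[idx, "REF"]),
    alt = unname(unlist(alt_list)),
    consequence = unname(ifelse(is.na(csq) | csq == "", "unknown", csq)),
    gene = unname(ifelse(is.na(gene), "", gene)))
  df$variant_class <- variant_class_from_alleles(df$ref, df$alt)
  structure(as_variant_records(df), n_filtered = n_filtered)
}

#' Read somatic variants from a flat TSV
#'
#' Expects a header with `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `consequence`; the variant class is derived from the allele lengths.
#'
#' @param path Path to a tab-separated file.
#' @return Variant tibble as in [read_variants()].
#' @export
read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "gene", "consequence")
  if (!all(need %in% names(df))) {
    stop("variant TSV must have columns: ", paste(need, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$variant_class <- variant_class_from_alleles(df$ref, df$alt)
  as_variant_records(df)
}

#' Classify the consequence of a coding single-base substitution
#'
#' Translates the reference codon and the mutated codon with the standard
#' genetic code: an unchanged amino acid is `synonymous`, a new stop codon is
#' `nonsense`, anything else is `missense`. The redundancy of the code is
#' what makes a fixed fraction of random coding substitutions silent.
#'
#' @param ref_codon Character vector of 3-base codons over `A`,`C`,`G`,`T`
#'   (no stop codons).
#' @param codon_pos Mutated position within the codon, 0, 1 or 2.
#' @param alt_base Replacement base, different from the reference base at
#'   `codon_pos`.
#' @return Character vector: `"synonymous"`, `"missense"` or `"nonsense"`.
#' @export
classify_consequence <- function(ref_codon, codon_pos, alt_base) {
  n <- max(length(ref_codon), length(codon_pos), length(alt_base))
  ref_codon <- toupper(rep_len(ref_codon, n))
  alt_base <- toupper(rep_len(alt_base, n))
  codon_pos <- rep_len(as.integer(codon_pos), n)
  if (!all(grepl("^[ACGT]{3}$", ref_codon))) stop("invalid reference codon")
  if (!all(alt_base %in% c("A", "C", "G", "T"))) stop("invalid alternate base")
  if (!all(codon_pos %in% 0:2)) stop("codon_pos must be 0, 1 or 2")
  code <- Biostrings::GENETIC_CODE
  if (any(code[ref_codon] == "*")) stop("reference codon is a stop codon")
  ref_base <- substr(ref_codon, codon_pos + 1L, codon_pos + 1L)
  if (any(ref_base == alt_base)) stop("alt_base equals the reference base")
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos + 1L, codon_pos + 1L) <- alt_base
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  ifelse(aa_alt == "*", "nonsense",
         ifelse(aa_alt == aa_ref, "synonymous", "missense"))
}

#' Variant inclusion policy
#'
#' Bundles the knobs that define one TMB counting method: whether synonymous
#' variants count, which variant classes count, and the coding footprint a
#' variant must fall in.
#'
#' @param include_synonymous Logical; count synonymous variants?
#' @param region A `panel_footprint` the variant position must lie in.
#' @param variant_classes Subset of `c("SNV", "insertion", "deletion")`.
#' @param include_splice Count `splice` consequences as non-synonymous coding
#'   events (default TRUE).
#' @return An `inclusion_policy` list.
#' @export
inclusion_policy <- function(include_synonymous, region,
                             variant_classes = VARIANT_CLASSES,
                             include_splice = TRUE) {
  stopifnot(inherits(region, "panel_footprint"),
            is.logical(include_synonymous), length(variant_classes) >= 1,
            all(variant_classes %in% VARIANT_CLASSES))
  structure(list(include_synonymous = include_synonymous,
                 variant_classes = variant_classes,
                 region = region,
                 include_splice = include_splice),
            class = "inclusion_policy")
}

#' Test whether variants fall inside a coding footprint
#'
#' The anchor is the variant's reported position (the leftmost reference base
#' affected; for insertions, the base before the insertion point), tested
#' against the footprint's merged intervals.
#'
#' @param variants Variant tibble.
#' @param fp A `panel_footprint`.
#' @return Logical vector, one value per variant.
#' @export
in_region <- function(variants, fp) {
  stopifnot(inherits(fp, "panel_footprint"))
  if (!nrow(variants)) return(logical(0))
  v <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1L))
  # disjoint seqlevels are expected when a panel misses whole chromosomes
  suppressWarnings(
    GenomicRanges::countOverlaps(v, fp$intervals, ignore.strand = TRUE) > 0)
}

#' Apply an inclusion policy to a variant list
#'
#' Keeps variants whose class is allowed, whose anchor position lies inside
#' the policy's footprint, and whose consequence is counted: all coding
#' consequences when synonymous variants are included, the non-synonymous
#' coding consequences otherwise. `noncoding` and `unknown` consequences are
#' never counted. Exact duplicates (same sample, position and alleles) are
#' collapsed to one event before filtering, with the collapsed count recorded
#' in the `n_duplicates` attribute. Order is preserved.
#'
#' @param variants Variant tibble.
#' @param policy An [inclusion_policy()].
#' @return Filtered variant tibble; attribute `drop_summary` counts the
#'   variants removed at each step.
#' @export
filter_variants <- function(variants, policy) {
  stopifnot(inherits(policy, "inclusion_policy"))
  v <- tibble::as_tibble(variants)
  dup <- duplicated(v[, c("sample_id", "chrom", "pos", "ref", "alt")])
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(n_dup, " duplicate variant record(s) collapsed")
    v <- v[!dup, , drop = FALSE]
  }
  class_ok <- v$variant_class %in% policy$variant_classes
  v1 <- v[class_ok, , drop = FALSE]
  region_ok <- in_region(v1, policy$region)
  v2 <- v1[region_ok, , drop = FALSE]
  counted <- CODING_CONSEQUENCES
  if (!policy$include_synonymous) counted <- setdiff(counted, "synonymous")
  if (!policy$include_splice) counted <- setdiff(counted, "splice")
  csq_ok <- v2$consequence %in% counted
  out <- v2[csq_ok, , drop = FALSE]
  structure(out, drop_summary = list(
    n_duplicates = n_dup,
    n_dropped_class = sum(!class_ok),
    n_out_of_region = sum(!region_ok),
    n_dropped_consequence = sum(!csq_ok)))
}
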