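write_test_vcf <- function(body, path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="g">',
    '##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description="c">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body), path)
  path
}

test_that("VCF records parse with annotation, multi-allelic split and FILTER drop", {
  path <- write_test_vcf(c(
    "chr17\t7579472\t.\tG\tA\t.\tPASS\tGENE=TP53;CSQ_CLASS=missense",
    "chr1\t100\t.\tC\tA,T\t.\tPASS\tGENE=G1;CSQ_CLASS=synonymous",
    "chr2\t200\t.\tG\tT\t.\tLowQual\tGENE=G2;CSQ_CLASS=missense",
    "chr3\t300\t.\tGA\tG\t.\tPASS\tGENE=G3;CSQ_CLASS=frameshift",
    "chr4\t400\t.\tA\tC\t.\tPASS\tDP=10"))
  v <- read_variants(path, sample_id = "S1")
  expect_equal(nrow(v), 5)  # 1 + 2 (multi-allelic) + 0 (filtered) + 1 + 1
  expect_equal(attr(v, "n_filtered"), 1L)
  tp53 <- v[v$gene == "TP53", ]
  expect_equal(tp53$variant_class, "SNV")
  expect_equal(tp53$consequence, "missense")
  multi <- v[v$chrom == "chr1", ]
  expect_equal(multi$alt, c("A", "T"))
  expect_equal(v$variant_class[v$chrom == "chr3"], "deletion")
  # missing annotation keys
  unk <- v[v$chrom == "chr4", ]
  expect_equal(unk$consequence, "unknown")
  expect_equal(unk$gene, "")
})

test_that("sample id defaults to the VCF file name", {
  path <- file.path(tempdir(), "TCGA-XX-0001.vcf")
  write_test_vcf("chr1\t1\t.\tA\tT\t.\tPASS\tGENE=G;CSQ_CLASS=missense", path)
  expect_equal(unique(read_variants(path)$sample_id), "TCGA-XX-0001")
})

test_that("malformed VCF raises a format error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("this is not", "a vcf"), path)
  expect_error(read_variants(path), "malformed VCF")
})

test_that("TSV variant dialect round-trips", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tgene\tconsequence",
               "S1\tchr1\t10\tA\tT\tG1\tmissense",
               "S1\tchr1\t20\tAT\tA\tG1\tframeshift"), path)
  v <- read_variants_tsv(path)
  expect_equal(v$variant_class, c("SNV", "deletion"))
  expect_error(read_variants_tsv({
    p <- tempfile(); writeLines("a\tb", p); p
  }), "columns")
})

test_that("consequence classification follows the standard genetic code", {
  expect_equal(classify_consequence("GGA", 2, "G"), "synonymous")  # Gly -> Gly
  expect_equal(classify_consequence("TAC", 2, "A"), "nonsense")    # Tyr -> stop
  expect_equal(classify_consequence("ATG", 0, "C"), "missense")    # Met -> Leu
  expect_error(classify_consequence("AXG", 1, "C"), "invalid")
  expect_error(classify_consequence("ATG", 1, "Z"), "invalid")
  expect_error(classify_consequence("TAA", 0, "C"), "stop codon")
  expect_error(classify_consequence("ATG", 0, "A"), "equals")
})

test_that("classifier matches exhaustive enumeration against a hard-coded table", {
  cases <- oracle_all_substitutions()
  expect_equal(nrow(cases), 61 * 3 * 3)
  got <- classify_consequence(cases$codon, cases$pos, cases$alt)
  expect_equal(got, cases$expected)
})

test_that("random substitutions reproduce the code-determined synonymous fraction", {
  cases <- oracle_all_substitutions()
  p_exact <- mean(cases$expected == "synonymous")  # 134/549
  expect_equal(p_exact, 134 / 549)
  set.seed(7)
  n <- 2e5
  idx <- sample.int(nrow(cases), n, replace = TRUE)  # uniform codon x pos x alt
  got <- classify_consequence(cases$codon[idx], cases$pos[idx], cases$alt[idx])
  expect_lt(abs(mean(got == "synonymous") - p_exact), 0.005)
})

test_that("region membership respects half-open interval boundaries", {
  df <- data.frame(chrom = "chr1", start1 = 11, end1 = 20, gene = "A", tx = "T1")
  fp <- exome_footprint(load_gene_models(gtf_file(df)))  # 0-based (10, 20)
  expect_true(in_region(make_variants(15), fp))
  expect_false(in_region(make_variants(21), fp))
  expect_true(in_region(make_variants(20, ref = "AT", alt = "A",
                                      variant_class = "deletion",
                                      consequence = "frameshift"), fp))
  expect_false(in_region(make_variants(10), fp))  # base before the interval
  expect_true(in_region(make_variants(11), fp))
})

test_that("inclusion policy filters by class, region and synonymous toggle", {
  df <- data.frame(chrom = "chr1", start1 = 1, end1 = 1000, gene = "A", tx = "T1")
  fp <- exome_footprint(load_gene_models(gtf_file(df)))
  v <- make_variants(c(10, 20, 30, 40, 5000),
                     consequence = c("synonymous", "missense", "missense",
                                     "missense", "missense"))
  pol_ns <- inclusion_policy(include_synonymous = FALSE, region = fp)
  pol_all <- inclusion_policy(include_synonymous = TRUE, region = fp)
  expect_equal(nrow(filter_variants(v, pol_ns)), 3)   # syn and out-of-region dropped
  expect_equal(nrow(filter_variants(v, pol_all)), 4)  # out-of-region still dropped

  # variant-class restriction
  v2 <- make_variants(c(10, 20), variant_class = c("SNV", "insertion"),
                      ref = c("A", "A"), alt = c("T", "AT"),
                      consequence = c("missense", "frameshift"))
  pol_snv <- inclusion_policy(include_synonymous = FALSE, region = fp,
                              variant_classes = "SNV")
  expect_equal(filter_variants(v2, pol_snv)$variant_class, "SNV")

  # noncoding and unknown are never counted
  v3 <- make_variants(c(10, 20), consequence = c("noncoding", "unknown"))
  expect_equal(nrow(filter_variants(v3, pol_all)), 0)

  # splice toggle
  v4 <- make_variants(10, consequence = "splice")
  expect_equal(nrow(filter_variants(v4, pol_ns)), 1)
  pol_nosplice <- inclusion_policy(include_synonymous = FALSE, region = fp,
                                   include_splice = FALSE)
  expect_equal(nrow(filter_variants(v4, pol_nosplice)), 0)
})

test_that("synonymous toggle is monotone and filtering is idempotent, order-preserving", {
  df <- data.frame(chrom = "chr1", start1 = 1, end1 = 5000, gene = "A", tx = "T1")
  fp <- exome_footprint(load_gene_models(gtf_file(df)))
  pol_ns <- inclusion_policy(include_synonymous = FALSE, region = fp)
  pol_all <- inclusion_policy(include_synonymous = TRUE, region = fp)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    v <- make_variants(sample(1:6000, n),
                       consequence = sample(c("synonymous", "missense", "nonsense",
                                              "frameshift", "unknown"),
                                            n, replace = TRUE))
    kept_ns <- filter_variants(v, pol_ns)
    kept_all <- filter_variants(v, pol_all)
    key <- function(d) paste(d$pos, d$consequence)
    expect_true(all(key(kept_ns) %in% key(kept_all)))
    # idempotent
    expect_equal(key(filter_variants(kept_ns, pol_ns)), key(kept_ns))
    # order preserved
    expect_equal(kept_ns$pos, v$pos[v$pos %in% kept_ns$pos &
                                      key(v) %in% key(kept_ns)])
  }
})

test_that("exact duplicate records collapse to one counted event", {
  df <- data.frame(chrom = "chr1", start1 = 1, end1 = 1000, gene = "A", tx = "T1")
  fp <- exome_footprint(load_gene_models(gtf_file(df)))
  v <- make_variants(c(10, 10, 20))
  pol <- inclusion_policy(include_synonymous = FALSE, region = fp)
  expect_message(kept <- filter_variants(v, pol), "duplicate")
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "drop_summary")$n_duplicates, 1)
})
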