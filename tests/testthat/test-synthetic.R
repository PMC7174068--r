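small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 31, n_genes = 300, n_samples = 30,
         panels = list(p1 = 60), panel_pool_size = 150),
    list(...))
  do.call(sim_config, args)
}

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$models, g2$models)
  expect_identical(g1$panels$p1$genes, g2$panels$p1$genes)
  c1 <- simulate_cohort(cfg, g1); c2 <- simulate_cohort(cfg, g2)
  expect_identical(c1$variants, c2$variants)

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_genome(g1, d1); write_genome(g2, d2)
  expect_identical(readLines(file.path(d1, "annotation.gtf")),
                   readLines(file.path(d2, "annotation.gtf")))
  write_cohort_vcfs(c1, d1); write_cohort_vcfs(c2, d2)
  sid <- c1$samples$sample_id[1]
  expect_identical(readLines(file.path(d1, paste0(sid, ".vcf"))),
                   readLines(file.path(d2, paste0(sid, ".vcf"))))
  tmb1 <- tibble::tibble(sample_id = c1$samples$sample_id,
                         tmb = runif(30, 1, 50))
  set.seed(99)  # survival must not depend on the ambient RNG state
  s1 <- simulate_survival(cfg, tmb1)
  set.seed(1234)
  s2 <- simulate_survival(cfg, tmb1)
  expect_identical(s1, s2)
})

test_that("every variant written to VCF is parsed back (conservation)", {
  cfg <- small_cfg()
  genome <- simulate_genome(cfg)
  cohort <- simulate_cohort(cfg, genome)
  dir <- file.path(tempdir(), "cons")
  paths <- write_cohort_vcfs(cohort, dir)
  parsed <- dplyr::bind_rows(lapply(paths, read_variants))
  expect_equal(nrow(parsed), nrow(cohort$variants))
  a <- dplyr::arrange(cohort$variants, sample_id, chrom, pos, ref, alt)
  b <- dplyr::arrange(parsed, sample_id, chrom, pos, ref, alt)
  expect_equal(a$pos, b$pos)
  expect_equal(a$ref, b$ref)
  expect_equal(a$alt, b$alt)
  expect_equal(a$gene, b$gene)
  expect_equal(a$consequence, b$consequence)
  expect_equal(a$variant_class, b$variant_class)
})

test_that("placed variants always fall in their gene's coding footprint", {
  cfg <- small_cfg()
  genome <- simulate_genome(cfg)
  cohort <- simulate_cohort(cfg, genome)
  ex <- exome_footprint(genome$models)
  expect_true(all(in_region(cohort$variants, ex)))
  # and the annotated gene matches the footprint gene at that position
  v <- cohort$variants[1:min(200, nrow(cohort$variants)), ]
  for (i in seq_len(nrow(v))) {
    gm <- genome$models[genome$models$gene == v$gene[i], ]
    expect_true(any(gm$start < v$pos[i] & v$pos[i] <= gm$end))
  }
})

test_that("a fixed mutation rate is recovered by the whole-exome TMB mean", {
  cfg <- sim_config(seed = 33, n_genes = 600, n_samples = 120,
                    tumor_types = data.frame(name = "t", weight = 1,
                                             rate_min = 10, rate_max = 10 + 1e-9),
                    panels = list(p1 = 50), panel_pool_size = 200,
                    indel_fraction = 0.1)
  genome <- simulate_genome(cfg)
  cohort <- simulate_cohort(cfg, genome)
  ex <- exome_footprint(genome$models)
  m <- tmb_matrix(cohort$variants, standard_methods(ex, list()),
                  samples = cohort$samples$sample_id)
  wide <- tmb_wide(m)
  tmb_all <- wide[["WES.allcoding"]]
  se <- stats::sd(tmb_all) / sqrt(length(tmb_all))
  expect_lt(abs(mean(tmb_all) - 10), 3 * se + 1e-9)
})

test_that("a negligible mutation rate yields empty but valid VCFs", {
  cfg <- sim_config(seed = 34, n_genes = 50, n_samples = 5,
                    tumor_types = data.frame(name = "t", weight = 1,
                                             rate_min = 1e-9, rate_max = 2e-9),
                    panels = list(p1 = 10), panel_pool_size = 20)
  cohort <- simulate_cohort(cfg, simulate_genome(cfg))
  expect_equal(nrow(cohort$variants), 0)
  dir <- file.path(tempdir(), "empty_vcfs")
  paths <- write_cohort_vcfs(cohort, dir)
  expect_length(paths, 5)
  parsed <- read_variants(paths[1])
  expect_equal(nrow(parsed), 0)
})

test_that("the mechanistic consequence model reproduces the genetic-code constant", {
  cfg <- sim_config(seed = 35, n_genes = 400, n_samples = 100,
                    tumor_types = data.frame(name = "t", weight = 1,
                                             rate_min = 60, rate_max = 120),
                    panels = list(p1 = 50), panel_pool_size = 100,
                    consequence_model = "genetic_code", indel_fraction = 0)
  cohort <- simulate_cohort(cfg, simulate_genome(cfg))
  syn_frac <- mean(cohort$variants$consequence == "synonymous")
  p_exact <- 134 / 549  # exhaustive codon-table enumeration
  n <- nrow(cohort$variants)
  expect_gt(n, 4000)
  expect_lt(abs(syn_frac - p_exact), 4 * sqrt(p_exact * (1 - p_exact) / n))
})

test_that("the fixed-fraction model hits its configured synonymous probability", {
  cfg <- sim_config(seed = 36, n_genes = 400, n_samples = 60,
                    tumor_types = data.frame(name = "t", weight = 1,
                                             rate_min = 30, rate_max = 60),
                    panels = list(p1 = 50), panel_pool_size = 100,
                    consequence_model = "fixed_fraction", syn_fraction = 0.4,
                    indel_fraction = 0)
  cohort <- simulate_cohort(cfg, simulate_genome(cfg))
  expect_lt(abs(mean(cohort$variants$consequence == "synonymous") - 0.4), 0.03)
})

test_that("panel rate multipliers scale variant density inside panel genes", {
  cfg <- sim_config(seed = 37, n_genes = 800, n_samples = 80,
                    tumor_types = data.frame(name = "t", weight = 1,
                                             rate_min = 20, rate_max = 20 + 1e-9),
                    panels = list(p1 = 200), panel_pool_size = 400,
                    panel_rate_multiplier = c(p1 = 0.5), indel_fraction = 0)
  genome <- simulate_genome(cfg)
  cohort <- simulate_cohort(cfg, genome)
  pfp <- panel_footprint(genome$panels$p1, genome$models)
  inside <- sum(in_region(cohort$variants, pfp))
  dens_in <- inside / pfp$total_mb
  ex <- exome_footprint(genome$models)
  outside <- nrow(cohort$variants) - inside
  dens_out <- outside / (ex$total_mb - pfp$total_mb)
  expect_lt(abs(dens_in / dens_out - 0.5), 0.07)
})

test_that("survival generation respects censoring rate and hazard direction", {
  cfg <- small_cfg(n_samples = 400, censoring_rate = 0.3, beta_logtmb = 0.8)
  tv <- tibble::tibble(sample_id = sprintf("S%04d", 1:400),
                       tmb = exp(runif(400, 0, 5)))
  cl <- simulate_survival(cfg, tv)
  expect_true(all(cl$os_days >= 1))
  expect_true(all(cl$event %in% 0:1))
  cens <- mean(cl$event == 0)
  expect_lt(abs(cens - 0.3), 0.08)
  # higher TMB -> higher hazard -> shorter survival among events
  qa <- assign_quartiles(tv, mode = "pan_cohort")
  hr <- cox_quartile_hr(cl, qa)
  expect_gt(hr$hr[hr$contrast == "Q4 vs Q1"], 1)

  cfg_neg <- small_cfg(n_samples = 400, censoring_rate = 0.3, beta_logtmb = -0.8)
  cl_neg <- simulate_survival(cfg_neg, tv)
  hr_neg <- cox_quartile_hr(cl_neg, qa)
  expect_lt(hr_neg$hr[hr_neg$contrast == "Q4 vs Q1"], 1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(panels = list(p = 50), n_genes = 40),
               "larger than the gene universe")
  expect_error(sim_config(panels = list(p = 50), n_genes = 100,
                          panel_pool_size = 30), "pool")
  expect_error(sim_config(panel_rate_multiplier = c(nope = 2)))
  expect_error(sim_config(censoring_rate = 1.2))
  # single-gene exome is legal
  cfg1 <- sim_config(seed = 38, n_genes = 1, n_samples = 2,
                     panels = list(p = 1), panel_pool_size = 1)
  genome <- simulate_genome(cfg1)
  expect_equal(length(unique(genome$models$gene)), 1)
})
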