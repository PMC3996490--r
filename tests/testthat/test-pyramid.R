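test_that("stage 1 keeps trait-mirroring genes and respects the threshold", {
  sim <- small_sim(seed = 1, n_chains = 0)
  ds <- sim$dataset
  # make one gene equal to the trait: certain retention
  ds$mrna["gene_0001", ] <- ds$phenotypes$dsp
  r <- stage1_trait_mrna(ds, "dsp", pyramid_config())
  expect_s3_class(r, "stage_report")
  expect_true("gene_0001" %in% r$stats$gene_id)
  expect_true(all(r$stats$pvalue < 0.05))

  # vacuous threshold: every testable gene retained
  r_all <- stage1_trait_mrna(ds, "dsp", pyramid_config(alpha_stage1 = 1))
  expect_equal(nrow(r_all$stats), nrow(ds$mrna))
})

test_that("stage 1 null retention matches the nominal rate", {
  set.seed(21)
  n <- 90
  E <- matrix(rnorm(1000 * n), 1000, n,
              dimnames = list(sprintf("gene_%04d", 1:1000), paste0("s", 1:n)))
  sim <- small_sim(seed = 2, n_chains = 0, n_samples = n)
  ds <- sim$dataset
  colnames(E) <- ds$sample_ids
  ds$mrna <- E
  r <- stage1_trait_mrna(ds, "dsp", pyramid_config())
  # Binomial(1000, 0.05): mean 50, sd ~6.9; allow 5 sd
  expect_gt(nrow(r$stats), 50 - 35)
  expect_lt(nrow(r$stats), 50 + 35)
})

test_that("stage 2 retains a planted trait-associated miRNA with high power", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    n <- 90
    mirna <- rnorm(n)
    trait <- 0.6 * mirna + rnorm(n, sd = sqrt(1 - 0.36)) # r = 0.6, power >> 0.99
    sim <- small_sim(seed = s, n_chains = 0, n_samples = n)
    ds <- sim$dataset
    ds$mirna["mir_001", ] <- mirna
    ds$phenotypes$dsp <- trait
    r <- stage2_trait_mirna(ds, "dsp", pyramid_config())
    hits <- hits + ("mir_001" %in% r$stats$mirna_id)
  }
  expect_gte(hits, 95)
})

test_that("stage 2 with an empty miRNA matrix yields an empty report", {
  sim <- small_sim(seed = 3, n_chains = 0)
  ds <- sim$dataset
  ds$mirna <- ds$mirna[0, , drop = FALSE]
  r <- stage2_trait_mirna(ds, "dsp", pyramid_config())
  expect_equal(nrow(r$stats), 0)
  expect_equal(r$n_tests, 0)
})

test_that("stage 3 enforces both the p-value and the sign constraint", {
  sim <- small_sim(seed = 4, n_chains = 0)
  ds <- sim$dataset
  # perfect positive correlation: excluded despite p ~ 0
  ds$mrna["gene_0001", ] <- ds$mirna["mir_001", ]
  # strong negative correlation: retained
  ds$mrna["gene_0002", ] <- -ds$mirna["mir_002", ] +
    rnorm(90, sd = 0.5)
  # negative but weak: excluded on p
  ds$mrna["gene_0003", ] <- -0.05 * ds$mirna["mir_003", ] + rnorm(90, sd = 2)

  cfg <- pyramid_config()
  r <- stage3_negative_pairs(ds, paste0("gene_000", 1:3),
                             paste0("mir_00", 1:3), cfg)
  expect_false(any(r$stats$gene_id == "gene_0001"))
  expect_true(any(r$stats$gene_id == "gene_0002" & r$stats$mirna_id == "mir_002"))
  expect_true(all(r$stats$slope < 0))
  expect_true(all(r$stats$pvalue < cfg$alpha_stage3))
  expect_equal(r$n_tests, 9)

  # with the sign filter off, the positive pair is admitted on p alone
  cfg_off <- pyramid_config(require_negative_stage3 = FALSE)
  r_off <- stage3_negative_pairs(ds, paste0("gene_000", 1:3),
                                 paste0("mir_00", 1:3), cfg_off)
  expect_true(any(r_off$stats$gene_id == "gene_0001"))
})

test_that("stage 3 retains a correlation of -0.5 at n = 90 at its theoretical power", {
  # noncentral-t oracle: ncp = r sqrt(88) / sqrt(1 - r^2) = 5.416,
  # two-sided alpha = 1e-4 => power 0.902; 4-sd binomial lower bound = 79/100
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    m <- rnorm(90)
    g <- -0.5 * m + rnorm(90, sd = sqrt(0.75)) # population r = -0.5
    sim <- small_sim(seed = s + 500, n_chains = 0)
    ds <- sim$dataset
    ds$mirna["mir_001", ] <- m
    ds$mrna["gene_0001", ] <- g
    r <- stage3_negative_pairs(ds, "gene_0001", "mir_001", pyramid_config())
    hits <- hits + (nrow(r$stats) == 1)
  }
  expect_gte(hits, 79)
})

test_that("QTL scans retain a planted cis effect explaining 25% of variance", {
  # R2 = 25% <=> |r| = 0.5: same noncentral-t oracle as stage 3, power 0.902
  # at alpha = 1e-4 (stage 4); stage 5 at alpha = 0.05 has power ~ 0.999.
  # Common-variant MAF range so the MAF filter never removes the planted SNP.
  hits4 <- 0
  hits5 <- 0
  for (s in 1:100) {
    sim <- small_sim(seed = s, n_chains = 0, n_snps = 10,
                     maf_range = c(0.2, 0.4))
    ds <- sim$dataset
    snp <- ds$genotypes["snp_0001", ]
    if (var(snp) == 0) next
    z <- (snp - mean(snp)) / sd(snp)
    ds$mrna["gene_0001", ] <- 0.5 * z + rnorm(90, sd = sqrt(0.75)) # R2 = 25%
    ds$mirna["mir_001", ] <- 0.5 * z + rnorm(90, sd = sqrt(0.75))
    cfg <- pyramid_config()
    r4 <- stage4_eqtl_scan(ds, "gene_0001", cfg)
    r5 <- stage5_miqtl_scan(ds, "mir_001", cfg)
    hits4 <- hits4 + any(r4$stats$snp_id == "snp_0001")
    hits5 <- hits5 + any(r5$stats$snp_id == "snp_0001")
  }
  expect_gte(hits4, 79)
  expect_gte(hits5, 95)
})

test_that("stage 6 thresholds candidates and the empty set short-circuits", {
  sim <- small_sim(seed = 6)
  ds <- sim$dataset
  cfg <- pyramid_config()
  r_empty <- stage6_snp_trait(ds, "dsp", character(), cfg)
  expect_equal(nrow(r_empty$stats), 0)

  # a SNP that is a thresholded copy of the trait: overwhelming association
  ds$genotypes["snp_0002", ] <-
    as.numeric(cut(ds$phenotypes$dsp, breaks = 3)) - 1
  r <- stage6_snp_trait(ds, "dsp", c("snp_0002", "snp_0003"), cfg)
  expect_true("snp_0002" %in% r$stats$snp_id)

  # null calibration: survivors ~ |candidates| * alpha at a loose alpha
  set.seed(7)
  sim0 <- small_sim(seed = 7, n_chains = 0, n_snps = 400)
  cfg_loose <- pyramid_config(alpha_stage6 = 0.1)
  cands <- rownames(sim0$dataset$genotypes)
  r0 <- stage6_snp_trait(sim0$dataset, "dsp", cands, cfg_loose)
  expected <- length(cands) * 0.1
  expect_lt(abs(nrow(r0$stats) - expected), 5 * sqrt(expected))
})

test_that("triplet assembly equals brute-force enumeration on random edge sets", {
  snps <- paste0("s", 1:5)
  mirnas <- paste0("m", 1:4)
  genes <- paste0("g", 1:6)
  for (s in 1:20) {
    set.seed(s)
    s1 <- sample(genes, sample(0:6, 1))
    s2 <- sample(mirnas, sample(0:4, 1))
    s3 <- dplyr::distinct(tibble::tibble(
      mirna_id = sample(mirnas, 8, replace = TRUE),
      gene_id = sample(genes, 8, replace = TRUE)
    ))
    s4 <- dplyr::distinct(tibble::tibble(
      snp_id = sample(snps, 10, replace = TRUE),
      gene_id = sample(genes, 10, replace = TRUE)
    ))
    s5 <- dplyr::distinct(tibble::tibble(
      snp_id = sample(snps, 10, replace = TRUE),
      mirna_id = sample(mirnas, 10, replace = TRUE)
    ))
    s6 <- sample(snps, sample(0:5, 1))

    got <- assemble_triplets(fake_reports(s1, s2, s3, s4, s5, s6))
    want <- brute_force_triplets(s1, s2, s3, s4, s5, s6, snps, mirnas, genes)
    expect_identical(
      got[, c("snp_id", "mirna_id", "gene_id")],
      want
    )
  }
})

test_that("minimal closure yields exactly one triplet; any empty stage yields none", {
  s3 <- tibble::tibble(mirna_id = "m1", gene_id = "g1")
  s4 <- tibble::tibble(snp_id = "s1", gene_id = "g1")
  s5 <- tibble::tibble(snp_id = "s1", mirna_id = "m1")
  got <- assemble_triplets(fake_reports("g1", "m1", s3, s4, s5, "s1"))
  expect_equal(nrow(got), 1)
  expect_identical(got$snp_id, "s1")
  expect_identical(got$mirna_id, "m1")
  expect_identical(got$gene_id, "g1")

  empty <- assemble_triplets(fake_reports(character(), "m1", s3, s4, s5, "s1"))
  expect_equal(nrow(empty), 0)
})

test_that("run_pyramid recovers a planted causal chain", {
  recovered <- 0
  for (s in 1:10) {
    sim <- small_sim(seed = 300 + s, n_chains = 1)
    res <- run_pyramid(sim$dataset, "dsp")
    tr <- tidy(res)
    ok <- nrow(tr) == 1 &&
      tr$snp_id == "snp_0001" && tr$mirna_id == "mir_001" &&
      tr$gene_id == "gene_0001"
    recovered <- recovered + ok
  }
  expect_gte(recovered, 8)
})

test_that("run_pyramid on a null dataset returns an empty, well-formed result", {
  sim <- small_sim(seed = 11, n_chains = 0, n_snps = 100, n_genes = 50,
                   n_mirnas = 10)
  res <- run_pyramid(sim$dataset, "dsp")
  expect_s3_class(res, "pyramid_result")
  expect_equal(nrow(res$triplets), 0)
  expect_equal(nrow(res$summary), 7)
  g <- glance(res)
  expect_equal(g$n_triplets, 0)
})

test_that("vacuous thresholds yield the full Cartesian closure", {
  sim <- small_sim(seed = 12, n_chains = 0, n_snps = 8, n_genes = 4,
                   n_mirnas = 3, n_samples = 30)
  cfg <- pyramid_config(
    alpha_stage1 = 1, alpha_stage2 = 1, alpha_stage3 = 1,
    alpha_stage4 = 1, alpha_stage5 = 1, alpha_stage6 = 1,
    require_negative_stage3 = FALSE, maf_min = 0
  )
  res <- run_pyramid(sim$dataset, "dsp", cfg)
  n_snps_kept <- nrow(filter_snps_by_maf(sim$dataset, 0)$genotypes)
  expect_equal(nrow(res$triplets), n_snps_kept * 4 * 3)
})

test_that("the pyramid is monotone in its thresholds and deterministic", {
  sim <- small_sim(seed = 13, n_chains = 1, n_snps = 60, n_genes = 20,
                   n_mirnas = 8)
  base_cfg <- pyramid_config(
    alpha_stage1 = 0.2, alpha_stage2 = 0.2, alpha_stage3 = 0.01,
    alpha_stage4 = 0.01, alpha_stage5 = 0.2, alpha_stage6 = 0.05
  )
  base <- run_pyramid(sim$dataset, "dsp", base_cfg)
  key <- function(res) {
    with(res$triplets, paste(snp_id, mirna_id, gene_id))
  }
  expect_identical(key(run_pyramid(sim$dataset, "dsp", base_cfg)), key(base))

  cfg_with <- function(stage, value) {
    args <- stats::setNames(
      lapply(1:6, function(k) {
        if (k == stage) value else base_cfg[[paste0("alpha_stage", k)]]
      }),
      paste0("alpha_stage", 1:6)
    )
    do.call(pyramid_config, args)
  }
  for (stage in 1:6) {
    a <- base_cfg[[paste0("alpha_stage", stage)]]
    relax_res <- run_pyramid(sim$dataset, "dsp", cfg_with(stage, min(1, a * 5)))
    # relaxing one threshold never removes a triplet
    expect_true(all(key(base) %in% key(relax_res)))
    tight_res <- run_pyramid(sim$dataset, "dsp", cfg_with(stage, a / 5))
    # tightening never adds one
    expect_true(all(key(tight_res) %in% key(base)))
  }
})

test_that("final SNPs nest inside stage-6 survivors inside the QTL intersection", {
  for (s in c(14, 15)) {
    sim <- small_sim(seed = s, n_chains = 1, n_snps = 80, n_genes = 30,
                     n_mirnas = 10)
    cfg <- pyramid_config(
      alpha_stage3 = 0.05, alpha_stage4 = 0.05, alpha_stage6 = 0.2
    )
    res <- run_pyramid(sim$dataset, "dsp", cfg)
    final_snps <- unique(res$triplets$snp_id)
    s6 <- unique(res$stages[[6]]$stats$snp_id)
    s4 <- unique(res$stages[[4]]$stats$snp_id)
    s5 <- unique(res$stages[[5]]$stats$snp_id)
    expect_true(all(final_snps %in% s6))
    expect_true(all(s6 %in% intersect(s4, s5)))
  }
})
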