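test_that("simulate_genome respects the TU size distribution and degenerate cases", {
  one <- simulate_genome(sim_config(n_genes = 1,
                                    genes_per_tu_dist = c("1" = 1), seed = 4))
  expect_equal(nrow(one$annotation), 1)
  expect_equal(length(unique(one$tu_truth$tu_id)), 1)

  pairs <- simulate_genome(sim_config(n_genes = 100,
                                      genes_per_tu_dist = c("2" = 1), seed = 4))
  expect_equal(nrow(pairs$annotation), 100)
  expect_equal(length(unique(pairs$tu_truth$tu_id)), 50)
  expect_true(all(table(pairs$tu_truth$tu_id) == 2))

  # genes are non-overlapping, TU members share a strand and are contiguous
  ann <- dplyr::arrange(pairs$annotation, start)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$end[-nrow(ann)] < ann$start[-1]))
  by_tu <- dplyr::left_join(pairs$tu_truth, pairs$annotation, by = "gene_id")
  strands <- tapply(by_tu$strand, by_tu$tu_id, dplyr::n_distinct)
  expect_true(all(strands == 1))
})

test_that("infeasible genome configs fail loudly", {
  expect_error(simulate_genome(sim_config(n_genes = 2, gene_length = 30,
                                          guides_per_gene = 8, seed = 1)),
               "infeasible")
})

test_that("build_library designs genomic spacers and non-genomic controls", {
  cfg <- sim_config(n_genes = 10, n_controls = 100, seed = 11)
  gen <- simulate_genome(cfg)
  lib <- build_library(gen$genome, gen$annotation, cfg)
  expect_equal(nrow(lib), 10 * 4 + 100)
  expect_true(all(nchar(lib$sequence) == 20))
  expect_false(anyDuplicated(lib$sequence) > 0)

  fwd <- as.character(gen$genome)
  rev <- as.character(Biostrings::reverseComplement(gen$genome))
  targ <- lib[lib$gene_id != "CONTROL", ]
  expect_true(all(vapply(targ$sequence, function(s)
    grepl(s, fwd, fixed = TRUE) || grepl(s, rev, fixed = TRUE), logical(1))))
  ctrl <- lib[lib$gene_id == "CONTROL", ]
  expect_false(any(vapply(ctrl$sequence, function(s)
    grepl(s, fwd, fixed = TRUE) || grepl(s, rev, fixed = TRUE), logical(1))))
  expect_true(all(ctrl$efficiency == 0))
  expect_true(all(targ$offset_frac >= 0 & targ$offset_frac <= 1))
})

test_that("fixed seed gives bit-identical genomes, libraries and counts", {
  cfg <- sim_config(n_genes = 8, n_controls = 30, seed = 99)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  la <- build_library(a$genome, a$annotation, cfg)
  lb <- build_library(b$genome, b$annotation, cfg)
  expect_identical(la, lb)
  sheet <- make_sample_sheet()
  eff <- true_effects(unique(la$gene_id[la$gene_id != "CONTROL"]),
                      rep("neutral", 8))
  expect_identical(simulate_counts(la, eff, cfg, sheet),
                   simulate_counts(lb, eff, cfg, sheet))
})

test_that("simulated spacer LFC converges to G*s*e on a neutral background", {
  # one affected spacer (e = 1, s = -0.3, G = 10) among neutral controls:
  # closed form predicts LFC -3; averaged over 200 replicate screens
  lib <- toy_library(n_genes = 1, guides = 1, n_controls = 200, seed = 2,
                     efficiency = 1)
  cfg <- sim_config(n_genes = 1, n_controls = 200, depth = 500, phi = 0.05,
                    seed = 1)
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 1)
  eff <- tibble::tibble(gene_id = "g01", s_aerobic = -0.3, s_anaerobic = 0)
  lfc <- ctrl_lfc <- numeric(200)
  for (k in 1:200) {
    cfg$seed <- k
    cts <- simulate_counts(lib, eff, cfg, sheet)
    is_ctrl <- lib$gene_id == "CONTROL"
    norm <- cts$aerobic_Tf_rep1 / median(cts$aerobic_Tf_rep1[is_ctrl]) *
      median(cts$aerobic_Ti_rep1[is_ctrl])
    lfc[k] <- log2((norm[1] + 0.5) / (cts$aerobic_Ti_rep1[1] + 0.5))
    ctrl_lfc[k] <- mean(log2((norm[is_ctrl] + 0.5) /
                               (cts$aerobic_Ti_rep1[is_ctrl] + 0.5)))
  }
  expect_lt(abs(mean(lfc) - (-3)), 0.1)
  expect_lt(abs(mean(ctrl_lfc)), 0.05)  # controls are fitness-neutral
})

test_that("doubling the depth leaves expected LFCs unchanged", {
  lib <- toy_library(n_genes = 2, guides = 2, n_controls = 100, seed = 5,
                     efficiency = 1)
  eff <- tibble::tibble(gene_id = c("g01", "g02"),
                        s_aerobic = c(-0.3, 0), s_anaerobic = c(0, 0))
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 2)
  mean_lfc <- function(depth) {
    v <- numeric(50)
    for (k in 1:50) {
      cfg <- sim_config(n_genes = 2, n_controls = 100, depth = depth,
                        phi = 0.01, seed = 1000 + k)
      cts <- simulate_counts(lib, eff, cfg, sheet)
      ti <- rowMeans(cts[, c("aerobic_Ti_rep1", "aerobic_Ti_rep2")])
      tf <- rowMeans(cts[, c("aerobic_Tf_rep1", "aerobic_Tf_rep2")])
      is_ctrl <- lib$gene_id == "CONTROL"
      tf <- tf / median(tf[is_ctrl]) * median(ti[is_ctrl])
      v[k] <- log2((tf[1] + 0.5) / (ti[1] + 0.5))
    }
    mean(v)
  }
  expect_lt(abs(mean_lfc(500) - mean_lfc(1000)), 0.12)
})

test_that("polar simulation adds downstream effects and attenuated upstream effects", {
  # two-gene TU, g01 upstream of g02; only g02 is essential
  lib <- toy_library(n_genes = 2, guides = 1, n_controls = 200, seed = 3,
                     efficiency = 1)
  lib$offset_frac[1:2] <- 0  # spacers at the 5' end of their genes
  tu <- tibble::tibble(tu_id = "TU1", gene_id = c("g01", "g02"),
                       tu_position = 1:2)
  eff <- tibble::tibble(gene_id = c("g01", "g02"),
                        s_aerobic = c(0, -0.3), s_anaerobic = 0)
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 1)
  lfc_g1 <- lfc_g2 <- numeric(120)
  for (k in 1:120) {
    cfg <- sim_config(n_genes = 2, n_controls = 200, depth = 800, phi = 0.01,
                      polar = TRUE, seed = 2000 + k)
    cts <- simulate_counts(lib, eff, cfg, sheet, tu_truth = tu)
    is_ctrl <- lib$gene_id == "CONTROL"
    tf <- cts$aerobic_Tf_rep1 / median(cts$aerobic_Tf_rep1[is_ctrl]) *
      median(cts$aerobic_Ti_rep1[is_ctrl])
    lfc_g1[k] <- log2((tf[1] + 0.5) / (cts$aerobic_Ti_rep1[1] + 0.5))
    lfc_g2[k] <- log2((tf[2] + 0.5) / (cts$aerobic_Ti_rep1[2] + 0.5))
  }
  # g01's spacer inherits g02's full effect via polarity (downstream gene)
  expect_lt(abs(mean(lfc_g1) - (-3)), 0.15)
  # g02's spacer at offset 0 reverse-polarizes g01 (s = 0): stays near -3
  expect_lt(abs(mean(lfc_g2) - (-3)), 0.15)
})

test_that("missing effects for a targeted gene are an error", {
  lib <- toy_library(n_genes = 2, guides = 1, n_controls = 10, seed = 1)
  eff <- tibble::tibble(gene_id = "g01", s_aerobic = 0, s_anaerobic = 0)
  expect_error(simulate_counts(lib, eff, sim_config(seed = 1),
                               make_sample_sheet()),
               "missing TrueEffect")
})

test_that("emit_fastq realizes counts exactly and conserves read totals", {
  lib <- toy_library(n_genes = 2, guides = 2, n_controls = 5, seed = 8)
  counts <- tibble::tibble(spacer_id = lib$spacer_id,
                           s1 = c(5L, 0L, 2L, 1L, 3L, 0L, 0L, 1L, 4L))
  d <- withr::local_tempdir()
  fp <- emit_fastq(counts, lib, "s1", d, seed = 1)
  r1 <- read_fastq(fp[1])
  expect_equal(length(r1), sum(counts$s1))  # total pairs = column sum
  rc <- count_spacers(fp[1], fp[2], lib)
  expect_equal(rc$count, counts$s1)         # round-trip identity

  zero <- counts; zero$s1 <- 0L
  fp0 <- emit_fastq(zero, lib, "s1", withr::local_tempdir(), seed = 1)
  expect_equal(length(read_fastq(fp0[1])), 0)
})
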