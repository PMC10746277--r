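test_that("size factors follow the median-of-ratios closed form", {
  counts <- tibble::tibble(spacer_id = sprintf("s%d", 1:100),
                           a = rpois(100, 200) + 1L)
  counts$b <- counts$a
  sf <- normalize_counts(counts)
  expect_equal(unname(sf), c(1, 1))

  counts$b <- counts$a * 2L
  sf <- normalize_counts(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(exp(mean(log(sf))), 1)

  # scale invariance: multiplying every column by 7 changes nothing
  scaled <- counts
  scaled$a <- scaled$a * 7L; scaled$b <- scaled$b * 7L
  expect_equal(normalize_counts(scaled), sf)
})

test_that("size factors anchor on controls when enough controls are usable", {
  # essential-gene spacers heavily depleted in sample b; controls unchanged.
  # Whole-library scaling would shrink b's factor; control anchoring must not.
  set.seed(21)
  lib <- toy_library(n_genes = 25, guides = 4, n_controls = 60, seed = 21)
  n <- nrow(lib)
  a <- rpois(n, 500) + 1L
  b <- a
  b[lib$gene_id != "CONTROL"] <- rpois(sum(lib$gene_id != "CONTROL"), 5) + 1L
  counts <- tibble::tibble(spacer_id = lib$spacer_id, a = a, b = b)
  sf_ctrl <- normalize_counts(counts, lib, min_controls = 50)
  expect_lt(abs(log(sf_ctrl[["b"]] / sf_ctrl[["a"]])), 0.1)
  sf_all <- normalize_counts(counts)
  expect_lt(sf_all[["b"]], 0.5 * sf_all[["a"]])
})

test_that("dispersion trend recovers Poisson and NB truths", {
  set.seed(5)
  sheet <- make_sample_sheet(replicates = 2)
  n <- 5000
  counts <- tibble::tibble(spacer_id = sprintf("s%04d", 1:n))
  for (sid in sheet$sample_id) counts[[sid]] <- rpois(n, 500)
  tr <- fit_dispersion(counts, normalize_counts(counts), sheet)
  expect_lte(phi_at(tr, 500), 0.01)

  for (sid in sheet$sample_id) counts[[sid]] <- rnbinom(n, mu = 500, size = 10)
  tr <- fit_dispersion(counts, normalize_counts(counts), sheet)
  expect_lt(abs(phi_at(tr, 500) - 0.1) / 0.1, 0.30)

  # constant counts across replicates -> zero dispersion
  for (sid in sheet$sample_id) counts[[sid]] <- rep(400L, n)
  tr0 <- fit_dispersion(counts, normalize_counts(counts), sheet)
  expect_equal(phi_at(tr0, 400), 0)

  # single replicate is refused with advice
  solo <- make_sample_sheet(replicates = 1)
  expect_error(fit_dispersion(counts[, c("spacer_id", solo$sample_id)],
                              normalize_counts(counts), solo),
               "dispersion_trend")
})

test_that("identical Ti/Tf columns give lfc 0 and p 1", {
  set.seed(6)
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 2)
  base <- rpois(200, 300)
  counts <- tibble::tibble(spacer_id = sprintf("s%03d", 1:200))
  for (sid in sheet$sample_id) counts[[sid]] <- base
  sf <- setNames(rep(1, 4), sheet$sample_id)
  st <- test_spacers(counts, sf, dispersion_trend(0.05), sheet, "aerobic")
  expect_true(all(st$lfc == 0))
  expect_true(all(st$p == 1))
})

test_that("a halved spacer reports lfc close to -1", {
  set.seed(7)
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 2)
  counts <- tibble::tibble(spacer_id = sprintf("s%03d", 1:300))
  for (sid in sheet$sample_id) counts[[sid]] <- 500L
  tf_cols <- sheet$sample_id[sheet$timepoint == "Tf"]
  for (sid in tf_cols) counts[[sid]][1] <- 250L
  sf <- normalize_counts(counts)
  st <- test_spacers(counts, sf, dispersion_trend(0.01), sheet, "aerobic")
  expect_lt(abs(st$lfc[1] - (-1)), 0.05)
  expect_lt(st$p[1], 0.05)
  expect_true(all(abs(st$lfc[-1]) < 0.01))
})

test_that("zero counts at both timepoints are flagged, not dropped", {
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 2)
  counts <- tibble::tibble(spacer_id = c("dead", sprintf("s%02d", 1:50)))
  for (sid in sheet$sample_id) counts[[sid]] <- c(0L, rpois(50, 400))
  sf <- normalize_counts(counts)
  st <- test_spacers(counts, sf, dispersion_trend(0.05), sheet, "aerobic")
  expect_equal(st$lfc[st$spacer_id == "dead"], 0)
  expect_equal(st$p[st$spacer_id == "dead"], 1)
  expect_true(st$low_count[st$spacer_id == "dead"])
  expect_error(test_spacers(counts, sf, dispersion_trend(0.05), sheet,
                            "anaerobic"), "Ti and Tf")
})

test_that("BH q-values are monotone in p-rank and never below p", {
  fx <- make_fixture("tiny", seed = 13)
  sf <- normalize_counts(fx$counts, fx$library)
  tr <- fit_dispersion(fx$counts, sf, fx$sample_sheet)
  st <- test_spacers(fx$counts, sf, tr, fx$sample_sheet, "aerobic")
  expect_true(all(st$q >= st$p))
  expect_true(all(st$q >= 0 & st$q <= 1))
  ord <- order(st$p)
  expect_true(all(diff(st$q[ord]) >= -1e-12))
})

test_that("multiplying one sample's counts by a constant leaves lfc unchanged", {
  set.seed(9)
  fx <- make_fixture("tiny", seed = 9)
  sf <- normalize_counts(fx$counts, fx$library)
  tr <- fit_dispersion(fx$counts, sf, fx$sample_sheet)
  st1 <- test_spacers(fx$counts, sf, tr, fx$sample_sheet, "aerobic")

  scaled <- fx$counts
  scaled$aerobic_Tf_rep1 <- scaled$aerobic_Tf_rep1 * 3L
  sf2 <- normalize_counts(scaled, fx$library)
  st2 <- test_spacers(scaled, sf2, tr, fx$sample_sheet, "aerobic")
  # pseudocount effects stay below 0.01 for spacers at depth >= 100 at
  # both timepoints (a depleted spacer's near-zero Tf mean is where the
  # pseudocount is supposed to act)
  mat <- as.matrix(fx$counts[, fx$sample_sheet$sample_id])
  norm <- sweep(mat, 2, sf[colnames(mat)], "/")
  aero <- fx$sample_sheet[fx$sample_sheet$condition == "aerobic", ]
  m_ti <- rowMeans(norm[, aero$sample_id[aero$timepoint == "Ti"]])
  m_tf <- rowMeans(norm[, aero$sample_id[aero$timepoint == "Tf"]])
  deep <- pmin(m_ti, m_tf) >= 100
  expect_gt(sum(deep), 50)
  expect_lt(max(abs(st1$lfc[deep] - st2$lfc[deep])), 0.01)
})

test_that("per-spacer lfc estimates are unbiased for G*s*e on simulated screens", {
  # 50 genes x 4 guides all at s = -0.2, efficiencies drawn once; averaged
  # over repeated screens the estimate must match G*s*e within 0.1
  lib <- toy_library(n_genes = 50, guides = 4, n_controls = 400, seed = 77)
  eff <- true_effects(unique(lib$gene_id[lib$gene_id != "CONTROL"]),
                      rep("neutral", 50))
  eff$s_aerobic <- -0.2
  sheet <- make_sample_sheet(conditions = "aerobic", replicates = 2)
  truth <- 10 * -0.2 * lib$efficiency[lib$gene_id != "CONTROL"]
  err <- matrix(NA_real_, 20, length(truth))
  for (k in 1:20) {
    cfg <- sim_config(n_genes = 50, n_controls = 400, depth = 500, phi = 0.05,
                      seed = 3000 + k)
    cts <- simulate_counts(lib, eff, cfg, sheet)
    sf <- normalize_counts(cts, lib)
    tr <- fit_dispersion(cts, sf, sheet)
    st <- test_spacers(cts, sf, tr, sheet, "aerobic", library = lib)
    err[k, ] <- st$lfc[st$gene_id != "CONTROL"] - truth
  }
  expect_lt(mean(abs(colMeans(err))), 0.1)
  expect_lt(abs(mean(err)), 0.1)
})
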