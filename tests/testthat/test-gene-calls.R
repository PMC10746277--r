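test_that("median LFC aggregation handles outlier guides and edge cases", {
  expect_equal(gene_median_lfc(c(-1, -2, -3, -4)), -2.5)
  expect_equal(gene_median_lfc(c(-6, -6, -6, 0)), -6)  # one dead guide
  expect_equal(gene_median_lfc(-3.2), -3.2)
  expect_true(is.na(gene_median_lfc(numeric(0))))
  # robustness: moving one value on the same side of the median is inert
  expect_equal(gene_median_lfc(c(-5, -4, -1)), gene_median_lfc(c(-9, -4, -1)))
})

test_that("Stouffer combination matches the normal-CDF closed form", {
  expect_equal(stouffer_combine(0.05), 0.05)          # k = 1 identity
  expect_equal(stouffer_combine(c(0.5, 0.5, 0.5)), 0.5)  # Z = 0
  # independent oracle: Z = 2 * qnorm(0.95) / sqrt(2)
  oracle <- pnorm(2 * qnorm(1 - 0.05) / sqrt(2), lower.tail = FALSE)
  expect_equal(stouffer_combine(c(0.05, 0.05)), oracle)
  expect_equal(round(oracle, 4), 0.0100)
  expect_error(stouffer_combine(numeric(0)), "empty")
  expect_error(stouffer_combine(c(0.5, 1.2)), "0, 1")
  # permutation invariance and monotonicity
  q <- c(0.01, 0.2, 0.6)
  expect_equal(stouffer_combine(q), stouffer_combine(rev(q)))
  expect_lt(stouffer_combine(c(0.005, 0.2, 0.6)), stouffer_combine(q))
  # extreme q survives clamping
  expect_true(is.finite(stouffer_combine(c(0, 1))))
})

fake_stats <- function(gene_id, lfc_a, q_a, lfc_b, q_b, n = 4) {
  dplyr::bind_rows(
    tibble::tibble(spacer_id = paste0(gene_id, "_a", 1:n), gene_id = gene_id,
                   condition = "aerobic", lfc = lfc_a, q = q_a),
    tibble::tibble(spacer_id = paste0(gene_id, "_b", 1:n), gene_id = gene_id,
                   condition = "anaerobic", lfc = lfc_b, q = q_b)
  )
}

test_that("classification implements the inclusive threshold rules", {
  st <- dplyr::bind_rows(
    fake_stats("gEss", -4, 1e-4, -5, 1e-5),      # essential both
    fake_stats("gAero", -4, 1e-4, -0.5, 0.6),    # essential aerobic only
    fake_stats("gDefA", -1.5, 1e-4, 0, 0.9),     # defect aerobic
    fake_stats("gNone", 0, 0.9, 0, 0.9),         # nothing
    fake_stats("gBound", -3, 0.0125, -3, 0.0125) # exactly at the thresholds
  )
  calls <- call_genes(st)
  cl <- setNames(calls$class_label, calls$gene_id)
  expect_equal(cl[["gEss"]], "generally_essential")
  expect_equal(cl[["gAero"]], "conditionally_essential_aerobic")
  expect_equal(cl[["gDefA"]], "fitness_defect_aerobic")
  expect_equal(cl[["gNone"]], "non_essential")
  # q = 0.0125 x4 guides -> Stouffer p just under 0.05?  Compute directly:
  p_bound <- stouffer_combine(rep(0.0125, 4))
  expect_equal(cl[["gBound"]],
               if (p_bound <= 0.05) "generally_essential" else "non_essential")
  # thresholds are inclusive: median exactly -3 with tiny p is essential
  st2 <- fake_stats("gEdge", -3, 1e-6, -3, 1e-6)
  expect_equal(call_genes(st2)$class_label, "generally_essential")
  # labels partition the gene set
  expect_true(all(table(calls$gene_id) == 1))
})

test_that("the conditional rule flag controls the non-qualifying condition", {
  # aerobic conjunction holds; anaerobic LFC passes but p fails
  st <- fake_stats("g1", -4, 1e-4, -4, 0.8)
  expect_equal(call_genes(st, conditional_rule = "conjunction")$class_label,
               "conditionally_essential_aerobic")
  # under lfc_only the anaerobic LFC criterion does NOT fail -> not conditional
  expect_false(call_genes(st, conditional_rule = "lfc_only")$class_label ==
                 "conditionally_essential_aerobic")
})

test_that("condition sensitivity flags follow the two-sided magnitude rule", {
  st <- dplyr::bind_rows(
    fake_stats("gA", -2, 1e-4, -0.1, 0.8),  # aerobic sensitive
    fake_stats("gBoth", -2, 1e-4, -2, 1e-4),  # both -> none
    fake_stats("gUp", 1.5, 1e-3, 0, 0.9)    # enrichment also counts
  )
  calls <- call_genes(st)
  fl <- setNames(calls$sensitivity_flag, calls$gene_id)
  expect_equal(fl[["gA"]], "aerobic_sensitive")
  expect_equal(fl[["gBoth"]], "none")
  expect_equal(fl[["gUp"]], "aerobic_sensitive")
})

test_that("TU annotation attaches ordered members and guards the partition", {
  calls <- call_genes(dplyr::bind_rows(fake_stats("g1", -4, 1e-4, -4, 1e-4),
                                       fake_stats("g2", 0, 0.9, 0, 0.9),
                                       fake_stats("g3", 0, 0.9, 0, 0.9),
                                       fake_stats("gX", 0, 0.9, 0, 0.9)))
  tu <- tibble::tibble(tu_id = c("TU1", "TU1", "TU1", "TU2"),
                       gene_id = c("g1", "g2", "g3", "gSolo"))
  expect_warning(out <- annotate_tu(calls, tu), "singleton")
  g1 <- out[out$gene_id == "g1", ]
  expect_equal(g1$tu_id, "TU1")
  expect_equal(g1$tu_members, "g1,g2,g3")
  gx <- out[out$gene_id == "gX", ]  # absent from table -> singleton fallback
  expect_equal(gx$tu_id, "gX")
  expect_equal(gx$tu_members, "gX")

  bad <- dplyr::bind_rows(tu, tibble::tibble(tu_id = "TU9", gene_id = "g1"))
  expect_error(annotate_tu(calls, bad), "partition")
})

test_that("screen summaries reproduce display-rounding identities", {
  expect_equal(percent_round(289, 1915), 15L)
  expect_equal(percent_round(307, 4131), 7L)
  expect_equal(percent_round(0, 10), 0L)
  calls <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:1915),
    class_label = c(rep("generally_essential", 289),
                    rep("non_essential", 1915 - 289)))
  s <- summarize_screen(calls)
  expect_equal(s$pct_generally_essential, 15L)
  expect_equal(s$n_generally_essential, 289)
  expect_equal(sum(s$class_counts$n), 1915)
})
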