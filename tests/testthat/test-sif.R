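test_that("G2-M mapping rules route each mutation class to its spec", {
  f_cdk1 <- mutation_record("Cdk1", "A177T", "F", ddg_monomer = 5.97)
  s_cdk1 <- mutation_record("Cdk1", "C67Y", "S", ddg_monomer = 3.17)
  s_cycb <- mutation_record("CycB", "W395R", "S", ddg_monomer = 6.57)

  expect_equal(map_mutation(f_cdk1, "g2m")$label, "J_combined")
  expect_equal(unname(map_mutation(f_cdk1, "g2m")$components), c(0.9, 0.1))
  expect_equal(map_mutation(s_cdk1, "g2m")$label, "kd_Cdk1")
  expect_equal(map_mutation(s_cycb, "g2m")$label, "kd_CycB")
  expect_equal(unname(map_mutation(s_cycb, "g2m")$components), c(0.3, 0.7))

  f_cycb <- mutation_record("CycB", "Q99R", "F", ddg_monomer = 1)
  expect_error(map_mutation(f_cycb, "g2m"), "known rules")
})

test_that("MAPK mutations map through the editable channel table", {
  rec <- mutation_record("H-Ras", "G12V", "F", ddg_monomer = 2.5)
  spec <- map_mutation(rec, "mapk_reduced")
  expect_setequal(names(spec$components), c("raf_activation", "raf_deactivation"))
  expect_equal(sum(spec$components), 1)

  unmapped <- mutation_record("Erk", "T185A", "F", ddg_monomer = 1)
  expect_error(map_mutation(unmapped, "mapk_reduced"), "mapping table")

  custom <- data.frame(protein = "Erk", impact_class = "F",
                       channels = "erk_activation", weights = "1")
  expect_equal(names(map_mutation(unmapped, "mapk_reduced", mapping = custom)$components),
               "erk_activation")
})

test_that("linear SIF reproduces the tabulated products to two significant figures", {
  c67y <- mutation_record("Cdk1", "C67Y", "S", ddg_monomer = 3.17, ddg_complex = 1.31)
  s <- sif_score(c67y, c(readout = 0.011))
  expect_equal(signif(unname(s$components), 2), 0.035)

  g227c <- mutation_record("Cdk1", "G227C", "S", ddg_monomer = 7.69, ddg_complex = 7.23)
  expect_equal(signif(unname(sif_score(g227c, 0.011)$components), 2), 0.085)

  zero <- mutation_record("Cdk1", "A1V", "S", ddg_monomer = 0)
  expect_equal(unname(sif_score(zero, 0.011)$components), 0)
  expect_equal(unname(sif_score(zero, 0.011, transform = "lambda", lambda_s = 3)$components), 0)
})

test_that("SIF is linear in ddG and lambda rescales by class", {
  base <- mutation_record("Cdk1", "X1Y", "S", ddg_monomer = 2)
  tripled <- mutation_record("Cdk1", "X1Y", "S", ddg_monomer = 6)
  expect_equal(unname(sif_score(tripled, 0.011)$components),
               3 * unname(sif_score(base, 0.011)$components))

  lam <- sif_score(base, 0.011, transform = "lambda", lambda_s = 0.5, lambda_f = 2)
  expect_equal(unname(lam$components), 0.5 * 2 * 0.011)
  f_rec <- mutation_record("Cdk1", "X1Y", "F", ddg_monomer = 2)
  lam_f <- sif_score(f_rec, 0.011, transform = "lambda", lambda_s = 0.5, lambda_f = 2)
  expect_equal(unname(lam_f$components), 2 * 2 * 0.011)
})

test_that("an attached ensemble yields a standard error on the score", {
  rec <- mutation_record("Cdk1", "C67Y", "S", ddg_monomer = 3.17,
                         ddg_ensemble = c(2.9, 3.1, 3.3))
  s <- sif_score(rec, 0.011)
  expect_false(is.null(s$stderr))
  expect_equal(unname(s$stderr),
               0.011 * stats::sd(c(2.9, 3.1, 3.3)) / sqrt(3))
  no_ens <- sif_score(mutation_record("Cdk1", "C67Y", "S", ddg_monomer = 3.17), 0.011)
  expect_null(no_ens$stderr)
})

test_that("table-C batch scoring reproduces the printed SIF column", {
  tab <- table3_mutations()
  scored <- batch_score(tab, model_key = "g2m", use = "table_c")
  expect_equal(nrow(scored), 8L)
  expect_true(all(is.na(scored$error)))
  expect_equal(signif(scored$sif, 2), signif(tab$sif, 2))
  # absolute agreement within printing precision of each entry
  expect_true(all(abs(scored$sif - tab$sif) <= 0.0005 + 0.005))
})

test_that("an empty mutation table scores to an empty result", {
  empty <- table3_mutations()[0, ]
  out <- batch_score(empty, use = "table_c")
  expect_equal(nrow(out), 0L)
})

test_that("model-C scoring preserves the printed ranking up to one adjacent pair", {
  tab <- table3_mutations()
  scored <- batch_score(tab, model_key = "g2m", use = "model_c")
  expect_true(all(is.na(scored$error)))
  rho <- stats::cor(scored$sif, tab$sif, method = "spearman")
  # the reconstructed kd(Cdk1) coefficient is smaller than the tabulated one,
  # which flips the adjacent A177T/G227C pair; the rest of the order holds
  expect_gte(rho, 0.95)
  expect_equal(order(-scored$sif)[1:2], order(-tab$sif)[1:2])
})

test_that("mapping failures are collected while the batch continues", {
  tab <- table3_mutations()
  tab$impact_class[2L] <- "F"
  tab$protein[2L] <- "CycB"   # no (CycB, F) rule
  scored <- batch_score(tab, use = "table_c")
  expect_equal(nrow(scored), 8L)
  expect_match(scored$error[2L], "rules")
  expect_true(all(is.na(scored$error[-2L])))
})

test_that("a synthetic MAPK panel scores to finite three-component rows", {
  tab <- generate_mutation_set(n_mutations = 40L, seed = 3L)
  scored <- batch_score(tab, model_key = "mapk_reduced", use = "model_c")
  expect_equal(nrow(scored), 40L)
  expect_true(all(is.na(scored$error)))
  comp <- as.matrix(scored[, c("sif_amplitude", "sif_duration", "sif_peak_time")])
  expect_true(all(is.finite(comp)))
})

test_that("component dominance summarises per protein", {
  toy <- data.frame(
    protein = c("A", "A", "B"),
    sif_amplitude = c(0, 0, 5),
    sif_duration = c(2, 3, 0.1),
    sif_peak_time = c(0.5, 0.2, 0.1)
  )
  g <- sif_trajectory_grouping(toy)
  expect_equal(g$dominant[g$protein == "A"], "duration")
  expect_equal(g$dominant[g$protein == "B"], "amplitude")
  one <- sif_trajectory_grouping(toy[3L, ])
  expect_equal(nrow(one), 1L)
})

test_that("Ras-routed and Mek-routed perturbations dominate different components", {
  m <- mapk_model()
  equal_ddg <- 5
  ras_rec <- mutation_record("H-Ras", "G12V", "F", ddg_monomer = equal_ddg)
  mek_rec <- mutation_record("Mek", "Y130C", "F", ddg_monomer = equal_ddg)
  rows <- lapply(list(ras_rec, mek_rec), function(rec) {
    cv <- mapk_control_vector(m, map_mutation(rec, "mapk_reduced"))
    sc <- sif_score(rec, cv)
    data.frame(protein = rec$protein,
               sif_amplitude = sc$components[["amplitude"]],
               sif_duration = sc$components[["duration"]],
               sif_peak_time = sc$components[["peak_time"]])
  })
  g <- sif_trajectory_grouping(do.call(rbind, rows))
  expect_equal(g$dominant[g$protein == "Mek"], "amplitude")
  expect_false(g$dominant[g$protein == "H-Ras"] == "amplitude")
})
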