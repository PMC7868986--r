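make_parent_phen <- function(n_parents = 10, n_traits = 4, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_parents * n_traits, mean = 20, sd = 3),
                 n_parents, n_traits,
                 dimnames = list(sprintf("L%02d", seq_len(n_parents)),
                                 c("YIELD", "TILLER", "GRAIN", "KGW")[seq_len(n_traits)]))
  parent_matrix(vals, "P")
}

test_that("the column-count law holds for all nine parental models", {
  phen <- make_parent_phen()
  plan <- enumerate_crosses(phen$parent_ids)
  for (t_scope in c("One", "All")) {
    t_count <- if (t_scope == "One") 1L else 4L
    for (coding in c("A", "D", "AD", "P")) {
      spec <- parental_model_spec(paste(coding, t_scope, sep = "-"),
                                  target_trait = "YIELD")
      blk <- suppressWarnings(build_parental_design(phen, plan, spec))
      expected <- switch(coding, A = t_count, D = t_count,
                         AD = 2L * t_count, P = 2L * t_count)
      expect_equal(ncol(blk), expected,
                   info = paste(coding, t_scope))
    }
  }
  expect_error(build_parental_design(phen, plan, parental_model_spec("Random")),
               "no fixed columns")
  expect_error(parental_model_spec("A-One"), "target_trait")
  expect_error(build_parental_design(
    phen, plan, parental_model_spec("A-One", target_trait = "HEIGHT")), "HEIGHT")
})

test_that("parental codings follow mid-parent / half-difference / raw-parent formulas", {
  phen <- make_parent_phen(n_parents = 6, n_traits = 2)
  plan <- cross_plan(c("L01", "L02", "L01", "L03", "L05"),
                     c("L03", "L04", "L04", "L02", "L06"), reciprocal = TRUE)
  PM <- phen$values[plan$male, ]
  PF <- phen$values[plan$female, ]
  a <- build_parental_design(phen, plan, parental_model_spec("A-All"), center = FALSE)
  d <- build_parental_design(phen, plan, parental_model_spec("D-All"), center = FALSE)
  p <- build_parental_design(phen, plan, parental_model_spec("P-All"), center = FALSE)
  expect_equal(unname(a), unname((PM + PF) / 2), ignore_attr = TRUE)
  expect_equal(unname(d), unname(abs(PM - PF) / 2), ignore_attr = TRUE)
  expect_equal(unname(p), unname(cbind(PM, PF)), ignore_attr = TRUE)

  # equal parents: the mid-parent value is the shared value, and the
  # all-zero difference column is removed by the collinearity guard
  plan_self <- cross_plan(c("L01", "L02", "L03"), c("L01", "L02", "L03"))
  a1 <- build_parental_design(phen, plan_self,
                              parental_model_spec("A-One", target_trait = "YIELD"),
                              center = FALSE)
  expect_equal(unname(a1[, "midparent_YIELD"]),
               unname(phen$values[c("L01", "L02", "L03"), "YIELD"]))
  expect_warning(
    ad1 <- build_parental_design(phen, plan_self,
                                 parental_model_spec("AD-One", target_trait = "YIELD"),
                                 center = FALSE),
    "dependent")
  expect_equal(colnames(ad1), "midparent_YIELD")
})

test_that("parental AD coding agrees with the coding module applied to the P layer", {
  phen <- make_parent_phen(seed = 8)
  plan <- enumerate_crosses(phen$parent_ids)
  blk <- suppressWarnings(build_parental_design(
    phen, plan, parental_model_spec("AD-All"), center = FALSE))
  d <- code_hybrid_layer(phen, plan)
  expect_equal(unname(blk[, 1:4]), unname(d$Z))
  expect_equal(unname(blk[, 5:8]), unname(d$W))
})

test_that("canonical plans void the maternal-effect reading of the P model", {
  phen <- make_parent_phen()
  plan <- enumerate_crosses(phen$parent_ids)
  expect_warning(build_parental_design(phen, plan, parental_model_spec("P-All")),
                 "maternal")
})

test_that("assemble_model builds the advertised kernel and column structure", {
  ds <- make_tiny_dataset(n_parents = 12, n_hybrids = 25, seed = 3, n_traits = 4)
  plan <- ds$plan
  designs <- list(G = ds$design)
  omic <- suppressMessages(suppressWarnings(standardize_columns(
    code_hybrid_layer(ds$parental, plan))))
  designs$P <- omic

  # GTMP-like full random model on available layers: P as random kernels
  full <- assemble_model(designs, "GP", "A+D",
                         parental_spec = parental_model_spec("Random"))
  expect_setequal(names(full$kernels), c("G_add", "G_dom", "P_add", "P_dom"))
  expect_equal(ncol(full$X), 1L)

  # fixed parental model: P leaves the kernel list and feeds columns
  mix <- suppressWarnings(assemble_model(
    designs["G"], "GP", "A+D",
    parental_spec = parental_model_spec("AD-All"),
    parent_phen = ds$parental, plan = plan))
  expect_setequal(names(mix$kernels), c("G_add", "G_dom"))
  expect_equal(ncol(mix$X), 1L + 8L)

  simple <- assemble_model(designs["G"], "G", "A")
  expect_equal(names(simple$kernels), "G_add")
  expect_equal(ncol(simple$X), 1L)

  expect_error(assemble_model(designs["G"], "G", "A+D",
                              parental_spec = parental_model_spec("AD-All")),
               "requires P")
  expect_error(assemble_model(designs["G"], "GT", "A"), "T")
})

test_that("full random model over four layers yields eight kernels", {
  ds <- make_tiny_dataset(n_parents = 14, n_hybrids = 30, seed = 12, n_traits = 4)
  cfg <- sim_config(n_parents = 14, n_transcripts = 20, n_metabolites = 15, seed = 12)
  omics <- simulate_omics(ds$genotypes, cfg)
  std <- function(pm) suppressMessages(suppressWarnings(
    standardize_columns(code_hybrid_layer(pm, ds$plan))))
  designs <- list(G = ds$design, T = std(omics$transcripts),
                  M = std(omics$metabolites), P = std(ds$parental))
  full <- assemble_model(designs, "GTMP", "A+D",
                         parental_spec = parental_model_spec("Random"),
                         check = FALSE)
  expect_equal(length(full$kernels), 8L)
  expect_setequal(names(full$kernels),
                  c("G_add", "G_dom", "T_add", "T_dom",
                    "M_add", "M_dom", "P_add", "P_dom"))
})

test_that("heritable parental covariates raise HAT predictability of the genomic model", {
  wins <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    ds <- make_tiny_dataset(n_parents = 60, n_hybrids = 140, seed = 850 + r,
                            n_traits = 4, parental_trait_noise = 1)
    ks <- build_kernels(list(G = ds$design), "A", check = FALSE)
    r2_g <- nfold_hat_press(ds$y, NULL, ks, reml_fit(ds$y, NULL, ks)$vc)$r2
    spec <- parental_model_spec("AD-All", target_trait = "TR1")
    Xp <- cbind(1, suppressWarnings(build_parental_design(ds$parental, ds$plan, spec)))
    fit_p <- reml_fit(ds$y, Xp, ks)
    r2_gp <- nfold_hat_press(ds$y, Xp, ks, fit_p$vc)$r2
    if (r2_gp > r2_g) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
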