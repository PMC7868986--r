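#' Configuration of the synthetic RIL hybrid dataset generator
#'
#' Defines the study conditions emulated by the simulator: a biparental
#' population of fully homozygous recombinant inbred lines (genotypes
#' -1/+1) with linkage along chromosomes, transcript and metabolite layers
#' that are partly heritable linear functions of the genotypes, parental
#' phenotypes measured on the lines themselves, and hybrid phenotypes
#' generated from the additive-dominance model `y = mu + Z ga + W gd + e`.
#'
#' @param n_parents number of inbred parental lines.
#' @param n_chromosomes,markers_per_chromosome genome layout.
#' @param recomb_fraction per-adjacent-marker switch probability of the
#'   two-state chain generating each line's genotype mosaic (0 = fully
#'   linked chromosome, 0.5 = free recombination).
#' @param n_transcripts,n_metabolites sizes of the omic layers.
#' @param omic_heritability fraction of each omic feature's variance
#'   explained by genotype (0..1).
#' @param omic_qtl_per_feature number of markers underlying each omic
#'   feature.
#' @param n_traits number of traits (trait 1 is the target; all traits
#'   share the same architecture with independent effect vectors).
#' @param n_additive_qtl,n_dominance_qtl number of markers with additive /
#'   dominance effects on each trait; `NULL` (default) means every marker,
#'   i.e. the polygenic architecture the mixed model assumes.
#' @param var_additive,var_dominance,var_residual target variance
#'   components of the hybrid phenotype; realized components are rescaled
#'   to hit these exactly (population-variance convention).
#' @param parental_trait_noise variance of the environmental noise added
#'   to each parental line's own additive value to form its phenotype.
#' @param n_hybrids number of training hybrids sampled from all possible
#'   crosses.
#' @param seed integer master seed; layer-specific seeds are derived from
#'   it deterministically so e.g. adding metabolites never perturbs the
#'   genotypes.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 120, n_chromosomes = 5,
                       markers_per_chromosome = 60, recomb_fraction = 0.1,
                       n_transcripts = 300, n_metabolites = 200,
                       omic_heritability = 0.5, omic_qtl_per_feature = 5,
                       n_traits = 4, n_additive_qtl = NULL,
                       n_dominance_qtl = NULL, var_additive = 2,
                       var_dominance = 1, var_residual = 1,
                       parental_trait_noise = 1, n_hybrids = 250,
                       seed = 1) {
  cfg <- list(n_parents = n_parents, n_chromosomes = n_chromosomes,
              markers_per_chromosome = markers_per_chromosome,
              recomb_fraction = recomb_fraction,
              n_transcripts = n_transcripts, n_metabolites = n_metabolites,
              omic_heritability = omic_heritability,
              omic_qtl_per_feature = omic_qtl_per_feature,
              n_traits = n_traits, n_additive_qtl = n_additive_qtl,
              n_dominance_qtl = n_dominance_qtl,
              var_additive = var_additive, var_dominance = var_dominance,
              var_residual = var_residual,
              parental_trait_noise = parental_trait_noise,
              n_hybrids = n_hybrids, seed = as.integer(seed))
  stopifnot(cfg$n_parents >= 2, cfg$recomb_fraction >= 0,
            cfg$recomb_fraction <= 0.5, cfg$var_additive >= 0,
            cfg$var_dominance >= 0, cfg$var_residual >= 0,
            cfg$omic_heritability >= 0, cfg$omic_heritability <= 1,
            cfg$parental_trait_noise >= 0, cfg$n_traits >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate homozygous RIL genotypes with linkage
#'
#' Each parent is a mosaic of -1/+1 blocks: along every chromosome the
#' genotype follows a two-state chain that switches state between adjacent
#' markers with probability `recomb_fraction`.
#'
#' @param config a [sim_config()].
#' @return a [parent_matrix()] with `layer = "G"`, all entries in
#'   `{-1, 1}`.
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  n <- config$n_parents
  m_chr <- config$markers_per_chromosome
  r <- config$recomb_fraction
  chrs <- vector("list", config$n_chromosomes)
  for (c_i in seq_len(config$n_chromosomes)) {
    start <- sample(c(-1, 1), n, replace = TRUE)
    if (m_chr > 1L) {
      switches <- matrix(rbinom(n * (m_chr - 1L), 1L, r), n, m_chr - 1L)
      flips <- cbind(0L, t(apply(switches, 1L, cumsum)))
    } else {
      flips <- matrix(0L, n, 1L)
    }
    chrs[[c_i]] <- start * (-1)^flips
    colnames(chrs[[c_i]]) <- sprintf("chr%d_m%03d", c_i, seq_len(m_chr))
  }
  G <- do.call(cbind, chrs)
  rownames(G) <- sprintf("P%03d", seq_len(n))
  parent_matrix(G, layer = "G")
}

# center/scale a vector to an exact population variance; zero-variance
# input maps to the zero vector
scale_to_var <- function(x, target_var) {
  if (target_var <= 0) return(rep(0, length(x)))
  s <- pop_sd(x)
  if (s <= 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s * sqrt(target_var)
}

#' Simulate transcript and metabolite layers
#'
#' Each omic feature is a linear combination of a small random set of
#' markers plus Gaussian noise, with the genetic and noise parts scaled so
#' the genetic fraction of the feature's variance equals
#' `omic_heritability` exactly (total variance 1).
#'
#' @param genotypes a layer-G [parent_matrix()] from [simulate_parents()].
#' @param config a [sim_config()].
#' @return a list with elements `transcripts` (layer `"T"`) and
#'   `metabolites` (layer `"M"`).
#' @export
simulate_omics <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "parent_matrix"), genotypes$layer == "G",
            inherits(config, "sim_config"))
  G <- genotypes$values
  m <- ncol(G)
  h2 <- config$omic_heritability
  q <- min(config$omic_qtl_per_feature, m)
  one_layer <- function(n_feat, prefix, seed_offset) {
    set.seed(derive_seed(config$seed, seed_offset))
    out <- matrix(0, nrow(G), n_feat)
    for (f in seq_len(n_feat)) {
      idx <- sample.int(m, q)
      g <- drop(G[, idx, drop = FALSE] %*% rnorm(q))
      g <- scale_to_var(g, h2)
      e <- scale_to_var(rnorm(nrow(G)), 1 - h2)
      out[, f] <- g + e
    }
    dimnames(out) <- list(rownames(G),
                          sprintf("%s%0*d", prefix, nchar(n_feat), seq_len(n_feat)))
    out
  }
  list(
    transcripts = parent_matrix(one_layer(config$n_transcripts, "tr", 22L), "T"),
    metabolites = parent_matrix(one_layer(config$n_metabolites, "mb", 33L), "M")
  )
}

#' Simulate hybrid and parental phenotypes
#'
#' Hybrid phenotypes follow `y = mu + Z ga + W gd + e`, where `Z` and `W`
#' are the standardized additive/dominance designs coded from the parents
#' for the supplied cross plan, `ga`/`gd` are effect vectors drawn once on
#' the configured QTL set, and each variance component is rescaled to its
#' configured value exactly. Parental phenotypes are each line's own
#' additive value (the same marker effects applied to the line's
#' standardized genotype) plus independent noise; one column per trait.
#'
#' @param genotypes a layer-G [parent_matrix()].
#' @param plan a [cross_plan()] of the hybrids to phenotype.
#' @param config a [sim_config()].
#' @param mu grand mean of each trait (recycled over traits).
#' @return a list with `phenotypes` (data frame: cross_id plus one column
#'   per trait `TR1..TRk`), `parental` (layer-P [parent_matrix()]),
#'   `truth` (per-trait list with the genetic values and realized variance
#'   components) and `designs` (the standardized G-layer `hybrid_design`
#'   used for generation).
#' @export
simulate_hybrids <- function(genotypes, plan, config, mu = 0) {
  stopifnot(inherits(genotypes, "parent_matrix"), genotypes$layer == "G",
            inherits(plan, "cross_plan"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 44L))
  design <- suppressMessages(
    standardize_columns(code_hybrid_layer(genotypes, plan)))
  m <- ncol(design$Z)
  na_qtl <- min(config$n_additive_qtl %||% m, m)
  nd_qtl <- min(config$n_dominance_qtl %||% m, m)
  n <- nrow(design$Z)
  mu <- rep_len(mu, config$n_traits)

  # parental own additive values use the same effects on the lines'
  # standardized genotypes
  Gp <- genotypes$values
  Gp_std <- apply(Gp, 2L, function(x) {
    s <- pop_sd(x)
    if (s <= 1e-12) rep(0, length(x)) else (x - mean(x)) / s
  })

  traits <- sprintf("TR%d", seq_len(config$n_traits))
  phen <- matrix(NA_real_, n, config$n_traits,
                 dimnames = list(plan$cross_id, traits))
  parental <- matrix(NA_real_, nrow(Gp), config$n_traits,
                     dimnames = list(rownames(Gp), traits))
  truth <- vector("list", config$n_traits)
  names(truth) <- traits
  for (t_i in seq_len(config$n_traits)) {
    ga <- rep(0, m)
    idx_a <- sample.int(m, na_qtl)
    ga[idx_a] <- rnorm(na_qtl)
    gd <- rep(0, m)
    idx_d <- sample.int(m, nd_qtl)
    gd[idx_d] <- rnorm(nd_qtl)
    add <- scale_to_var(drop(design$Z %*% ga), config$var_additive)
    dom <- scale_to_var(drop(design$W %*% gd), config$var_dominance)
    e <- scale_to_var(rnorm(n), config$var_residual)
    phen[, t_i] <- mu[t_i] + add + dom + e
    par_add <- scale_to_var(drop(Gp_std %*% ga), config$var_additive)
    parental[, t_i] <- mu[t_i] + par_add +
      scale_to_var(rnorm(nrow(Gp)), config$parental_trait_noise)
    truth[[t_i]] <- list(
      additive_values = add, dominance_values = dom, residuals = e,
      effects_additive = ga, effects_dominance = gd,
      realized = c(additive = pop_var(add), dominance = pop_var(dom),
                   residual = pop_var(e)))
  }
  list(
    phenotypes = data.frame(cross_id = plan$cross_id, phen,
                            row.names = NULL, stringsAsFactors = FALSE),
    parental = parent_matrix(parental, "P"),
    truth = truth,
    designs = design,
    config = config
  )
}

#' Simulate a complete multi-layer dataset
#'
#' Convenience wrapper: genotypes, omic layers, a random training plan of
#' `n_hybrids` crosses drawn from all unordered pairs, and hybrid plus
#' parental phenotypes.
#'
#' @param config a [sim_config()].
#' @param mu grand mean of each trait, passed to [simulate_hybrids()].
#' @return a list with `genotypes`, `transcripts`, `metabolites`,
#'   `parental`, `plan`, `phenotypes`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), mu = 0) {
  genotypes <- simulate_parents(config)
  omics <- simulate_omics(genotypes, config)
  all_plan <- enumerate_crosses(genotypes$parent_ids)
  set.seed(derive_seed(config$seed, 55L))
  n_hyb <- min(config$n_hybrids, nrow(all_plan))
  keep <- sort(sample.int(nrow(all_plan), n_hyb))
  plan <- cross_plan(all_plan$female[keep], all_plan$male[keep])
  hyb <- simulate_hybrids(genotypes, plan, config, mu = mu)
  list(genotypes = genotypes, transcripts = omics$transcripts,
       metabolites = omics$metabolites, parental = hyb$parental,
       plan = plan, phenotypes = hyb$phenotypes, truth = hyb$truth,
       config = config)
}
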