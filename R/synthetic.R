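#' Configuration of the synthetic two-line, three-condition experiment
#'
#' Defines the generative model of the study design the package targets:
#' two cell lines, each measured in wild-type, empty-vector and
#' overexpressing variants with `n_reps` arrays per group. For gene g and
#' sample s,
#'
#' `x[g,s] = mu_g + L_g * 1[line(s) = B] + delta_g * 1[cond(s) = OVEREXPR]
#'          + Q_g * 1[line B, VECTOR] + eps[g,s]`
#'
#' with `eps ~ N(0, sigma2_g)`, `sigma2_g ~ s2_0_true * d0_true /
#' chisq(d0_true)` (the scaled inverse-chi-square prior the moderated t
#' assumes), `mu_g ~ N(7, 1.5^2)` on the log2 scale, `L_g ~ N(0,
#' line_effect_sd^2)` and `delta_g = de_effect` for the planted
#' overexpression-responsive genes, 0 otherwise. The optional `Q_g ~ N(0,
#' vector_quirk_sd^2)` offset, applied only to line B's empty-vector
#' samples, emulates an idiosyncratic control group; it is off by default.
#'
#' Defaults plant a strong cell-line difference that dominates total
#' variance (the confounder the pipeline must set aside) and a 150-gene
#' overexpression signature shared by both lines, plus one pathway whose
#' members are 75% planted genes among decoy pathways.
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_reps Arrays per (line, condition) group (default 3, >= 2).
#' @param line_effect_sd SD of the per-gene cell-line offset (default 1.2).
#' @param n_de_genes Number of planted overexpression-responsive genes (150).
#' @param de_effect Log2 shift in overexpressing samples (default 2).
#' @param vector_quirk_sd SD of the line-B empty-vector offset (default 0).
#' @param d0_true,s2_0_true Variance-prior parameters (defaults 4, 0.05).
#' @param n_pathways Total gene sets, planted first (default 51).
#' @param pathway_size Members per set (default 40).
#' @param n_planted_pathways Sets enriched in planted genes (default 1).
#' @param planted_fraction Fraction of a planted set drawn from the planted
#'   genes (default 0.75).
#' @param seed Integer seed; all randomness flows from it.
#' @param baseline_mean,baseline_sd Parameters of `mu_g` (defaults 7, 1.5).
#' @param line_names Labels of the two cell lines.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 5000L, n_reps = 3L, line_effect_sd = 1.2,
                       n_de_genes = 150L, de_effect = 2.0, vector_quirk_sd = 0,
                       d0_true = 4, s2_0_true = 0.05,
                       n_pathways = 51L, pathway_size = 40L,
                       n_planted_pathways = 1L, planted_fraction = 0.75,
                       seed = 1L, baseline_mean = 7, baseline_sd = 1.5,
                       line_names = c("LINE_A", "LINE_B")) {
  cfg <- list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
              line_effect_sd = line_effect_sd, n_de_genes = as.integer(n_de_genes),
              de_effect = de_effect, vector_quirk_sd = vector_quirk_sd,
              d0_true = d0_true, s2_0_true = s2_0_true,
              n_pathways = as.integer(n_pathways), pathway_size = as.integer(pathway_size),
              n_planted_pathways = as.integer(n_planted_pathways),
              planted_fraction = planted_fraction, seed = as.integer(seed),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              line_names = as.character(line_names))
  stopifnot(cfg$n_genes >= 1, cfg$n_de_genes >= 0, cfg$n_de_genes <= cfg$n_genes,
            cfg$line_effect_sd >= 0, cfg$vector_quirk_sd >= 0,
            cfg$d0_true > 0, cfg$s2_0_true > 0,
            cfg$n_pathways >= 0, cfg$pathway_size >= 1,
            cfg$n_planted_pathways <= cfg$n_pathways,
            cfg$planted_fraction >= 0, cfg$planted_fraction <= 1,
            length(cfg$line_names) == 2L, cfg$pathway_size <= cfg$n_genes)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic design: %d genes, 2 lines x 3 conditions x %d reps (seed %d)\n",
              x$n_genes, x$n_reps, x$seed))
  cat(sprintf("Planted: %d genes at +%g log2; line SD %g; quirk SD %g; prior (d0 = %g, s2_0 = %g)\n",
              x$n_de_genes, x$de_effect, x$line_effect_sd, x$vector_quirk_sd,
              x$d0_true, x$s2_0_true))
  invisible(x)
}

#' Generate a synthetic experiment with known truth
#'
#' Draws an expression matrix, annotation and gene-set collection from the
#' model of [sim_config()], plus a truth object recording every planted
#' quantity — the acceptance oracle for the rest of the package. Output is
#' deterministic given the config (the global RNG state is restored on
#' exit).
#'
#' @param config A `sim_config`.
#' @return An object of class `synthetic_experiment`: list with `expr`
#'   (genes x samples matrix), `ann` (annotation data.frame), `gene_sets`
#'   (`gene_set_collection`), `truth` (list with `de_gene_ids`, `sigma2`,
#'   `line_offset`, `delta`, `quirk_offset`, `baseline`,
#'   `planted_pathways`, `seed`, `config`).
#' @export
generate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reps < 2L) stop("n_reps must be >= 2 (within-group variance is undefined otherwise)")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ng <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(ng))
  lines <- config$line_names
  conds <- condition_levels
  ann <- expand.grid(rep = seq_len(config$n_reps), condition = conds,
                     cell_line = lines, stringsAsFactors = FALSE)
  ann <- data.frame(
    sample_id = sprintf("%s_%s_%d", ann$cell_line, ann$condition, ann$rep),
    cell_line = ann$cell_line,
    condition = factor(as.character(ann$condition), levels = condition_levels),
    stringsAsFactors = FALSE)
  ns <- nrow(ann)

  baseline <- stats::rnorm(ng, config$baseline_mean, config$baseline_sd)
  line_offset <- stats::rnorm(ng, 0, config$line_effect_sd)
  sigma2 <- config$s2_0_true * config$d0_true / stats::rchisq(ng, config$d0_true)
  de_idx <- sample.int(ng, config$n_de_genes)
  delta <- numeric(ng); delta[de_idx] <- config$de_effect
  quirk <- if (config$vector_quirk_sd > 0) stats::rnorm(ng, 0, config$vector_quirk_sd) else numeric(ng)

  is_b <- ann$cell_line == lines[2L]
  is_oe <- ann$condition == "OVEREXPR"
  is_quirk <- is_b & ann$condition == "VECTOR"
  signal <- outer(baseline, rep(1, ns)) +
    outer(line_offset, as.numeric(is_b)) +
    outer(delta, as.numeric(is_oe)) +
    outer(quirk, as.numeric(is_quirk))
  noise <- matrix(stats::rnorm(ng * ns, 0, sqrt(sigma2)), ng, ns)
  expr <- signal + noise
  dimnames(expr) <- list(gene_ids, ann$sample_id)

  gene_sets <- make_planted_collection(gene_ids, de_idx, config)

  truth <- list(de_gene_ids = gene_ids[sort(de_idx)],
                sigma2 = stats::setNames(sigma2, gene_ids),
                line_offset = stats::setNames(line_offset, gene_ids),
                delta = stats::setNames(delta, gene_ids),
                quirk_offset = stats::setNames(quirk, gene_ids),
                baseline = stats::setNames(baseline, gene_ids),
                planted_pathways = names(gene_sets)[seq_len(config$n_planted_pathways)],
                seed = config$seed,
                config = unclass(config))
  structure(list(expr = expr, ann = ann, gene_sets = gene_sets, truth = truth),
            class = "synthetic_experiment")
}

# Planted sets draw round(planted_fraction * size) members from the DE genes,
# the rest from the others; decoys are uniform draws from all genes.
make_planted_collection <- function(gene_ids, de_idx, config) {
  ng <- length(gene_ids)
  n_from_de <- min(round(config$planted_fraction * config$pathway_size), length(de_idx))
  sets <- vector("list", config$n_pathways)
  nm <- character(config$n_pathways)
  for (i in seq_len(config$n_pathways)) {
    if (i <= config$n_planted_pathways) {
      members <- c(sample(de_idx, n_from_de),
                   sample(setdiff(seq_len(ng), de_idx), config$pathway_size - n_from_de))
      nm[i] <- sprintf("PLANTED_PATHWAY_%02d", i)
    } else {
      members <- sample.int(ng, config$pathway_size)
      nm[i] <- sprintf("DECOY_PATHWAY_%02d", i - config$n_planted_pathways)
    }
    sets[[i]] <- gene_ids[sort(members)]
  }
  names(sets) <- nm
  descr <- stats::setNames(
    ifelse(seq_len(config$n_pathways) <= config$n_planted_pathways,
           "synthetic planted pathway", "synthetic decoy pathway"), nm)
  structure(sets, description = descr, class = "gene_set_collection")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic experiment:", nrow(x$expr), "genes x", ncol(x$expr), "samples;",
      length(x$truth$de_gene_ids), "planted genes;",
      length(x$gene_sets), "gene sets\n")
  invisible(x)
}

#' Write a synthetic experiment to disk as a fixture bundle
#'
#' Writes `expr.tsv`, `ann.tsv`, `sets.gmt` and `truth.json` into a
#' directory using the package's text formats, so the bundle can be read
#' back with [read_expression_matrix()], [read_sample_annotation()] and
#' [read_gmt()].
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the four file paths.
#' @export
write_fixture_bundle <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expr.tsv"),
             ann = file.path(dir, "ann.tsv"),
             gmt = file.path(dir, "sets.gmt"),
             truth = file.path(dir, "truth.json"))
  write_expression_matrix(experiment$expr, paths[["expr"]])
  write_sample_annotation(experiment$ann, paths[["ann"]])
  write_gmt(experiment$gene_sets, paths[["gmt"]])
  jsonlite::write_json(experiment$truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
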