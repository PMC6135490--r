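## Config-driven orchestration: healthy FBA -> per-study fold changes ->
## LSEI prediction with uniqueness certificates -> permutation tests ->
## cross-study t-test, Fisher meta-analysis and Holm-Bonferroni control ->
## tab-delimited report files plus a run manifest.

#' Assemble a pipeline run configuration
#'
#' @param studies List of study entries, each a list with elements
#'   \code{expression} (matrix path), \code{groups} (two-column file path
#'   or named vector) and optional \code{study_id}.
#' @param model \code{"default"} for the packaged brain model or a model
#'   file path.
#' @param constraints \code{"default"} or a constraint file path.
#' @param n_perm Permutations per study (>= 99).
#' @param seed Master seed.
#' @param weights_policy See \code{\link{predict_disease_fluxes}}.
#' @param out_dir Output directory for the report bundle.
#' @return A \code{run_config}.
#' @export
run_config <- function(studies, model = "default",
                       constraints = "default", n_perm = 999L, seed = 1L,
                       weights_policy = c("coverage", "uniform"),
                       out_dir = "lseifba_run") {
  weights_policy <- match.arg(weights_policy)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  for (s in studies) {
    if (!file.exists(s$expression))
      stop("expression file not found: ", s$expression)
    if (is.character(s$groups) && length(s$groups) == 1L &&
        !file.exists(s$groups))
      stop("group file not found: ", s$groups)
  }
  if (!identical(model, "default") && !file.exists(model))
    stop("model file not found: ", model)
  if (!identical(constraints, "default") && !file.exists(constraints))
    stop("constraint file not found: ", constraints)
  structure(list(studies = studies, model = model,
                 constraints = constraints, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), weights_policy = weights_policy,
                 out_dir = out_dir),
            class = "run_config")
}

write_tsv_commented <- function(tab, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full Lsei-FBA pipeline
#'
#' Stages: (1) healthy FBA with FVA uniqueness certificate; (2) per study,
#' fold-change mapping, LSEI prediction with displacement uniqueness
#' certificate and permutation test; (3) across studies, one-sample
#' t-tests per dependent reaction set, Fisher meta-analysis of the
#' permutation p-values and Holm-Bonferroni FWER control.  All tables are
#' written to the output directory; a JSON manifest records versions,
#' seeds, tolerances and the weight policy.
#'
#' @param config A \code{run_config}.
#' @return The report bundle (named list of all result objects),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  net <- stage("model", if (identical(config$model, "default"))
    default_brain_network() else load_network(config$model))
  cons <- stage("constraints", if (identical(config$constraints, "default"))
    default_constraints() else read_constraints(config$constraints))
  healthy <- stage("healthy_fba", solve_fba(net, cons))
  fva <- stage("fva", flux_variability(net, cons, healthy$objective_value))
  write_tsv_commented(
    data.frame(reaction_id = names(healthy$values),
               subsystem = net$reactions$subsystem,
               flux = unname(healthy$values),
               fva_min = fva$min, fva_max = fva$max),
    file.path(config$out_dir, "healthy_fluxes.tsv"),
    c("healthy-state FBA solution; units=umol/g wet brain/min",
      paste0("objective=", cons$objective_reaction, "=",
             format(healthy$objective_value, digits = 10)),
      paste0("fva_unique=", fva_unique(fva))))
  part <- stage("dependent_sets", dependent_sets(net, healthy))
  predictions <- list()
  perm_results <- list()
  unmatched_log <- list()
  for (s in config$studies) {
    sid <- if (!is.null(s$study_id)) s$study_id else
      sub("\\.[^.]*$", "", basename(s$expression))
    study <- stage(paste0("load:", sid),
                   load_expression(s$expression, s$groups, study_id = sid))
    fcs <- stage(paste0("fold_changes:", sid),
                 reaction_fold_changes(gene_fold_changes(study), net))
    unmatched_log[[sid]] <- fcs$unmatched
    pred <- stage(paste0("lsei:", sid),
                  predict_disease_fluxes(net, healthy, fcs,
                                         config$weights_policy))
    predictions[[sid]] <- pred
    write_prediction(pred, file.path(config$out_dir,
                                     paste0(sid, "_prediction.tsv")))
    write_tsv_commented(
      pred$uniqueness,
      file.path(config$out_dir, paste0(sid, "_uniqueness.tsv")),
      c(paste0("displacement uniqueness certificate; unique=",
               lsei_unique(pred$uniqueness)),
        paste0("ssq=", format(attr(pred$uniqueness, "ssq"), digits = 10))))
    perm <- stage(paste0("permutation:", sid),
                  permutation_test(study, net, healthy,
                                   n_perm = config$n_perm,
                                   seed = config$seed,
                                   weights_policy = config$weights_policy))
    perm_results[[sid]] <- perm
    write_tsv_commented(
      perm, file.path(config$out_dir, paste0(sid, "_permutation.tsv")),
      c(paste0("two-tailed permutation p-values; n_perm=",
               attr(perm, "n_perm"), "; seed=", attr(perm, "seed"),
               "; exhaustive=", attr(perm, "exhaustive"))))
  }
  bundle <- list(net = net, constraints = cons, healthy = healthy,
                 fva = fva, partition = part, predictions = predictions,
                 permutations = perm_results, config = config)
  if (length(predictions) >= 2L) {
    pm <- do.call(cbind, lapply(predictions, function(p) p$v))
    tt <- stage("ttest", ttest_across_studies(pm, healthy, part))
    reps <- part$representatives
    p_lists <- lapply(stats::setNames(seq_along(reps), names(reps)),
                      function(k) vapply(perm_results, function(pr)
                        pr$p[match(reps[k], pr$reaction_id)], numeric(1)))
    meta <- stage("fisher", fisher_meta(p_lists))
    holm <- stage("holm",
                  holm_bonferroni(stats::setNames(meta$p, meta$set)))
    meta_tab <- data.frame(
      set = meta$set,
      members = vapply(part$sets, paste, character(1), collapse = ";"),
      t = tt$t, t_p = tt$p, degenerate = tt$degenerate,
      fisher_X = meta$X, df = meta$df, combined_p = meta$p,
      holm_threshold = holm$threshold[match(meta$set, holm$set)],
      significant = holm$rejected[match(meta$set, holm$set)],
      stringsAsFactors = FALSE)
    write_tsv_commented(
      meta_tab, file.path(config$out_dir, "meta_analysis.tsv"),
      c(paste0("per-set t-test, Fisher meta-analysis, Holm-Bonferroni at ",
               "FWER alpha=", attr(holm, "alpha")),
        paste0("n_sets=", part$n_sets, "; rank1_threshold=",
               format(attr(holm, "rank1_threshold"), digits = 4))))
    bundle$ttest <- tt
    bundle$meta <- meta
    bundle$holm <- holm
  }
  manifest <- list(
    package = PKG_NAME,
    version = as.character(utils::packageVersion(PKG_NAME)),
    r_version = R.version.string,
    seed = config$seed,
    n_perm = config$n_perm,
    weights_policy = config$weights_policy,
    n_reactions = nrow(net$reactions),
    n_dependent_sets = part$n_sets,
    fva_unique = fva_unique(fva),
    tolerances = list(balance = 1e-8, fva_span = 1e-6,
                      uniqueness_rel = 1e-5, uniqueness_abs_floor = 1e-7,
                      uniqueness_gap = 1e-16),
    unmatched_genes = unmatched_log,
    studies = names(predictions))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(bundle)
}

#' Summarize a report bundle
#'
#' One row per study with the headline percentage changes relative to the
#' healthy state: glucose uptake, oxygen uptake, mitochondrial ATP
#' production, malate-aspartate shuttle, GABA shunt and
#' alpha-ketoglutarate dehydrogenase fluxes, plus diseased lactate release
#' as a percentage of the glycolytic pyruvate flux.
#'
#' @param bundle Result of \code{\link{run_pipeline}}.
#' @return data.frame, one row per study.
#' @export
summarize_bundle <- function(bundle) {
  hv <- bundle$healthy$values
  pct <- function(dis, id) {
    h <- hv[[id]]
    if (abs(h) < 1e-12) return(NA_real_)
    100 * (dis[[id]] - h) / h
  }
  rows <- lapply(names(bundle$predictions), function(sid) {
    v <- bundle$predictions[[sid]]$v
    data.frame(
      study_id = sid,
      glucose_uptake_pct = pct(v, "GLCt1r"),
      o2_uptake_pct = pct(v, "O2t"),
      atp_mito_pct = pct(v, "ATPS4mi"),
      mas_pct = pct(v, "ASPGLUm"),
      gaba_shunt_pct = pct(v, "GLUDC"),
      akgdh_pct = pct(v, "AKGDm"),
      lactate_pct_of_pyruvate = -100 * v[["L_LACt2r"]] / v[["PYK"]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Self-contained demonstration run on synthetic data
#'
#' Builds feasible diseased profiles (mitochondrial down-regulation of
#' graded severity), generates one synthetic expression study per profile
#' against the packaged brain model using its real gene symbols, and runs
#' the full pipeline.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_studies Number of synthetic studies (default 4).
#' @param n_perm Permutations per study (default 499 for a quick demo).
#' @param noise_sd Log2 expression noise (default 0.2).
#' @return The report bundle, invisibly (with \code{$summary} attached).
#' @export
demo_run <- function(out_dir = "lseifba_demo", seed = 1L, n_studies = 4L,
                     n_perm = 499L, noise_sd = 0.2) {
  net <- default_brain_network()
  cons <- default_constraints()
  healthy <- solve_fba(net, cons)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  studies <- list()
  for (k in seq_len(n_studies)) {
    sev <- 0.80 + 0.03 * (k - 1)   # graded mitochondrial down-regulation
    prof <- feasible_disease_profile(
      net, healthy,
      pattern = c(oxphos = sev, tca = sev + 0.05, shuttle = sev,
                  gaba_shunt = sev + 0.05, gln_cycle = 0.95,
                  pyruvate = 0.93, glycolysis = 0.95))
    cfg <- synthetic_config(true_reaction_fc = prof$true_reaction_fc,
                            noise_sd = noise_sd, seed = seed + k)
    gen <- generate_study(cfg, net, gene_mode = "network")
    paths <- write_study(gen, out_dir, prefix = paste0("demo_study", k))
    studies[[k]] <- list(expression = paths$matrix, groups = paths$groups,
                         study_id = paste0("demo_study", k))
  }
  config <- run_config(studies, n_perm = n_perm, seed = seed,
                       out_dir = out_dir)
  bundle <- run_pipeline(config)
  bundle$summary <- summarize_bundle(bundle)
  write_tsv_commented(bundle$summary,
                      file.path(out_dir, "summary.tsv"),
                      "per-study percentage changes vs healthy state")
  invisible(bundle)
}
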