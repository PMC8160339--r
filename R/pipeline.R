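beta_label <- function(beta) {
  if (beta == 1) "f1" else if (beta == 0.5) "f05" else if (beta == 2) "f2"
  else paste0("f", gsub("[.]", "", format(beta)))
}

fbeta_of <- function(triple, beta) {
  switch(beta_label(beta), f1 = triple$f1, f05 = triple$f05, f2 = triple$f2,
         stop("unsupported beta", call. = FALSE))
}

#' Pipeline configuration
#'
#' Bundles every stage's settings with desk-scale defaults: the full study
#' sample sizes (534/150 train, 128/111 test), 100-resample correlation
#' screening, small sequential-feature-selection grids with 5-fold CV, the
#' full hyperparameter grids for the final optimisation, 200 bootstrap
#' rounds and a reduced MLP search (8 training functions, up to 6 hidden
#' nodes, 150 epochs). The full-scale protocol (10-fold SFS CV, 10,000
#' bootstrap rounds, 20-node MLP search) is reachable by overriding the
#' corresponding fields. Unknown fields are rejected.
#'
#' @param generator A [generator_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param betas F-score weightings to optimise for.
#' @param corr_n_boot,corr_method,min_sep Frequency-screening settings.
#' @param sfs_folds,sfs_tol,sfs_grids Backward-SFS settings (small grids:
#'   the SFS x grid cross is the expensive stage).
#' @param opt_folds,opt_grids Final hyperparameter-optimisation settings.
#' @param bootstrap_rounds Out-of-bag bootstrap rounds.
#' @param mlp_funs,mlp_max_nodes,mlp_max_epochs,mlp_patience MLP search
#'   settings.
#' @param outdir Directory for CSV outputs (`NULL` = keep in memory only).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            seed = 1L,
                            betas = c(1, 0.5, 2),
                            corr_n_boot = 100, corr_method = "spearman",
                            min_sep = 0.3,
                            sfs_folds = 5, sfs_tol = 1e-4,
                            sfs_grids = list(
                              lr = list(lambda = c(1, 0.01)),
                              dt = list(maxdepth = c(3L, 6L, 10L),
                                        minbucket = 5L),
                              nbc = list(likelihood = c("gaussian", "kernel")),
                              knn = list(k = c(15L, 5L),
                                         metric = "euclidean"),
                              svm = list(kernel = c("linear", "rbf"),
                                         cost = 1, gamma = "scale")),
                            opt_folds = 5, opt_grids = default_grids(),
                            bootstrap_rounds = 200,
                            mlp_funs = mlp_registry(),
                            mlp_max_nodes = 6, mlp_max_epochs = 150,
                            mlp_patience = 10,
                            outdir = NULL) {
  cfg <- list(generator = generator, seed = as.integer(seed), betas = betas,
              corr_n_boot = corr_n_boot, corr_method = corr_method,
              min_sep = min_sep, sfs_folds = sfs_folds, sfs_tol = sfs_tol,
              sfs_grids = sfs_grids, opt_folds = opt_folds,
              opt_grids = opt_grids, bootstrap_rounds = bootstrap_rounds,
              mlp_funs = mlp_funs, mlp_max_nodes = mlp_max_nodes,
              mlp_max_epochs = mlp_max_epochs, mlp_patience = mlp_patience,
              outdir = outdir)
  stopifnot(inherits(generator, "generator_config"),
            all(cfg$betas > 0), cfg$sfs_folds >= 2, cfg$opt_folds >= 2,
            cfg$bootstrap_rounds >= 1, cfg$mlp_max_nodes >= 1,
            all(cfg$mlp_funs %in% mlp_registry()))
  structure(cfg, class = "pipeline_config")
}

#' Run one classical family for one beta
#'
#' The full left-branch treatment of a single family: selection-frequency
#' importance across the SFS grid, threshold subsets, per-subset
#' hyperparameter optimisation, choice of the best subset by CV F-beta
#' (smaller subset on ties), bootstrap validation of the winner, final fit
#' on the whole training table and external testing.
#'
#' @param family Family id (`"lr"`, `"dt"`, `"nbc"`, `"knn"`, `"svm"`).
#' @param ft_train,ft_test Feature tables.
#' @param beta F-score weighting.
#' @param cfg A [pipeline_config()] supplying grids, folds, rounds, seed.
#' @return List with the importance profile, subsets, chosen spec, bootstrap
#'   summary, fitted model and train/test scores.
#' @export
run_classical_family <- function(family, ft_train, ft_test, beta, cfg) {
  prof <- importance_profile(family, cfg$sfs_grids[[family]], ft_train,
                             beta = beta, folds = cfg$sfs_folds,
                             seed = cfg$seed + 11L, tol = cfg$sfs_tol)
  subsets <- subsets_from_thresholds(prof)
  specs <- lapply(subsets, function(fs)
    optimize_hyperparameters(family, fs, ft_train, beta = beta,
                             folds = cfg$opt_folds, seed = cfg$seed + 12L,
                             grid = cfg$opt_grids[[family]]))
  cv <- vapply(specs, attr, numeric(1), "cv_fbeta")
  nfeat <- vapply(subsets, length, integer(1))
  ord <- order(-cv, nfeat)           # best CV; smaller subset on ties
  best <- specs[[ord[1]]]
  boot <- bootstrap_validate(best, ft_train, beta = beta,
                             rounds = cfg$bootstrap_rounds,
                             seed = cfg$seed + 13L)
  model <- train_classifier(best, ft_train, seed = cfg$seed + 14L)
  test <- evaluate_model(model, ft_test)
  list(family = family, beta = beta, importance = prof$importance,
       subsets = subsets, cv_scores = cv, spec = best, bootstrap = boot,
       model = model,
       n_features = length(best$features),
       train_score = boot$median,
       test_score = fbeta_of(test, beta), test_triple = test)
}

#' Run the MLP branch (1 or 2 hidden layers) for one beta
#'
#' Two-stage training-function selection on the training table followed by
#' external testing of the frozen winner.
#'
#' @param layers 1 or 2 hidden layers.
#' @inheritParams run_classical_family
#' @return List with the selection object, fitted model and scores.
#' @export
run_mlp_branch <- function(layers, ft_train, ft_test, beta, cfg) {
  selres <- select_training_function(
    ft_train, registry = cfg$mlp_funs, max_nodes = cfg$mlp_max_nodes,
    layers = layers, beta = beta, seed = cfg$seed + 20L + layers,
    max_epochs = cfg$mlp_max_epochs, patience = cfg$mlp_patience)
  test <- score_triple(ft_test$label, predict(selres$model, ft_test))
  list(layers = layers, beta = beta, selection = selres,
       n_features = length(feature_names()),
       train_score = selres$score,    # internal-test estimate
       test_score = fbeta_of(test, beta), test_triple = test)
}

#' Run the full ripeness-grading pipeline
#'
#' Generate (or accept) a train/test fruit batch, screen frequency points,
#' assemble features, run the size-covariate likelihood-ratio screen, then
#' for every requested beta: backward-SFS importance, threshold subsets,
#' hyperparameter optimisation, bootstrap validation and external testing
#' for the five classical families, plus the two-stage MLP search for 1- and
#' 2-hidden-layer networks. Ends with the train/test report table.
#'
#' All randomness derives from `cfg$seed`; two runs with the same config
#' produce identical results and byte-identical CSV outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param data Optional pre-generated `list(train, test)` of
#'   `fruit_dataset`s; default generates from `cfg$generator`.
#' @return List of class `ripeness_pipeline`: `config`, `selection`,
#'   `features` (train/test tables), `size_screen`, `classical`, `mlp`,
#'   `report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), data = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(data)) data <- generate_dataset(cfg$generator)
  sel <- screen_frequencies(data$train, n_boot = cfg$corr_n_boot,
                            seed = cfg$seed + 1L, min_sep = cfg$min_sep,
                            method = cfg$corr_method)
  ft_train <- assemble_features(data$train, sel)
  ft_test <- assemble_features(data$test, sel)
  size_scr <- screen_all(ft_train)

  classical <- list(); mlp <- list()
  results <- list()
  fam_ids <- c(lr = "LR", dt = "DT", nbc = "NBC", knn = "KNN", svm = "SVM")
  for (beta in cfg$betas) {
    bl <- beta_label(beta)
    for (family in names(fam_ids)) {
      res <- run_classical_family(family, ft_train, ft_test, beta, cfg)
      classical[[bl]][[family]] <- res
      results[[fam_ids[[family]]]][[bl]] <-
        list(n_features = res$n_features, train = res$train_score,
             test = res$test_score)
    }
    for (layers in 1:2) {
      res <- run_mlp_branch(layers, ft_train, ft_test, beta, cfg)
      mlp[[bl]][[paste0("mlp", layers)]] <- res
      results[[paste0("MLP-", layers)]][[bl]] <-
        list(n_features = res$n_features, train = res$train_score,
             test = res$test_score)
    }
  }
  report <- make_report(results,
                        betas = vapply(cfg$betas, beta_label, character(1)))
  out <- structure(list(config = cfg, selection = sel,
                        features = list(train = ft_train, test = ft_test),
                        size_screen = size_scr, classical = classical,
                        mlp = mlp, report = report),
                   class = "ripeness_pipeline")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, data, cfg$outdir)
  out
}

# Persist every stage as diff-able CSV/TSV under `dir`.
write_pipeline_outputs <- function(res, data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra_csv(data$train, file.path(dir, "spectra_train.csv"))
  write_spectra_csv(data$test, file.path(dir, "spectra_test.csv"))
  write_selection_csv(res$selection, file.path(dir, "selected_frequencies.csv"))
  write_features_csv(res$features$train, file.path(dir, "features_train.csv"))
  write_features_csv(res$features$test, file.path(dir, "features_test.csv"))
  utils::write.csv(as.data.frame(res$size_screen),
                   file.path(dir, "size_screen.csv"), row.names = FALSE,
                   quote = FALSE)
  imp <- do.call(rbind, lapply(names(res$classical), function(bl)
    do.call(rbind, lapply(res$classical[[bl]], function(r)
      data.frame(family = r$family, beta = r$beta,
                 feature = names(r$importance),
                 importance = unname(r$importance))))))
  utils::write.csv(imp, file.path(dir, "importance.csv"), row.names = FALSE,
                   quote = FALSE)
  boot <- do.call(rbind, lapply(names(res$classical), function(bl)
    do.call(rbind, lapply(res$classical[[bl]], function(r)
      data.frame(family = r$family, beta = r$beta,
                 n_features = r$n_features, rounds = r$bootstrap$rounds,
                 median = r$bootstrap$median, ci_lo = r$bootstrap$ci_lo,
                 ci_hi = r$bootstrap$ci_hi)))))
  utils::write.csv(boot, file.path(dir, "bootstrap.csv"), row.names = FALSE,
                   quote = FALSE)
  write_report_tsv(res$report, file.path(dir, "report.tsv"))
  invisible(dir)
}

#' @method print ripeness_pipeline
#' @export
print.ripeness_pipeline <- function(x, ...) {
  cat("<ripeness_pipeline> betas:",
      paste(x$config$betas, collapse = ", "), "\n\n")
  print(x$report)
  invisible(x)
}
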