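# End-to-end orchestration: configuration, the full analysis bundle, and
# cross-taxon comparison.

# small stable config hash (polynomial rolling hash over serialized config)
.config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Analysis run configuration
#'
#' Bundles every knob of a full analysis run: the model source (a file path,
#' a model object, or a synthetic scenario -- exactly one), the property
#' source, the mode, the log base, the scaling policy, the fixed-effect
#' terms, the output directory and the seed.
#'
#' @param model_path Path to a model file (reversible PAML dialect unless
#'   `nonreversible = TRUE`).
#' @param model A ready `exchange_model` / `nonreversible_model` object.
#' @param scenario A [synth_scenario()] to generate the model from.
#' @param nonreversible Read `model_path` as a full-matrix non-reversible
#'   file.
#' @param properties `"builtin"`, a path to an AAindex1 flat file, a path to
#'   a property CSV, or a `property_table`.
#' @param mode `"directed"` or `"undirected"` pair table.
#' @param log_base Log base for rates (natural log default).
#' @param normalize Divide rates by their mean before logging.
#' @param scale Z-score response and covariates in fits.
#' @param formula Fixed-effects formula of the main model.
#' @param anchors PCA sign anchors; defaults to
#'   `c(PC1 = "hydropathy", PC2 = "mol_weight")` for the builtin property
#'   set and the largest-loading rule otherwise.
#' @param outdir Output directory (created; must not already contain a run
#'   with a different config).
#' @param seed Integer seed (used only for synthetic sources).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(model_path = NULL, model = NULL, scenario = NULL,
                       nonreversible = FALSE,
                       properties = "builtin",
                       mode = c("directed", "undirected"),
                       log_base = exp(1), normalize = FALSE, scale = TRUE,
                       formula = log_rate ~ PC1 * PC2 + min_steps + pyr_diff,
                       anchors = NULL, outdir = NULL, seed = 1) {
  mode <- match.arg(mode)
  nsrc <- sum(!is.null(model_path), !is.null(model), !is.null(scenario))
  if (nsrc != 1) stop("exactly one model source (model_path, model, scenario) required",
                      call. = FALSE)
  if (is.null(anchors) && identical(properties, "builtin"))
    anchors <- c(PC1 = "hydropathy", PC2 = "mol_weight")
  structure(list(model_path = model_path, model = model, scenario = scenario,
                 nonreversible = nonreversible, properties = properties,
                 mode = mode, log_base = log_base, normalize = normalize,
                 scale = scale, formula = formula, anchors = anchors,
                 outdir = outdir, seed = as.integer(seed)),
            class = "run_config")
}

.resolve_model <- function(config) {
  if (!is.null(config$model)) return(config$model)
  if (!is.null(config$model_path)) {
    if (config$nonreversible) return(read_nonreversible_model(config$model_path))
    return(read_exchange_model(config$model_path))
  }
  generate_exchange_model(config$scenario, noise_seed = config$seed)$model
}

.resolve_properties <- function(config) {
  p <- config$properties
  if (inherits(p, "property_table")) return(p)
  if (identical(p, "builtin")) return(builtin_properties())
  if (!is.character(p) || !file.exists(p))
    stop("property source not found: ", p, call. = FALSE)
  first <- readLines(p, n = 1, warn = FALSE)
  if (grepl("^H ", first)) parse_aaindex(p) else read_property_csv(p)
}

#' Run the full analysis
#'
#' Executes the whole pipeline on one model source: pair feature table, PCA
#' of property differences, the main mixed model, model comparisons (with
#' and without the GC term; with and without the PC1:PC2 interaction),
#' per-step subset fits, and the group tests (Welch ANOVA of the
#' pyrimidine-proportion difference across step classes; Welch t-tests of
#' PC1 and PC2 differences for one- vs two-step pairs). When `config$outdir`
#' is set, writes `features.csv`, `pca_summary.csv`, `fit_full.csv`,
#' `comparisons.json`, `fit_steps{1,2,3}.csv`, `group_tests.json` and
#' `run.log`, each tagged with the config hash.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `features`, `pca`, `fit`, `comparisons`,
#'   `step_fits`, `group_tests`, `config_hash`.
#' @export
run_full_analysis <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config[setdiff(names(config), "outdir")])
  say <- function(...) if (!quiet) message(...)
  stage <- "setup"
  log_lines <- c(sprintf("config hash: %s", hash),
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("aasubst"))),
                 sprintf("mode: %s; scaled: %s; log base: %g",
                         config$mode, config$scale, config$log_base))
  result <- tryCatch({
    stage <- "model"
    say("reading model source")
    model <- .resolve_model(config)

    stage <- "properties"
    props <- .resolve_properties(config)

    stage <- "pca"
    say("PCA of pairwise property differences")
    pca <- pair_pca(pairwise_differences(props), anchors = config$anchors)

    stage <- "features"
    feats <- feature_table(model, pca, mode = config$mode,
                           normalize = config$normalize,
                           log_base = config$log_base)

    stage <- "fit"
    say("fitting main mixed model")
    fit <- rate_lmm(config$formula, feats, scale = config$scale)

    stage <- "comparisons"
    base_terms <- attr(terms(config$formula), "term.labels")
    with_gc <- stats::update(config$formula, . ~ . + gc_diff)
    fit_gc <- rate_lmm(with_gc, feats, scale = config$scale)
    cmp_gc <- compare_models(fit_gc, fit)
    no_int <- stats::update(config$formula, . ~ . - PC1:PC2)
    cmp_int <- if (length(attr(terms(no_int), "term.labels")) <
                   length(base_terms)) {
      fit_noint <- rate_lmm(no_int, feats, scale = config$scale)
      compare_models(fit, fit_noint)
    } else NULL
    comparisons <- list(gc_term = cmp_gc, interaction = cmp_int)

    stage <- "steps"
    step_formula <- log_rate ~ PC1 * PC2 + pyr_diff
    step_fits <- lapply(1:3, function(s)
      fit_by_steps(feats, s, formula = step_formula, scale = config$scale))
    names(step_fits) <- paste0("steps", 1:3)

    stage <- "group_tests"
    u <- feats[!duplicated(.pair_key(feats$aa1, feats$aa2)), ]
    group_tests <- list(
      pyr_by_steps = welch_anova(u$pyr_diff, u$min_steps),
      pc1_steps12 = welch_t_test(u$PC1[u$min_steps == 1], u$PC1[u$min_steps == 2]),
      pc2_steps12 = welch_t_test(u$PC2[u$min_steps == 1], u$PC2[u$min_steps == 2]))

    list(features = feats, pca = pca, fit = fit, comparisons = comparisons,
         step_fits = step_fits, group_tests = group_tests, config_hash = hash)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(config$outdir)) {
    out <- config$outdir
    marker <- file.path(out, "run.log")
    if (file.exists(marker)) {
      prev <- grep("^config hash:", readLines(marker, warn = FALSE), value = TRUE)
      if (length(prev) && !grepl(hash, prev[1]))
        stop("output directory holds a run with a different config: ", out,
             call. = FALSE)
    }
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(d, f) write.csv(cbind(d, config_hash = hash),
                                     file.path(out, f), row.names = FALSE)
    wcsv(result$features, "features.csv")
    pca_sum <- data.frame(component = paste0("PC", seq_along(result$pca$explained_fraction)),
                          explained_fraction = result$pca$explained_fraction)
    wcsv(pca_sum, "pca_summary.csv")
    wcsv(result$fit$coefficients, "fit_full.csv")
    for (s in 1:3) wcsv(result$step_fits[[s]]$coefficients,
                        sprintf("fit_steps%d.csv", s))
    jsonlite::write_json(c(result$comparisons, config_hash = hash),
                         file.path(out, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(c(result$group_tests, config_hash = hash),
                         file.path(out, "group_tests.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out, "run.log"))
  }
  invisible(result)
}

#' Compare several taxa / model sources
#'
#' Runs the analysis per model source and assembles the per-taxon coefficient
#' tables plus the matrix of pairwise log-rate correlations between sources.
#'
#' @param configs A named list of [run_config()] objects sharing a mode.
#' @return A list with `fits` (one coefficient table per source, stacked into
#'   `table`), and `similarity` (Pearson correlations of log rates).
#' @export
compare_taxa <- function(configs) {
  if (length(configs) < 2) stop("need at least 2 model sources", call. = FALSE)
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    names(configs) <- paste0("taxon", seq_along(configs))
  modes <- vapply(configs, function(c) c$mode, character(1))
  if (length(unique(modes)) != 1) stop("configs have mixed modes", call. = FALSE)
  runs <- lapply(configs, function(cf) {
    cf$outdir <- NULL
    run_full_analysis(cf)
  })
  rates <- lapply(runs, function(r)
    structure(r$features, mode = attr(r$features, "mode")))
  k <- length(runs)
  sim <- matrix(1, k, k, dimnames = list(names(configs), names(configs)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    sim[i, j] <- sim[j, i] <- matrix_similarity(rates[[i]], rates[[j]])
  tabs <- lapply(names(runs), function(nm)
    cbind(taxon = nm, runs[[nm]]$fit$coefficients))
  list(fits = lapply(runs, function(r) r$fit),
       table = do.call(rbind, tabs),
       similarity = sim)
}
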