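## Pipeline orchestration: screen -> select -> model -> evaluate -> stratify.

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config must contain exactly one of 'input' and 'simulate'")
  config$split <- utils::modifyList(list(ratio = c(4, 1), seed = 1L),
                                    config$split %||% list())
  config$screening <- utils::modifyList(
    list(rule = "n_minus_p0_minus_1", d = NULL), config$screening %||% list())
  config$boosting <- utils::modifyList(
    list(max_steps = 100L, penalty = NULL, folds = 10L, seed = 1L),
    config$boosting %||% list())
  config$evaluation <- utils::modifyList(
    list(grid = NULL, horizons = NULL, dot632plus_B = 0L, seed = 1L),
    config$evaluation %||% list())
  if (is.null(config$output_dir)) stop("config needs an output_dir")
  config
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening-and-selection prognostic pipeline
#'
#' Orchestrates the end-to-end analysis: covariate-balanced train/test
#' split, PSH-CSIS screening on the training cohort, cross-validated
#' component-wise boosting on the screened features, IPCW prediction-error
#' curves (optionally .632+ corrected), time-dependent ROC/AUC on the test
#' cohort, and median-cutoff risk stratification with Aalen-Johansen
#' curves and Gray's test per cohort. Four benchmark models are emitted
#' for comparison: the covariate-free Aalen-Johansen null model, the
#' clinical-only PSH model, boosting without screening, and
#' screening + boosting. All artifacts are written as TSV plus a plain-text
#' run manifest recording seeds and settings.
#'
#' @param config a list, or path to a YAML file, with blocks: exactly one
#'   of `input` (`clinical`, `features` paths and optional column `config`)
#'   or `simulate` (arguments to [sim_config()]); `split` (`ratio`,
#'   `seed`); `screening` (`rule` or explicit `d`); `boosting`
#'   (`max_steps`, `penalty`, `folds`, `seed`); `evaluation` (`grid`,
#'   `horizons`, `dot632plus_B`, `seed`); and `output_dir`.
#' @return Invisibly, a list with every fitted object and the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  manifest <- list()

  data <- pipeline_stage("data", {
    if (!is.null(cfg$input)) {
      read_cr_dataset(cfg$input$clinical, cfg$input$features,
                      cfg$input$config %||% list())
    } else {
      simulate_crdata(do.call(sim_config, cfg$simulate))
    }
  })
  p0 <- ncol(data$Z)

  split <- pipeline_stage("split", {
    s <- split_train_test(data, ratio = unlist(cfg$split$ratio),
                          seed = cfg$split$seed)
    utils::write.table(s$strata_report, file.path(out, "split_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(id = data$subject_id,
                 cohort = ifelse(seq_len(n_subjects(data)) %in% s$train_index,
                                 "train", "test")),
      file.path(out, "split_assignment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    s
  })
  train <- data[split$train_index]
  test <- data[split$test_index]
  n_train <- n_subjects(train)

  screen <- pipeline_stage("screen", {
    d <- cfg$screening$d %||%
      min(default_model_size(n_train, p0, cfg$screening$rule),
          ncol(train$X))               # the rule may exceed the feature count
    sr <- psh_csis(train, d = d)
    write_screening(sr, file.path(out, "screening.tsv"))
    sr
  })

  boost <- pipeline_stage("boost", {
    bf <- cv_boost(train, features = screen$selected,
                   max_steps = cfg$boosting$max_steps,
                   penalty = cfg$boosting$penalty,
                   folds = cfg$boosting$folds, seed = cfg$boosting$seed)
    write_boost_path(bf, file.path(out, "boost_path.tsv"))
    bf
  })

  models <- pipeline_stage("fit", {
    m <- list(
      screen_boost = boost_as_psh_fit(boost, train),
      boost_only = boost_as_psh_fit(
        cv_boost(train, max_steps = cfg$boosting$max_steps,
                 penalty = cfg$boosting$penalty,
                 folds = cfg$boosting$folds, seed = cfg$boosting$seed),
        train),
      clinical = if (p0) psh_fit(train, feature_subset = integer(0)) else NULL
    )
    if (length(m$screen_boost$beta) || length(m$screen_boost$gamma)) {
      tab <- summary_boosted(m$screen_boost)
      utils::write.table(tab, file.path(out, "model_screen_boost.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    m
  })

  evaluation <- pipeline_stage("evaluate", {
    grid <- cfg$evaluation$grid %||% default_grid(train)
    null_cif <- aalen_johansen(train, group_label = "null")
    f1 <- null_cif$cif[["1"]]
    res <- list(grid = grid, null = null_cif)
    pe_path <- file.path(out, "prediction_error.tsv")
    first <- TRUE
    emit <- function(pe) {
      write_pe_curve(pe, pe_path, append = !first)
      first <<- FALSE
    }
    for (cohort in c("train", "test")) {
      dd <- if (cohort == "train") train else test
      preds <- list(
        null = matrix(rep(eval_step(f1, grid), each = n_subjects(dd)),
                      nrow = n_subjects(dd)),
        clinical = if (!is.null(models$clinical))
          predict_cif_matrix(models$clinical, dd$X[, 0, drop = FALSE], dd$Z, grid),
        boost_only = predict_cif_matrix(models$boost_only, dd$X, dd$Z, grid),
        screen_boost = predict_cif_matrix(models$screen_boost, dd$X, dd$Z, grid)
      )
      for (nm in names(preds)) {
        if (is.null(preds[[nm]])) next
        pe <- brier_cif(dd, preds[[nm]], grid, model_label = nm,
                        estimator = if (cohort == "train") "apparent" else "test")
        emit(pe)
        res[[paste0("err_", nm, "_", cohort)]] <- pe
      }
    }
    if (cfg$evaluation$dot632plus_B >= 2) {
      recipe <- screen_boost_recipe(d = screen$d,
                                    max_steps = cfg$boosting$max_steps,
                                    penalty = cfg$boosting$penalty,
                                    folds = cfg$boosting$folds,
                                    seed = cfg$boosting$seed)
      pe632 <- dot632plus(train, recipe, grid,
                          B = cfg$evaluation$dot632plus_B,
                          seed = cfg$evaluation$seed,
                          model_label = "screen_boost")
      emit(pe632)
      res$err_632plus <- pe632
    }
    horizons <- cfg$evaluation$horizons %||%
      stats::quantile(grid, c(0.25, 0.5, 0.75), names = FALSE)
    marker <- risk_score(models$screen_boost, test)
    res$roc <- lapply(horizons, function(h) {
      r <- tryCatch(roc_cif(test, marker, h), error = function(e) NULL)
      if (!is.null(r)) write_roc(r, file.path(out, sprintf("roc_t%g.tsv", h)))
      r
    })
    res
  })

  strat <- pipeline_stage("stratify", {
    sc_train <- risk_score(models$screen_boost, train)
    sc_test <- risk_score(models$screen_boost, test)
    st <- stratify(sc_train, sc_test)
    cifs <- list()
    tests <- list()
    for (cohort in c("train", "test")) {
      dd <- if (cohort == "train") train else test
      gg <- if (cohort == "train") st$train_group else st$test_group
      for (g in levels(gg)) {
        if (!sum(gg == g)) next
        cifs[[paste(cohort, g, sep = "_")]] <-
          aalen_johansen(dd[gg == g], group_label = paste(cohort, g, sep = "_"))
      }
      tests[[cohort]] <- tryCatch(gray_test(dd, gg), error = function(e) NULL)
    }
    write_cif_curves(cifs, file.path(out, "cif_by_risk_group.tsv"))
    gl <- vapply(names(tests), function(ch) {
      gt <- tests[[ch]]
      if (is.null(gt)) sprintf("%s\tNA\tNA\tNA", ch)
      else sprintf("%s\t%.6f\t%d\t%.6g", ch, gt$statistic, gt$df, gt$p_value)
    }, character(1))
    writeLines(c("cohort\tstatistic\tdf\tp_value", gl),
               file.path(out, "gray_test.tsv"))
    list(strat = st, cifs = cifs, gray = tests)
  })

  manifest <- c(
    sprintf("pshscreen_version: %s",
            as.character(utils::packageVersion("pshscreen"))),
    sprintf("n: %d", n_subjects(data)),
    sprintf("n_train: %d", n_train),
    sprintf("n_test: %d", n_subjects(test)),
    sprintf("p: %d", ncol(data$X)),
    sprintf("p0: %d", p0),
    sprintf("split_ratio: %s", paste(cfg$split$ratio, collapse = ":")),
    sprintf("split_seed: %d", cfg$split$seed),
    sprintf("screening_d: %d", screen$d),
    sprintf("boost_penalty: %g", boost$penalty),
    sprintf("boost_folds: %d", cfg$boosting$folds),
    sprintf("boost_seed: %d", cfg$boosting$seed),
    sprintf("boost_selected_steps: %d", boost$selected_steps),
    sprintf("selected_features: %s",
            paste(models$screen_boost$feature_names, collapse = ",")),
    sprintf("risk_cutoff: %.10g", strat$strat$cutoff),
    sprintf("elapsed_seconds: %.2f", proc.time()[["elapsed"]] - t0),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(manifest, file.path(out, "manifest.txt"))

  invisible(list(config = cfg, data = data, split = split, screening = screen,
                 boost = boost, models = models, evaluation = evaluation,
                 stratification = strat, output_dir = out))
}

# default evaluation grid: event-time quantiles inside the follow-up range
default_grid <- function(data, length_out = 20) {
  tt <- data$time[data$cause == 1L]
  if (!length(tt)) tt <- data$time
  seq(min(tt), stats::quantile(data$time, 0.9, names = FALSE),
      length.out = length_out)
}

#' Risk score: linear combination of the selected features
#'
#' The gene-signature score \eqn{\hat\beta' x_i} over the model's selected
#' features (controls excluded: the score summarizes the genomic signature
#' only).
#'
#' @param fit a `psh_fit` (typically from [boost_as_psh_fit()]).
#' @param data a [cr_dataset()].
#' @return Numeric vector of per-subject scores.
#' @export
risk_score <- function(fit, data) {
  if (!length(fit$beta)) return(numeric(n_subjects(data)))
  drop(data$X[, fit$feature_names, drop = FALSE] %*% fit$beta)
}

# coefficient table for a boosted model (no naive SEs: not an ML fit)
summary_boosted <- function(fit) {
  est <- coef(fit)
  data.frame(term = names(est), coef = as.numeric(est),
             hazard_ratio = exp(as.numeric(est)), row.names = NULL)
}

#' Model recipe: screening followed by cross-validated boosting
#'
#' Returns a refittable pipeline for [dot632plus()]: given a training
#' dataset it screens with PSH-CSIS (size `d`, capped at the identifiable
#' maximum for the resample), runs [cv_boost()] on the screened features,
#' and returns a prediction function `(newdata, times)`.
#'
#' @param d screening size (`NULL` = the `n - p0 - 1` default).
#' @param max_steps,penalty,folds,seed passed to [cv_boost()].
#' @return A function `(train_data) -> function(newdata, times)`.
#' @export
screen_boost_recipe <- function(d = NULL, max_steps = 50L, penalty = NULL,
                                folds = 5L, seed = 1L) {
  force(d); force(max_steps); force(penalty); force(folds); force(seed)
  function(train_data) {
    d_use <- min(d %||% default_model_size(n_subjects(train_data),
                                           ncol(train_data$Z)),
                 ncol(train_data$X),
                 max(1L, sum(train_data$cause == 1L) - ncol(train_data$Z) - 1L))
    sr <- psh_csis(train_data, d = d_use)
    bf <- cv_boost(train_data, features = sr$selected, max_steps = max_steps,
                   penalty = penalty, folds = folds, seed = seed)
    fit <- boost_as_psh_fit(bf, train_data)
    function(newdata, times) predict_cif_matrix(fit, newdata$X, newdata$Z, times)
  }
}
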