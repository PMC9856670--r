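#' Competing-risks datasets
#'
#' The central data container: per-subject follow-up time, cause-of-failure
#' code (0 = censored, 1 = event of interest, 2..K = competing causes), a
#' matrix `X` of features subject to screening/selection, and a matrix `Z`
#' of control covariates that are always adjusted for (categorical controls
#' pre-encoded as indicator columns).
#'
#' @param subject_id character vector of unique subject labels.
#' @param time non-negative follow-up times.
#' @param cause integer cause codes; 0 means censored.
#' @param X numeric matrix, subjects x features, with unique column names.
#' @param Z numeric matrix, subjects x controls (may have zero columns).
#' @return An object of class `cr_dataset`.
#' @export
cr_dataset <- function(subject_id, time, cause, X, Z = NULL) {
  n <- length(time)
  if (n < 2) stop("a competing-risks dataset needs at least 2 subjects")
  subject_id <- as.character(subject_id)
  time <- as.numeric(time)
  cause <- as.integer(cause)
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = n, ncol = 0)
  Z <- as.matrix(Z)
  storage.mode(X) <- "double"
  if (ncol(Z)) storage.mode(Z) <- "double"

  if (length(subject_id) != n || nrow(X) != n || nrow(Z) != n)
    stop("subject_id, time, cause, X and Z must agree in length/rows")
  if (anyDuplicated(subject_id))
    stop("duplicated subject identifiers: ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop("times must be finite and non-negative; offending rows: ",
         paste(bad, collapse = ", "))
  bad <- which(is.na(cause) | cause < 0)
  if (length(bad))
    stop("cause codes must be non-negative integers; offending rows: ",
         paste(bad, collapse = ", "))
  if (anyNA(X) || (ncol(Z) && anyNA(Z)))
    stop("missing values in covariate matrices")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (ncol(Z) && is.null(colnames(Z)))
    colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  if (anyDuplicated(colnames(X)))
    stop("duplicated feature names: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "))
  if (ncol(Z) && anyDuplicated(colnames(Z)))
    stop("duplicated control names")

  structure(
    list(subject_id = subject_id, time = time, cause = cause, X = X, Z = Z),
    class = "cr_dataset"
  )
}

#' @export
print.cr_dataset <- function(x, ...) {
  tab <- table(factor(x$cause))
  cat(sprintf("<cr_dataset: n=%d, p=%d features, p0=%d controls>\n",
              length(x$time), ncol(x$X), ncol(x$Z)))
  cat("  cause codes: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param data a [cr_dataset()].
#' @export
n_subjects <- function(data) length(data$time)

#' Subset a competing-risks dataset by subject index
#' @param x a [cr_dataset()].
#' @param i integer or logical subject index.
#' @param ... unused.
#' @export
`[.cr_dataset` <- function(x, i, ...) {
  # bootstrap resampling may repeat subjects; keep labels unique
  cr_dataset(make.unique(x$subject_id[i]), x$time[i], x$cause[i],
             x$X[i, , drop = FALSE], x$Z[i, , drop = FALSE])
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a competing-risks dataset from a clinical table and a feature table
#'
#' The clinical table must contain subject id, follow-up time and cause
#' columns; every remaining column (unless restricted by
#' `config$controls`) is taken as a control covariate. Non-numeric controls
#' are expanded into indicator columns with the first observed level as the
#' reference. The feature table has the subject id as its first column and
#' one numeric column per feature. Subjects are matched by id and returned
#' in clinical-table order.
#'
#' @param clinical_path path to the clinical CSV/TSV.
#' @param features_path path to the feature CSV/TSV.
#' @param config optional list with entries `id`, `time`, `cause`
#'   (column names, defaults `"id"`, `"time"`, `"cause"`) and optionally
#'   `controls` (character vector restricting the control columns).
#' @return A [cr_dataset()].
#' @export
read_cr_dataset <- function(clinical_path, features_path, config = list()) {
  id_col <- config$id %||% "id"
  time_col <- config$time %||% "time"
  cause_col <- config$cause %||% "cause"

  clin <- utils::read.table(clinical_path, header = TRUE,
                            sep = delim_for(clinical_path),
                            stringsAsFactors = FALSE, check.names = FALSE)
  feat <- utils::read.table(features_path, header = TRUE,
                            sep = delim_for(features_path),
                            stringsAsFactors = FALSE, check.names = FALSE)

  for (cn in c(id_col, time_col, cause_col))
    if (!cn %in% names(clin))
      stop("clinical table lacks required column '", cn, "'")

  fnames <- names(feat)[-1]
  if (anyDuplicated(fnames))
    stop("duplicated feature names: ",
         paste(unique(fnames[duplicated(fnames)]), collapse = ", "))

  ids <- as.character(clin[[id_col]])
  fids <- as.character(feat[[1]])
  missing_ids <- setdiff(ids, fids)
  if (length(missing_ids))
    stop("subjects absent from feature table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  extra <- setdiff(fids, ids)
  if (length(extra))
    stop("subjects absent from clinical table: ",
         paste(utils::head(extra, 5), collapse = ", "))

  X <- as.matrix(feat[match(ids, fids), -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- NULL
  if (anyNA(X))
    stop("unparseable or missing feature values for subjects: ",
         paste(utils::head(ids[rowSums(is.na(X)) > 0], 5), collapse = ", "))

  ctrl_cols <- config$controls %||%
    setdiff(names(clin), c(id_col, time_col, cause_col))
  Z <- NULL
  if (length(ctrl_cols)) {
    miss <- setdiff(ctrl_cols, names(clin))
    if (length(miss)) stop("control columns not found: ",
                           paste(miss, collapse = ", "))
    zdf <- clin[ctrl_cols]
    pieces <- lapply(ctrl_cols, function(cn) {
      v <- zdf[[cn]]
      if (is.numeric(v)) {
        m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cn))
      } else {
        # indicator encoding, first observed level as reference
        lev <- unique(as.character(v))
        if (length(lev) < 2)
          m <- matrix(numeric(length(v)), ncol = 1, dimnames = list(NULL, cn))
        else
          m <- sapply(lev[-1], function(l) as.numeric(v == l))
        if (is.null(dim(m))) m <- matrix(m, ncol = 1)
        colnames(m) <- paste0(cn, lev[-1])
        m
      }
      m
    })
    Z <- do.call(cbind, pieces)
  }

  cr_dataset(ids, clin[[time_col]], clin[[cause_col]], X, Z)
}

#' Write a competing-risks dataset as a clinical table and a feature table
#'
#' Inverse of [read_cr_dataset()]: times, causes, features and (already
#' numeric) controls round-trip exactly through the text representation.
#'
#' @param data a [cr_dataset()].
#' @param clinical_path,features_path output paths (`.tsv`/`.txt` write
#'   tab-separated, anything else comma-separated).
#' @export
write_cr_dataset <- function(data, clinical_path, features_path) {
  stopifnot(inherits(data, "cr_dataset"))
  clin <- data.frame(id = data$subject_id, time = data$time,
                     cause = data$cause, check.names = FALSE)
  if (ncol(data$Z)) clin <- cbind(clin, as.data.frame(data$Z))
  feat <- cbind(data.frame(id = data$subject_id), as.data.frame(data$X))
  utils::write.table(clin, clinical_path, sep = delim_for(clinical_path),
                     quote = FALSE, row.names = FALSE)
  utils::write.table(feat, features_path, sep = delim_for(features_path),
                     quote = FALSE, row.names = FALSE)
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream; global .Random.seed restored after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv(), inherits = FALSE)), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Covariate-balanced train/test split
#'
#' Stratified random split: strata are the cross of the cause code with
#' quantile bins (quartiles by default) of the first control column, so the
#' two cohorts share similar event composition and clinical make-up. Within
#' every stratum the train share matches the requested ratio to within one
#' subject (largest-remainder apportionment keeps the overall train size at
#' `round(n * train/(train+test))`).
#'
#' @param data a [cr_dataset()].
#' @param ratio length-2 positive integer vector, `c(train, test)`, e.g.
#'   `c(4, 1)`. A zero test part is only allowed with `all_train = TRUE`.
#' @param seed integer seed; the split is reproducible given the seed.
#' @param n_bins number of quantile bins for the first control column.
#' @param all_train set `TRUE` to allow `ratio = c(k, 0)`.
#' @return A list of class `split_result` with `train_index`, `test_index`
#'   and a per-stratum count table `strata_report`.
#' @export
split_train_test <- function(data, ratio = c(4, 1), seed = 1L,
                             n_bins = 4L, all_train = FALSE) {
  stopifnot(inherits(data, "cr_dataset"))
  ratio <- as.numeric(ratio)
  if (length(ratio) != 2 || any(ratio < 0) || ratio[1] < 1 ||
      (ratio[2] < 1 && !all_train) || any(ratio != floor(ratio)))
    stop("ratio must be two positive integers (test part 0 only with all_train)")
  n <- n_subjects(data)
  r <- ratio[1] / sum(ratio)

  strata <- as.character(data$cause)
  if (ncol(data$Z) > 0) {
    z1 <- data$Z[, 1]
    qs <- unique(stats::quantile(z1, probs = seq(0, 1, length.out = n_bins + 1)))
    bin <- if (length(qs) > 2) cut(z1, qs, include.lowest = TRUE) else factor(1)
    strata <- paste(strata, as.integer(bin), sep = ":")
  }

  target_train <- round(n * r)
  sizes <- table(strata)
  floors <- floor(as.numeric(sizes) * r)
  frac <- as.numeric(sizes) * r - floors
  leftover <- target_train - sum(floors)
  leftover <- max(0L, min(leftover, sum(frac > 0)))
  take <- floors
  if (leftover > 0) {
    bump <- order(frac, decreasing = TRUE)[seq_len(leftover)]
    take[bump] <- take[bump] + 1L
  }
  names(take) <- names(sizes)

  train_index <- integer(0)
  with_seed(seed, {
    for (s in names(sizes)) {
      idx <- which(strata == s)
      k <- take[[s]]
      if (k > 0)
        train_index <- c(train_index, idx[sample.int(length(idx), k)])
    }
  })
  train_index <- sort(train_index)
  test_index <- setdiff(seq_len(n), train_index)

  report <- data.frame(
    stratum = names(sizes),
    n = as.integer(sizes),
    train = as.integer(take),
    test = as.integer(sizes) - as.integer(take),
    row.names = NULL
  )
  structure(list(train_index = train_index, test_index = test_index,
                 strata_report = report, ratio = ratio, seed = seed),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result: %d train / %d test (ratio %d:%d, seed %d)>\n",
              length(x$train_index), length(x$test_index),
              x$ratio[1], x$ratio[2], x$seed))
  invisible(x)
}
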