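# Tabular cardiovascular-disease-style data: synthetic generator, Kaggle
# CSV dialect reader, train/test split with z-score normalization, and a
# multilayer-perceptron objective.

.cvd_feature_cols <- c("age", "gender", "height", "weight", "ap_hi", "ap_lo",
                       "cholesterol", "gluc", "smoke", "alco", "active")

# Marginal band frequencies of the 70,000-record Kaggle CVD cohort
# (age in days; height cm; weight kg; pressures mmHg).
.cvd_marginals <- list(
  age = list(breaks = c(10000, 16000, 18000, 20000, 22000, 24000),
             prob = c(0.1166, 0.1432, 0.2927, 0.2859, 0.1616)),
  height = list(breaks = c(140, 150, 160, 170, 180, 190, 200),
                prob = c(0.0220, 0.2427, 0.4780, 0.2242, 0.0316, 0.0015)),
  weight = list(breaks = c(40, 50, 60, 70, 80, 90, 100, 140),
                prob = c(0.0141, 0.1025, 0.2956, 0.2782, 0.1713, 0.0833, 0.0550)),
  ap_hi = list(breaks = c(90, 120, 140, 160, 180, 200),
               prob = c(0.1863, 0.5366, 0.2062, 0.0557, 0.0152)),
  ap_lo = list(breaks = c(60, 80, 90, 100, 110, 130),
               prob = c(0.2017, 0.5064, 0.2087, 0.0591, 0.0240)),
  gender = c(0.6540, 0.3460),            # 1 = female, 2 = male
  cholesterol = c(0.7484, 0.1364, 0.1152),
  gluc = c(0.8497, 0.0741, 0.0762),
  smoke = 0.0881, alco = 0.0538, active = 0.8037
)

.default_cvd_signal <- c(age = 0.8, gender = 0.1, height = -0.1, weight = 0.4,
                         ap_hi = 1.2, ap_lo = 0.6, cholesterol = 0.5,
                         gluc = 0.2, smoke = 0.1, alco = 0.05, active = -0.2)

.sample_banded <- function(n, spec, integer = TRUE) {
  band <- sample.int(length(spec$prob), n, replace = TRUE, prob = spec$prob)
  lo <- spec$breaks[band]
  hi <- spec$breaks[band + 1L]
  x <- stats::runif(n, lo, hi)  # uniform jitter within the band
  if (integer) floor(x) else round(x, 1)
}

#' Generate a synthetic cardiovascular-disease-style tabular dataset
#'
#' Features are drawn to approximate the marginal distributions of the
#' Kaggle cardiovascular-disease cohort: banded draws matching the printed
#' band frequencies (age in days, height, weight, systolic/diastolic
#' pressure) with uniform jitter within bands, and categorical draws for
#' gender (about 65% female), cholesterol, glucose, smoking, alcohol and
#' activity. The binary outcome `cardio` is drawn from a logistic model on
#' z-scored features with the supplied coefficients; the intercept is
#' calibrated numerically so the expected prevalence is 50%. Correlations
#' between features are not modeled (each feature is sampled from its
#' marginal independently).
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param signal Named coefficient vector over (a subset of) the feature
#'   columns; unnamed features get coefficient 0. `signal = NULL` uses a
#'   plausible default dominated by age and blood pressure; a zero vector
#'   yields an outcome independent of the features.
#' @return A data frame in the Kaggle dialect schema: `id`, `age` (days),
#'   `gender` (1/2), `height` (cm), `weight` (kg), `ap_hi`, `ap_lo`,
#'   `cholesterol` (1-3), `gluc` (1-3), `smoke`, `alco`, `active`,
#'   `cardio`. Attribute `bayes_accuracy` holds the Bayes-optimal accuracy
#'   of the generating model (computable because the model is known).
#' @examples
#' d <- generate_synthetic_cvd(500, seed = 1)
#' mean(d$cardio)  # close to 0.5
#' @export
generate_synthetic_cvd <- function(n, seed = 1, signal = NULL) {
  stopifnot(n >= 1)
  if (is.null(signal)) signal <- .default_cvd_signal
  if (is.null(names(signal)) && length(signal) > 0 && any(signal != 0)) {
    stop("signal coefficients must be named by feature", call. = FALSE)
  }
  unknown <- setdiff(names(signal), .cvd_feature_cols)
  if (length(unknown)) {
    stop("Unknown feature(s) in signal: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  m <- .cvd_marginals
  df <- data.frame(
    id = seq_len(n),
    age = .sample_banded(n, m$age),
    gender = sample(1:2, n, replace = TRUE, prob = m$gender),
    height = .sample_banded(n, m$height),
    weight = .sample_banded(n, m$weight, integer = FALSE),
    ap_hi = .sample_banded(n, m$ap_hi),
    ap_lo = .sample_banded(n, m$ap_lo),
    cholesterol = sample(1:3, n, replace = TRUE, prob = m$cholesterol),
    gluc = sample(1:3, n, replace = TRUE, prob = m$gluc),
    smoke = stats::rbinom(n, 1, m$smoke),
    alco = stats::rbinom(n, 1, m$alco),
    active = stats::rbinom(n, 1, m$active)
  )

  beta <- stats::setNames(numeric(length(.cvd_feature_cols)), .cvd_feature_cols)
  beta[names(signal)] <- signal
  z <- scale(as.matrix(df[.cvd_feature_cols]))
  z[is.nan(z)] <- 0  # constant column at tiny n
  lp <- drop(z %*% beta)
  intercept <- if (all(beta == 0)) 0 else {
    stats::uniroot(function(b0) mean(stats::plogis(lp + b0)) - 0.5,
                   interval = c(-20, 20))$root
  }
  p <- stats::plogis(lp + intercept)
  df$cardio <- stats::rbinom(n, 1, p)
  attr(df, "bayes_accuracy") <- mean(pmax(p, 1 - p))
  attr(df, "signal") <- beta
  df
}

#' Read a cardiovascular-disease CSV in the Kaggle dialect
#'
#' Expects the column set `id;age;gender;height;weight;ap_hi;ap_lo;
#' cholesterol;gluc;smoke;alco;active;cardio`. The delimiter (semicolon by
#' default in this dialect, comma accepted) is auto-detected from the
#' header unless given. The `id` column is dropped; all cells must be
#' numeric and complete.
#'
#' @param path CSV file path.
#' @param delimiter `";"`, `","`, or `NULL` to auto-detect.
#' @return Data frame with the 11 feature columns plus `cardio`, typed
#'   numeric/integer, no missing values.
#' @export
read_cvd_csv <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) {
    delimiter <- if (lengths(gregexpr(";", header)) >=
                     lengths(gregexpr(",", header))) ";" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE)
  expected <- c("id", .cvd_feature_cols, "cardio")
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) || length(extra)) {
    stop("Schema mismatch:",
         if (length(missing)) paste0(" missing [", paste(missing, collapse = ", "), "]"),
         if (length(extra)) paste0(" unexpected [", paste(extra, collapse = ", "), "]"),
         call. = FALSE)
  }
  df <- df[c(.cvd_feature_cols, "cardio")]
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("Non-numeric or missing value in column '", col, "', row ",
           bad[1L], call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Write a dataset in the Kaggle CVD dialect
#' @param dataset Data frame with the feature columns and `cardio`.
#' @param path Output path.
#' @param delimiter Field delimiter (default `";"`).
#' @return The path, invisibly.
#' @export
write_cvd_csv <- function(dataset, path, delimiter = ";") {
  out <- dataset
  if (!"id" %in% names(out)) out <- cbind(id = seq_len(nrow(out)), out)
  utils::write.table(out[c("id", .cvd_feature_cols, "cardio")], path,
                     sep = delimiter, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Seeded 80/20 split with train-fitted z-score normalization
#'
#' Shuffles the rows with the given seed, takes the first 80% as training
#' data, and z-scores every feature column using the mean and SD of the
#' training portion only (the test set never enters the normalization
#' parameters). A zero-variance feature is passed through centered, with a
#' warning.
#'
#' @param dataset Data frame with feature columns and a `cardio` outcome.
#' @param seed Integer seed for the shuffle.
#' @param train_fraction Fraction of rows in the training set
#'   (default 0.8).
#' @return A `tsto_split`: list with `train`, `test` (data frames of
#'   z-scored features + `cardio`), `center`, `scale` (the train-fitted
#'   parameters).
#' @export
split_and_normalize <- function(dataset, seed = 1, train_fraction = 0.8) {
  stopifnot(is.data.frame(dataset), nrow(dataset) >= 5,
            "cardio" %in% names(dataset))
  feats <- setdiff(names(dataset), c("id", "cardio"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ord <- sample.int(nrow(dataset))
  n_train <- floor(train_fraction * nrow(dataset))
  tr_idx <- ord[seq_len(n_train)]
  te_idx <- ord[-seq_len(n_train)]

  center <- vapply(dataset[tr_idx, feats, drop = FALSE], mean, numeric(1))
  scale_ <- vapply(dataset[tr_idx, feats, drop = FALSE], stats::sd, numeric(1))
  zero_var <- names(scale_)[scale_ == 0]
  if (length(zero_var)) {
    warning("Zero-variance feature(s) passed through centered: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
    scale_[scale_ == 0] <- 1
  }
  apply_z <- function(idx) {
    z <- sweep(sweep(as.matrix(dataset[idx, feats, drop = FALSE]), 2, center),
               2, scale_, "/")
    out <- as.data.frame(z)
    out$cardio <- dataset$cardio[idx]
    out
  }
  structure(list(train = apply_z(tr_idx), test = apply_z(te_idx),
                 center = center, scale = scale_,
                 train_index = tr_idx, test_index = te_idx),
            class = "tsto_split")
}

#' MLP hyperparameter set
#'
#' @param hidden_layers Hidden-layer count (>= 1).
#' @param hidden_nodes Nodes per hidden layer (equal across layers).
#' @param activation `"logistic"`, `"tanh"` or `"relu"`.
#' @param optimizer `"lbfgs"`, `"sgd"` or `"adam"`.
#' @param learning_rate,moment_rate Rates in (0, 1).
#' @return A `tsto_mlp_hp` list.
#' @export
mlp_hyperparameters <- function(hidden_layers = 1, hidden_nodes = 8,
                                activation = c("logistic", "tanh", "relu"),
                                optimizer = c("lbfgs", "sgd", "adam"),
                                learning_rate = 0.3, moment_rate = 0.9) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  stopifnot(hidden_layers >= 1, hidden_nodes >= 1,
            learning_rate > 0, learning_rate < 1,
            moment_rate > 0, moment_rate < 1)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_nodes = as.integer(hidden_nodes),
                 activation = activation, optimizer = optimizer,
                 learning_rate = learning_rate, moment_rate = moment_rate),
            class = "tsto_mlp_hp")
}

#' Neural-network training objective over a fixed train/test split
#'
#' Wraps the `nnet` single-hidden-layer feed-forward trainer as a
#' larger-the-better objective: given a hyperparameter assignment it
#' trains a network on the (already normalized) training portion, seeded
#' per replicate so repeated evaluations capture weight-initialization
#' randomness, and returns the test-set classification accuracy in (0, 1].
#'
#' Backend notes: `nnet` fits one hidden layer with logistic activation by
#' BFGS optimization, so `hidden_layers` beyond 1 only selects the node
#' count of that single layer, and `activation`, `optimizer`,
#' `learning_rate` and `moment_rate` are accepted for interface
#' completeness but not consumed by the backend (they matter for backends
#' that define them). Non-convergence within `maxit` is reported as a
#' warning; the accuracy is still returned.
#'
#' @param split A `tsto_split` from [split_and_normalize()].
#' @param maxit Training iteration budget (default 100).
#' @return A `tsto_objective` function of (assignment, replicate, seed).
#'   The assignment may use the worked example's factor names
#'   (`hidden_nodes` etc.) or `nodes`.
#' @export
mlp_objective <- function(split, maxit = 100) {
  stopifnot(inherits(split, "tsto_split"))
  train <- split$train
  test <- split$test
  if (length(unique(train$cardio)) < 2L || length(unique(test$cardio)) < 2L) {
    stop("Train and test sets must both contain both outcome classes",
         call. = FALSE)
  }
  xtr <- as.matrix(train[setdiff(names(train), "cardio")])
  ytr <- train$cardio
  xte <- as.matrix(test[setdiff(names(test), "cardio")])
  yte <- test$cardio

  .as_objective(function(assignment, replicate, seed) {
    nodes <- assignment$hidden_nodes
    if (is.null(nodes)) nodes <- assignment$nodes
    if (is.null(nodes)) nodes <- 8
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed + replicate)
    fit <- nnet::nnet(xtr, ytr, size = as.integer(nodes), entropy = TRUE,
                      maxit = maxit, trace = FALSE,
                      MaxNWts = 10000L)
    if (fit$convergence != 0) {
      warning("nnet did not converge within ", maxit, " iterations",
              call. = FALSE)
    }
    pred <- as.integer(predict(fit, xte) > 0.5)
    max(mean(pred == yte), 1e-6)
  }, type = "mlp")
}
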