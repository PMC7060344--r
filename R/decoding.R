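#' Decoder specification
#'
#' @param cost Regularization constant C of the linear max-margin classifier.
#' @param window_radius Temporal feature window radius in samples; features
#'   at bin t concatenate all channels over bins `t - radius .. t + radius`
#'   (clipped at epoch edges), i.e. a maximum width of `2 * radius + 1`
#'   samples.
#' @param pseudo_trial_group Number of same-class training trials averaged
#'   into one pseudo-trial.
#' @param n_folds Number of cross-validation folds.
#' @param standardize Z-score features with statistics estimated on the
#'   averaged training set and applied to the test set.
#' @return An object of class `decoder_spec`.
#' @export
decoder_spec <- function(cost = 1, window_radius = 2, pseudo_trial_group = 5,
                         n_folds = 20, standardize = TRUE) {
  stopifnot(cost > 0, window_radius >= 0, pseudo_trial_group >= 1,
            n_folds >= 2)
  structure(list(cost = cost, window_radius = as.integer(window_radius),
                 pseudo_trial_group = as.integer(pseudo_trial_group),
                 n_folds = as.integer(n_folds),
                 standardize = isTRUE(standardize)),
            class = "decoder_spec")
}

#' Bundle epochs with decoding labels and balance covariates
#'
#' @param epochs An `epoched_data` object.
#' @param labels One class label per epoch (factor or character).
#' @param covariates Optional data.frame of per-trial nuisance variables;
#'   balancing equalizes every label x covariate cell.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(epochs, labels, covariates = NULL) {
  stopifnot(inherits(epochs, "epoched_data"))
  labels <- factor(labels)
  if (length(labels) != dim(epochs$data)[1])
    stop("one label per trial required")
  if (any(table(labels) == 0L)) labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stop("need at least two label classes")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(labels))
      stop("covariates must have one row per trial")
  }
  structure(list(epochs = epochs, labels = labels, covariates = covariates,
                 class_names = levels(labels)),
            class = "labeled_dataset")
}

#' Balance trials across label classes and covariates
#'
#' Reduces every cell of the label x covariate cross-tabulation to the
#' minimum cell count by seeded uniform subsampling, so that after balancing
#' the label is statistically independent of every covariate (the chi-square
#' association statistic on the retained cross-tab is exactly zero) and all
#' label classes have equal size.
#'
#' @param labels Per-trial class labels.
#' @param covariates Optional data.frame of per-trial covariates.
#' @param seed Integer seed for the subsampling.
#' @param drop_empty_cells In strict mode (default) an empty cell is an
#'   error naming the cell; if `TRUE`, covariate cells that are empty for
#'   some label are dropped entirely instead.
#' @return Sorted integer vector of retained trial indices.
#' @export
balance_trials <- function(labels, covariates = NULL, seed = 1L,
                           drop_empty_cells = FALSE) {
  labels <- as.factor(labels)
  if (!length(labels) || any(table(labels) == 0L))
    stop("every label class must be nonempty")
  cov_cell <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    factor(rep("all", length(labels)))
  else
    interaction(as.data.frame(covariates), drop = FALSE, sep = ":")
  tab <- table(labels, cov_cell)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]  # unused covariate combos
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)
    cells <- paste0(rownames(tab)[bad[, 1]], " x ", colnames(tab)[bad[, 2]])
    if (!drop_empty_cells)
      stop("empty label x covariate cell(s): ", paste(cells, collapse = "; "))
    keep_cov <- colnames(tab)[colSums(tab == 0L) == 0L]
    if (!length(keep_cov)) stop("no covariate cell has all label classes")
    tab <- tab[, keep_cov, drop = FALSE]
  } else {
    keep_cov <- colnames(tab)
  }
  m <- min(tab)
  withr::with_seed(as.integer(seed), {
    keep <- integer(0)
    for (lv in levels(labels))
      for (cc in keep_cov) {
        idx <- which(labels == lv & as.character(cov_cell) == cc)
        keep <- c(keep, if (length(idx) > m) sample(idx, m) else idx)
      }
    sort(keep)
  })
}

#' Stratified cross-validation splits
#'
#' Partitions trials into `n_folds` test sets that are disjoint, jointly
#' exhaustive (each trial appears exactly once in a testing set) and
#' class-balanced up to a remainder of one trial per class and fold. Classes
#' smaller than `n_folds` are legal (40 trials in 4 classes still split into
#' 20 two-trial test sets); test sets then do not all contain every class,
#' while every training set still does.
#'
#' @param labels Per-trial class labels of the (balanced) dataset.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @param allow_small Permit more folds than trials (some test sets are then
#'   empty and their accuracies undefined); default is an error.
#' @return An object of class `cv_split`: list with `fold_id` (1-based fold
#'   assignment per trial) and `folds` (list of `train`/`test` index pairs).
#' @export
make_splits <- function(labels, n_folds = 20, seed = 1L,
                        allow_small = FALSE) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("class(es) too small to train and test: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (length(labels) < n_folds && !allow_small)
    stop("n_folds exceeds the number of trials (", length(labels), ")")
  fold_id <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    offset <- 0L
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      # continue the fold cycle across classes so test-set sizes stay within
      # one of each other even when a class is smaller than n_folds
      fold_id[idx] <- ((offset + seq_along(idx) - 1L) %% n_folds) + 1L
      offset <- offset + length(idx)
    }
  })
  folds <- lapply(seq_len(n_folds), function(k)
    list(train = which(fold_id != k), test = which(fold_id == k)))
  structure(list(fold_id = fold_id, folds = folds, n_folds = n_folds),
            class = "cv_split")
}

#' Windowed feature matrix at one time bin
#'
#' Concatenates, per trial, all channels over the temporal window
#' `[bin - radius, bin + radius]`, clipped at the epoch edges. Channels vary
#' fastest, window bins slowest.
#'
#' @param epochs An `epoched_data` object.
#' @param bin 1-based time-bin index.
#' @param radius Window radius in samples.
#' @return Trials x features numeric matrix (`n_channels * realized width`
#'   columns).
#' @export
window_features <- function(epochs, bin, radius = 2) {
  stopifnot(inherits(epochs, "epoched_data"))
  d <- dim(epochs$data)
  if (bin < 1 || bin > d[3]) stop("bin index out of range")
  cpp_window_features(as.numeric(epochs$data), as.integer(d),
                      seq_len(d[1]) - 1L, as.integer(bin) - 1L,
                      as.integer(radius))
}

#' Average same-class trials into pseudo-trials
#'
#' Within each class, trials are randomly partitioned into groups of
#' `group_size` and averaged. A remainder group of two or more trials is
#' averaged; a single left-over trial passes through unaveraged.
#'
#' @param features Trials x features matrix (training trials only).
#' @param labels Per-trial class labels.
#' @param group_size Trials per pseudo-trial.
#' @param seed Integer seed for the random partition.
#' @return List with `features` (pseudo-trials x features) and `labels`.
#' @export
average_pseudotrials <- function(features, labels, group_size = 5,
                                 seed = 1L) {
  labels <- as.factor(labels)
  if (!length(labels) || any(table(labels) == 0L)) stop("empty class")
  withr::with_seed(as.integer(seed), {
    rows <- list(); labs <- character(0)
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      starts <- seq(1L, length(idx), by = group_size)
      for (s in starts) {
        g <- idx[s:min(length(idx), s + group_size - 1L)]
        rows[[length(rows) + 1L]] <-
          colMeans(features[g, , drop = FALSE])
        labs <- c(labs, lv)
      }
    }
    list(features = do.call(rbind, rows),
         labels = factor(labs, levels = levels(labels)))
  })
}

# shared driver around the C++ engine: one full cross-validated run
decode_run <- function(epochs, labels, spec, seed, shuffle = FALSE,
                       balance_idx = NULL, split_seed = NULL) {
  d <- dim(epochs$data)
  idx <- balance_idx %||% seq_len(d[1])
  labs <- droplevels(factor(labels)[idx])
  split <- make_splits(labs, spec$n_folds, seed = split_seed %||% seed)
  acc <- cpp_decode_run(as.numeric(epochs$data), as.integer(d),
                        as.integer(idx) - 1L,
                        as.integer(labs) - 1L,
                        as.integer(split$fold_id) - 1L,
                        spec$n_folds, spec$window_radius,
                        spec$pseudo_trial_group, spec$cost,
                        spec$standardize, shuffle, as.double(seed))
  list(acc = acc, n_classes = nlevels(labs), idx = idx)
}

#' Time-resolved cross-validated decoding
#'
#' For every time bin and cross-validation fold: extract windowed features,
#' average same-class training trials into pseudo-trials, fit a linear
#' max-margin classifier (one-vs-one with majority voting for more than two
#' classes, ties broken by summed pairwise margins), and score single-trial
#' accuracy on the left-out test split. Balancing (when covariates are
#' present), splitting and pseudo-trial grouping are all re-drawn from the
#' seed, making the run fully reproducible.
#'
#' @param dataset A [labeled_dataset()].
#' @param spec A [decoder_spec()].
#' @param seed Integer seed.
#' @param balance Balance the dataset before decoding (default when
#'   covariates are present). Set to `FALSE` when the caller already passed
#'   balanced trials.
#' @return An object of class `decoding_timecourse`: `time_ms`, `accuracy`
#'   (folds x bins), `mean_accuracy`, `n_classes`, `chance`, `retained`
#'   (indices into the dataset), `spec`, `seed`.
#' @export
decode_timecourse <- function(dataset, spec = decoder_spec(), seed = 1L,
                              balance = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(spec, "decoder_spec"))
  seeds <- derive_seeds(seed, 3L)
  idx <- if (balance)
    balance_trials(dataset$labels, dataset$covariates, seed = seeds[1])
  else seq_along(dataset$labels)
  run <- decode_run(dataset$epochs, dataset$labels, spec, seed = seeds[2],
                    shuffle = FALSE, balance_idx = idx,
                    split_seed = seeds[3])
  structure(list(time_ms = dataset$epochs$time_ms, accuracy = run$acc,
                 mean_accuracy = colMeans(run$acc),
                 n_classes = run$n_classes, chance = 1 / run$n_classes,
                 retained = idx, spec = spec, seed = seed,
                 class_names = dataset$class_names),
            class = "decoding_timecourse")
}

#' Per-channel decoding timecourses
#'
#' Runs [decode_timecourse()] once per channel, with features restricted to
#' that channel's temporal window, e.g. for rendering array maps of where
#' information is available.
#'
#' @inheritParams decode_timecourse
#' @return An object of class `single_channel_decoding`: `accuracy`
#'   (channels x folds x bins array), `mean_accuracy` (channels x bins),
#'   `time_ms`, `channel_ids`, `chance`.
#' @export
single_channel_timecourses <- function(dataset, spec = decoder_spec(),
                                       seed = 1L, balance = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  ep <- dataset$epochs
  n_ch <- dim(ep$data)[2]
  res <- NULL
  for (ch in seq_len(n_ch)) {
    sub <- ep
    sub$data <- ep$data[, ch, , drop = FALSE]
    ds <- dataset
    ds$epochs <- sub
    tc <- decode_timecourse(ds, spec, seed = seed, balance = balance)
    if (is.null(res))
      res <- array(NA_real_, dim = c(n_ch, nrow(tc$accuracy),
                                     ncol(tc$accuracy)))
    res[ch, , ] <- tc$accuracy
    chance <- tc$chance
  }
  structure(list(accuracy = res,
                 mean_accuracy = apply(res, c(1, 3), mean),
                 time_ms = ep$time_ms, channel_ids = ep$channel_ids,
                 chance = chance),
            class = "single_channel_decoding")
}
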