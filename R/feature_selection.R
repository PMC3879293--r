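# Diversity-driven feature-subspace selection: build a repository of feature
# subsets (directed random sampling within per-channel blocks), train a pool
# of classifiers, prune to the most accurate 30%, then forward-select a
# committee minimizing inter-rater agreement (i.e. maximizing diversity).

#' Per-channel feature layout
#'
#' Describes how a flat feature vector decomposes into channel blocks, e.g.
#' 8 channels x 12 spectral bins = 96 features. A single block covering all
#' features gives plain (undirected) random subsets.
#'
#' @param n_channels number of channel blocks.
#' @param block_width features per block; all blocks equal width.
#' @return an object of class `feature_layout`: a list of integer index
#'   blocks.
#' @export
feature_layout <- function(n_channels, block_width) {
  stopifnot(n_channels >= 1L, block_width >= 1L)
  blocks <- lapply(seq_len(n_channels), function(ch)
    seq.int((ch - 1L) * block_width + 1L, ch * block_width))
  structure(blocks, class = "feature_layout",
            n_channels = as.integer(n_channels),
            block_width = as.integer(block_width))
}

#' Directed random feature subset
#'
#' Samples `k_per_channel` indices without replacement from every channel
#' block and concatenates the draws in channel order (sorted within each
#' block), so every channel contributes equally to the subset.
#'
#' @param layout a [feature_layout()] (or plain list of index blocks).
#' @param k_per_channel features drawn per block (1..block width).
#' @param seed integer seed; the draw is deterministic per seed.
#' @return integer vector of `k_per_channel * n_channels` feature indices.
#' @examples
#' directed_random_subset(feature_layout(8, 12), 6, seed = 1) # 48 indices
#' @export
directed_random_subset <- function(layout, k_per_channel, seed) {
  k <- as.integer(k_per_channel)
  widths <- lengths(layout)
  if (k < 1L || any(k > widths))
    stop("k_per_channel must be between 1 and the block width")
  withr::with_seed(as.integer(seed), {
    unlist(lapply(layout, function(block)
      sort(sample(block, k, replace = FALSE))))
  })
}

#' Repository of feature subsets
#'
#' @param layout a [feature_layout()].
#' @param n_subsets number of subsets to draw.
#' @param k_per_channel features per block and subset.
#' @param seed base seed; subset `i` uses `seed + i - 1`.
#' @return an object of class `subset_repository`.
#' @export
subset_repository <- function(layout, n_subsets, k_per_channel, seed = 1L) {
  seeds <- as.integer(seed) + seq_len(n_subsets) - 1L
  subsets <- lapply(seeds, function(s)
    directed_random_subset(layout, k_per_channel, s))
  structure(list(layout = layout, subsets = subsets, seeds = seeds,
                 k_per_channel = as.integer(k_per_channel)),
            class = "subset_repository")
}

#' Train a pool of classifiers, one per feature subset
#'
#' Each subset in the repository yields one network trained on the
#' corresponding feature columns; its validation accuracy and per-sample
#' correctness vector are recorded. A training failure is recorded for that
#' classifier (accuracy `NA`) rather than aborting the pool.
#'
#' @param repository a [subset_repository()] (or plain list of index
#'   vectors).
#' @param x,y training features and integer labels.
#' @param x_val,y_val validation features and labels.
#' @param cfg an [mlp_config()]; classifier `i` trains with `cfg$seed + i -
#'   1`.
#' @return an object of class `classifier_pool` with elements `classifiers`
#'   (list of model, subset, accuracy) and `correctness` (classifiers x
#'   validation samples logical matrix).
#' @export
build_pool <- function(repository, x, y, x_val, y_val, cfg = mlp_config()) {
  subsets <- if (inherits(repository, "subset_repository"))
    repository$subsets else repository
  stopifnot(length(subsets) >= 1L)
  x <- as.matrix(x); x_val <- as.matrix(x_val)
  y <- as.integer(y); y_val <- as.integer(y_val)
  n_classes <- max(y)
  L <- length(subsets)
  correctness <- matrix(NA, L, length(y_val))
  classifiers <- vector("list", L)
  for (i in seq_len(L)) {
    sub <- subsets[[i]]
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i - 1L
    res <- tryCatch({
      model <- train_mlp_expert(x[, sub, drop = FALSE], y,
                                val_features = x_val[, sub, drop = FALSE],
                                val_labels = y_val, cfg = cfg_i,
                                n_classes = n_classes)
      pred <- max.col(expert_mass_matrix(model,
                                         x_val[, sub, drop = FALSE]) %*%
                        model$pignistic_map, "first")
      list(model = model, subset = sub, accuracy = mean(pred == y_val),
           correct = pred == y_val)
    }, error = function(e)
      list(model = NULL, subset = sub, accuracy = NA_real_,
           correct = rep(NA, length(y_val)), error = conditionMessage(e)))
    classifiers[[i]] <- list(model = res$model, subset = res$subset,
                             accuracy = res$accuracy, error = res$error)
    correctness[i, ] <- res$correct
  }
  structure(list(classifiers = classifiers, correctness = correctness,
                 accuracies = vapply(classifiers, `[[`, numeric(1),
                                     "accuracy")),
            class = "classifier_pool")
}

#' Prune a classifier pool to its most accurate fraction
#'
#' Keeps the `ceiling(keep_fraction * n)` classifiers with the highest
#' validation accuracies; ties at the cut are broken toward the lower pool
#' index. Failed classifiers (accuracy `NA`) rank last.
#'
#' @param pool a `classifier_pool`.
#' @param keep_fraction fraction kept (default 0.3).
#' @return the pruned `classifier_pool` (with `kept` indices recorded).
#' @export
prune_pool <- function(pool, keep_fraction = 0.3) {
  acc <- pool$accuracies
  n <- length(acc)
  keep_n <- ceiling(keep_fraction * n)
  ord <- order(-replace(acc, is.na(acc), -Inf), seq_len(n))
  kept <- sort(ord[seq_len(keep_n)])
  structure(list(classifiers = pool$classifiers[kept],
                 correctness = pool$correctness[kept, , drop = FALSE],
                 accuracies = acc[kept], kept = kept),
            class = "classifier_pool")
}

#' Inter-rater agreement of a classifier committee
#'
#' Kuncheva's non-pairwise kappa over a classifiers x samples correctness
#' matrix: `kappa = 1 - sum_j l_j (L - l_j) / (N L (L-1) pbar (1-pbar))`,
#' where `l_j` counts classifiers correct on sample `j` and `pbar` is the
#' mean accuracy. Lower kappa means more disagreement, i.e. better
#' diversity; identical committees have `kappa = 1`. When `pbar` is 0 or 1
#' no disagreement is possible and `kappa = 1` is returned with a warning.
#'
#' @param correctness logical (or 0/1) matrix, classifiers x samples, L >=
#'   2.
#' @return kappa (a real number <= 1; can be negative).
#' @export
interrater_agreement <- function(correctness) {
  correctness <- as.matrix(correctness) * 1
  L <- nrow(correctness); N <- ncol(correctness)
  if (L < 2L) stop("need at least two classifiers")
  pbar <- mean(correctness)
  if (pbar <= 0 || pbar >= 1) {
    warning("mean accuracy is ", pbar, ": no disagreement possible, kappa = 1")
    return(1)
  }
  l <- colSums(correctness)
  1 - sum(l * (L - l)) / (N * L * (L - 1) * pbar * (1 - pbar))
}

#' Forward search for a diverse committee
#'
#' Greedy selection: the most accurate classifier seeds the committee; each
#' iteration adds the candidate minimizing the inter-rater agreement of the
#' enlarged committee (ties broken by higher accuracy, then lower index),
#' until `target_size` classifiers are selected.
#'
#' @param pool a `classifier_pool` (typically after [prune_pool()]).
#' @param target_size committee size (<= pool size); the reference protocol
#'   selects 5.
#' @return integer vector of selected pool indices, in admission order, with
#'   the kappa at each admission as attribute `kappa_trace`.
#' @export
forward_search <- function(pool, target_size = 5L) {
  acc <- pool$accuracies
  n <- length(acc)
  target_size <- as.integer(target_size)
  if (target_size > n) stop("target_size exceeds pool size (", n, ")")
  seed_idx <- order(-replace(acc, is.na(acc), -Inf), seq_len(n))[1L]
  selected <- seed_idx
  kappas <- NA_real_
  while (length(selected) < target_size) {
    cand <- setdiff(seq_len(n), selected)
    k_vals <- vapply(cand, function(j) suppressWarnings(
      interrater_agreement(pool$correctness[c(selected, j), , drop = FALSE])),
      numeric(1))
    best <- cand[order(k_vals, -acc[cand], cand)][1L]
    selected <- c(selected, best)
    kappas <- c(kappas, k_vals[match(best, cand)])
  }
  structure(selected, kappa_trace = kappas)
}

#' Read and write subset repositories as TSV
#'
#' One row per subset: `id<TAB>comma-separated indices`.
#'
#' @param repo a `subset_repository` (or list of index vectors).
#' @param path file path.
#' @return `read_repository` returns a list of integer index vectors.
#' @export
write_repository <- function(repo, path) {
  subsets <- if (inherits(repo, "subset_repository")) repo$subsets else repo
  lines <- vapply(seq_along(subsets), function(i)
    paste0(i, "\t", paste(subsets[[i]], collapse = ",")), character(1))
  writeLines(c("id\tindices", lines), path)
  invisible(path)
}

#' @rdname write_repository
#' @export
read_repository <- function(path) {
  lines <- readLines(path)[-1L]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(f)
    as.integer(strsplit(f[2L], ",", fixed = TRUE)[[1L]]))
}
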